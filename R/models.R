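# Concentration-response model suite.
#
# Ten models fit to standardized responses as functions of concentration,
# with the vehicle mapped to a pseudo-concentration half a log10-step below
# the lowest tested level (c0). All models satisfy f -> 0 as conc -> c0 (log
# models) or conc -> 0 (saturating models), so the vehicle anchors the null
# response. Positive parameters (potencies ga/b/la, exponents p/q) are
# optimized on the log scale, which is the declared bound: they stay
# positive; amplitude parameters (tp, a) are sign-free so responses may go
# in either direction. Exponent arguments are capped to avoid overflow.

EXP_CAP <- 50

# u = log10(conc / c0) >= 0: log-concentration measured from the vehicle
# pseudo-concentration.
cr_ctx <- function(cc) {
  list(cmin = min(cc), cmax = max(cc))
}

cr_models <- function() {
  list(
    cnst = list(
      pnames = character(0), trans = character(0),
      f = function(par, cc, ctx) rep(0, length(cc)),
      starts = function(d, ctx) list(numeric(0))
    ),
    poly1 = list(
      pnames = "a", trans = "id",
      f = function(par, cc, ctx) par[1] * log10(cc / ctx$cmin),
      starts = function(d, ctx) {
        u <- log10(ctx$cmax / ctx$cmin)
        list(c(a = d$emax / max(u, 0.5)))
      }
    ),
    poly2 = list(
      pnames = c("a", "b"), trans = c("id", "id"),
      f = function(par, cc, ctx) {
        u <- log10(cc / ctx$cmin)
        par[1] * u + par[2] * u^2
      },
      starts = function(d, ctx) {
        u <- log10(ctx$cmax / ctx$cmin)
        list(c(a = d$emax / max(u, 0.5), b = 0),
             c(a = 2 * d$emax / max(u, 0.5), b = -d$emax / max(u, 0.5)^2))
      }
    ),
    power = list(
      pnames = c("a", "p"), trans = c("id", "log"),
      f = function(par, cc, ctx) par[1] * (cc / ctx$cmax)^par[2],
      starts = function(d, ctx) list(c(a = d$emax, p = 1), c(a = d$emax, p = 0.5))
    ),
    hill = list(
      pnames = c("tp", "ga", "p"), trans = c("id", "log", "log"),
      f = function(par, cc, ctx) par[1] / (1 + (par[2] / cc)^par[3]),
      starts = function(d, ctx) list(
        c(tp = d$emax, ga = d$cmed, p = 1.2),
        c(tp = d$emax, ga = ctx$cmin * 2, p = 1.2),
        c(tp = 1.2 * d$emax, ga = ctx$cmax / 2, p = 2)
      )
    ),
    gnls = list(
      pnames = c("tp", "ga", "p", "la", "q"),
      trans = c("id", "log", "log", "log", "log"),
      f = function(par, cc, ctx) {
        par[1] / ((1 + (par[2] / cc)^par[3]) * (1 + (cc / par[4])^par[5]))
      },
      starts = function(d, ctx) list(
        c(tp = d$emid, ga = d$cmed / 3, p = 1.2, la = 3 * ctx$cmax, q = 1.2),
        c(tp = d$emid, ga = ctx$cmin, p = 1.2, la = d$cmed * 3, q = 1.2)
      )
    ),
    exp2 = list(
      pnames = c("a", "b"), trans = c("id", "log"),
      f = function(par, cc, ctx) par[1] * expm1(pmin(cc / par[2], EXP_CAP)),
      starts = function(d, ctx) list(c(a = d$emax / expm1(1), b = ctx$cmax))
    ),
    exp3 = list(
      pnames = c("a", "b", "p"), trans = c("id", "log", "log"),
      f = function(par, cc, ctx) {
        par[1] * expm1(pmin((cc / par[2])^par[3], EXP_CAP))
      },
      starts = function(d, ctx) list(c(a = d$emax / expm1(1), b = ctx$cmax, p = 1.2))
    ),
    exp4 = list(
      pnames = c("tp", "ga"), trans = c("id", "log"),
      f = function(par, cc, ctx) par[1] * (1 - 2^(-cc / par[2])),
      starts = function(d, ctx) list(c(tp = d$emax, ga = d$cmed))
    ),
    exp5 = list(
      pnames = c("tp", "ga", "p"), trans = c("id", "log", "log"),
      f = function(par, cc, ctx) par[1] * (1 - 2^(-pmin((cc / par[2])^par[3], EXP_CAP))),
      starts = function(d, ctx) list(
        c(tp = d$emax, ga = d$cmed, p = 1.2),
        c(tp = d$emax, ga = ctx$cmax / 2, p = 2)
      )
    )
  )
}

to_opt <- function(par, trans) {
  out <- par
  i <- trans == "log"
  out[i] <- log(par[i])
  out
}
from_opt <- function(th, trans) {
  out <- th
  i <- trans == "log"
  out[i] <- exp(th[i])
  out
}

# negative log-likelihood with Student-t(df = tdf) residuals; the last
# element of th is log(sigma). Parameters flagged "log" in model$trans are
# optimized on the log scale.
cr_nll <- function(th, model, cc, resp, ctx, tdf = 4) {
  k <- length(model$pnames)
  par <- th[seq_len(k)]
  i <- model$trans == "log"
  par[i] <- exp(par[i])
  lsigma <- th[k + 1]
  sigma <- exp(lsigma)
  mu <- model$f(par, cc, ctx)
  if (any(!is.finite(mu))) return(1e10)
  z <- (resp - mu) / sigma
  tconst <- lgamma((tdf + 1) / 2) - lgamma(tdf / 2) - 0.5 * log(tdf * pi)
  nll <- -sum(tconst - (tdf + 1) / 2 * log1p(z * z / tdf) - lsigma)
  if (!is.finite(nll)) 1e10 else nll
}

# data-driven start heuristics shared across models
cr_start_info <- function(cc, resp, ctx) {
  grp <- split(resp, cc)
  med <- vapply(grp, median, numeric(1))
  conc_lvl <- as.numeric(names(grp))
  top_med <- med[which.max(conc_lvl)]
  big <- med[which.max(abs(med))]
  emax <- if (abs(top_med) > 1e-8) top_med else if (abs(big) > 1e-8) big else 0.1
  list(
    emax = unname(emax),
    emid = unname(if (abs(big) > 1e-8) big else 0.1),
    cmed = exp(mean(log(range(cc)))),
    sigma0 = max(mad(unlist(lapply(grp, function(g) g - median(g)))), 0.05)
  )
}

fit_one_model <- function(name, model, cc, resp, ctx, tdf = 4) {
  d <- cr_start_info(cc, resp, ctx)
  starts <- model$starts(d, ctx)
  k <- length(model$pnames)
  logi <- model$trans == "log"
  f <- model$f
  tconst <- lgamma((tdf + 1) / 2) - lgamma(tdf / 2) - 0.5 * log(tdf * pi)
  hdf <- (tdf + 1) / 2
  obj <- function(th) {
    par <- th[seq_len(k)]
    par[logi] <- exp(par[logi])
    lsigma <- th[k + 1]
    mu <- f(par, cc, ctx)
    if (any(!is.finite(mu))) return(1e10)
    z <- (resp - mu) / exp(lsigma)
    nll <- -sum(tconst - hdf * log1p(z * z / tdf) - lsigma)
    if (!is.finite(nll)) 1e10 else nll
  }
  best <- NULL
  for (s in starts) {
    th0 <- c(to_opt(s, model$trans), log(d$sigma0))
    o <- tryCatch(
      suppressWarnings(
        if (length(th0) == 1) {
          opt <- optimize(obj, interval = log(d$sigma0) + c(-8, 8))
          list(par = opt$minimum, value = opt$objective, convergence = 0L)
        } else {
          optim(th0, obj,
            method = "Nelder-Mead",
            control = list(maxit = 600, reltol = 1e-10)
          )
        }
      ),
      error = function(e) NULL
    )
    if (!is.null(o) && is.finite(o$value) && o$value < 1e9 &&
      (is.null(best) || o$value < best$value)) {
      best <- o
    }
  }
  if (is.null(best)) return(NULL)
  # restart from the incumbent when Nelder-Mead stopped on the iteration cap
  if (length(best$par) > 1 && best$convergence != 0) {
    o2 <- tryCatch(
      suppressWarnings(optim(best$par, obj,
        method = "Nelder-Mead", control = list(maxit = 600, reltol = 1e-10)
      )),
      error = function(e) NULL
    )
    if (!is.null(o2) && is.finite(o2$value) && o2$value <= best$value) best <- o2
  }
  th <- best$par
  par <- from_opt(th[seq_len(k)], model$trans)
  names(par) <- model$pnames
  sigma <- exp(th[k + 1])
  loglik <- -best$value
  npar <- k + 1 # model parameters + residual scale
  grid <- exp(seq(log(ctx$cmin), log(ctx$cmax), length.out = 200))
  pred <- suppressWarnings(model$f(par, grid, ctx))
  if (any(!is.finite(pred))) return(NULL)
  i_top <- if (k == 0) 1L else which.max(abs(pred))
  list(
    name = name, par = as.list(par), sigma = sigma, th = th,
    loglik = loglik, npar = npar, aic = 2 * npar - 2 * loglik,
    top = abs(pred[i_top]), top_signed = pred[i_top],
    conc_at_top = grid[i_top],
    predict = function(conc) model$f(par, conc, ctx),
    model = model, ctx = ctx,
    converged = TRUE
  )
}
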