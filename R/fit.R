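#' Fit the concentration-response model suite to one endpoint
#'
#' Fits ten concentration-response models (constant, linear and quadratic in
#' log10 concentration, power, Hill, gain-loss, and four exponential forms)
#' to standardized responses by maximum likelihood with Student-t (df = 4)
#' residuals, which down-weights the heavy tails typical of larval activity
#' data. Concentration is handled on the log10 scale with the vehicle mapped
#' to a pseudo-concentration half a log10-step below the lowest tested
#' level. Models whose optimizer fails are dropped with a message, never
#' fatally; an error is raised only if every model fails.
#'
#' @param data Tibble with columns `conc` (uM; 0 for vehicle) and `resp`
#'   (standardized response).
#' @param tdf Degrees of freedom of the Student-t residual distribution.
#' @return A `zf_suite` object: list with `fits` (per-model fit lists),
#'   `tbl` (per-model summary tibble with `aic`, `loglik`, `top`),
#'   `data` (with the pseudo-concentration column `cc`), and `ctx`.
#' @export
fit_suite <- function(data, tdf = 4) {
  stopifnot(all(c("conc", "resp") %in% names(data)))
  if (any(data$conc < 0)) abort("concentrations must be >= 0")
  if (anyNA(data$resp) || any(!is.finite(data$resp))) {
    abort("responses must be finite")
  }
  nz <- sort(unique(data$conc[data$conc > 0]))
  if (length(nz) < 2) abort("need >= 2 distinct nonzero concentrations")
  c0 <- nz[1] / 10^0.5
  cc <- ifelse(data$conc == 0, c0, data$conc)
  ctx <- cr_ctx(cc)
  fits <- list()
  failed <- character(0)
  models <- cr_models()
  for (name in names(models)) {
    model <- models[[name]]
    fit <- fit_one_model(name, model, cc, data$resp, ctx, tdf)
    if (is.null(fit)) failed <- c(failed, name) else fits[[name]] <- fit
  }
  if (length(failed)) {
    inform(paste0("model(s) failed to converge and were excluded: ",
                  paste(failed, collapse = ", ")))
  }
  if (!length(fits)) abort("all concentration-response models failed")
  tbl <- purrr::map_dfr(fits, function(f) {
    tibble(
      model = f$name, npar = f$npar, loglik = f$loglik, aic = f$aic,
      top = f$top, top_signed = f$top_signed, conc_at_top = f$conc_at_top,
      sigma = f$sigma
    )
  })
  structure(
    list(fits = fits, tbl = tbl, data = tibble(conc = data$conc, cc = cc,
                                               resp = data$resp),
         ctx = ctx, tdf = tdf, c0 = c0),
    class = "zf_suite"
  )
}

akaike_weights <- function(aic) {
  d <- aic - min(aic)
  w <- exp(-d / 2)
  w / sum(w)
}

# Winning model: lowest AIC, with the standard parsimony convention that
# models within a few AIC units of the minimum have comparable support, so
# the simplest of them (fewest parameters; ties by AIC) is selected. This
# keeps the constant model winning on null data instead of an overfit curve
# while leaving clear-signal winners (AIC gaps of tens to hundreds)
# untouched.
suite_winner <- function(suite, window = 4) {
  tbl <- suite$tbl
  cand <- tbl[tbl$aic <= min(tbl$aic) + window, ]
  cand <- cand[order(cand$npar, cand$aic), ]
  suite$fits[[cand$model[1]]]
}

# asymptotic SE of a sample median of n draws from the fitted t(df) error
# model with scale sigma: 1 / (2 f(0) sqrt(n)) with f(0) = dt(0, df)/sigma
median_se <- function(sigma, n, tdf = 4) {
  sigma / (2 * dt(0, df = tdf) * sqrt(n))
}

# delta-method SE of the winning model's top from the numeric Hessian of the
# negative log-likelihood; falls back to sigma/sqrt(N) when singular
top_se <- function(fit, suite) {
  n <- nrow(suite$data)
  fallback <- fit$sigma / sqrt(n)
  if (!length(fit$model$pnames)) return(fallback)
  H <- tryCatch(
    stats::optimHess(fit$th, cr_nll,
      model = fit$model, cc = suite$data$cc, resp = suite$data$resp,
      ctx = fit$ctx, tdf = suite$tdf
    ),
    error = function(e) NULL
  )
  if (is.null(H)) return(fallback)
  cov <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(cov)) return(fallback)
  th <- fit$th
  k <- length(th)
  top_of <- function(t) {
    par <- from_opt(t[seq_len(k - 1)], fit$model$trans)
    grid <- exp(seq(log(fit$ctx$cmin), log(fit$ctx$cmax), length.out = 200))
    max(abs(fit$model$f(par, grid, fit$ctx)))
  }
  h <- pmax(abs(th) * 1e-4, 1e-5)
  g <- vapply(seq_len(k), function(i) {
    tp <- th; tp[i] <- tp[i] + h[i]
    tm <- th; tm[i] <- tm[i] - h[i]
    (top_of(tp) - top_of(tm)) / (2 * h[i])
  }, numeric(1))
  v <- drop(t(g) %*% cov %*% g)
  if (!is.finite(v) || v <= 0) fallback else sqrt(v)
}

#' Continuous hitcall for a fitted model suite
#'
#' The hitcall is the product of three proportional weights, each in
#' `[0, 1]`: `w1`, one minus the Akaike weight of the constant model among
#' all fitted models (evidence that any concentration-response model beats
#' flat); `w2`, the probability that the treated concentration group with
#' the largest absolute median response truly exceeds the cutoff, using the
#' median's asymptotic sampling SE under the fitted t-residual model; and
#' `w3`, the probability that the winning model's maximal absolute predicted
#' response (its "top") exceeds the cutoff, using a delta-method SE. A curve
#' is called active when the hitcall reaches the activity threshold
#' (conventionally 0.9).
#'
#' @param suite A [fit_suite()] object.
#' @param cutoff Response cutoff in standardized (control-SD) units.
#' @return A list with `w1`, `w2`, `w3`, `hitcall`, and `winner` (name of
#'   the winning model by AIC).
#' @export
hitcall <- function(suite, cutoff) {
  stopifnot(inherits(suite, "zf_suite"), cutoff > 0)
  tbl <- suite$tbl
  non_cnst <- tbl$model[tbl$model != "cnst"]
  if (!length(non_cnst)) {
    return(list(w1 = 0, w2 = 0, w3 = 0, hitcall = 0, winner = "cnst"))
  }
  w <- akaike_weights(tbl$aic)
  w1 <- if ("cnst" %in% tbl$model) 1 - w[tbl$model == "cnst"] else 1
  winner <- suite_winner(suite)

  treated <- suite$data[suite$data$conc > 0, ]
  grp <- split(treated$resp, treated$conc)
  med <- vapply(grp, median, numeric(1))
  ng <- lengths(grp)
  i <- which.max(abs(med))
  se_med <- median_se(winner$sigma, ng[i], suite$tdf)
  w2 <- pnorm((abs(med[i]) - cutoff) / se_med) +
    pnorm((-cutoff - abs(med[i])) / se_med)

  if (winner$name == "cnst") {
    w3 <- 0
  } else {
    se_top <- top_se(winner, suite)
    w3 <- 1 - pnorm(cutoff, mean = winner$top, sd = se_top)
  }
  hc <- unname(w1 * w2 * w3)
  list(w1 = unname(w1), w2 = unname(w2), w3 = unname(w3),
       hitcall = min(max(hc, 0), 1), winner = winner$name)
}

# first concentration in [cmin, cmax] where |f| crosses bmr; grid bracket
# then bisection. Returns NA when the curve never reaches bmr in range.
bmc_crossing <- function(predict, cmin, cmax, bmr, tol = 1e-8) {
  grid <- exp(seq(log(cmin), log(cmax), length.out = 400))
  a <- abs(predict(grid))
  if (a[1] >= bmr) return(grid[1])
  hit <- which(a >= bmr)
  if (!length(hit)) return(NA_real_)
  i <- hit[1]
  lo <- grid[i - 1]; hi <- grid[i]
  g <- function(c) abs(predict(c)) - bmr
  for (iter in 1:100) {
    mid <- sqrt(lo * hi)
    if (g(mid) >= 0) hi <- mid else lo <- mid
    if (hi / lo - 1 < tol) break
  }
  sqrt(lo * hi)
}

#' Benchmark concentration with bootstrap confidence bounds
#'
#' The benchmark response (BMR) is `bmr_multiplier` control SDs in
#' standardized units (default 1.349, the conventional continuous benchmark
#' response). The BMC is the smallest concentration in the tested range
#' where the winning model's absolute predicted response equals the BMR,
#' found by a grid bracket plus bisection. Confidence bounds (BMDL, BMDU)
#' are the 5th and 95th percentiles of the BMC over nonparametric bootstrap
#' refits of the winning model, resampling responses within each
#' concentration group.
#'
#' @param suite A [fit_suite()] object.
#' @param bmr_multiplier BMR in control-SD units (default 1.349).
#' @param n_boot Number of bootstrap refits (default 1000; 0 skips the
#'   bounds).
#' @param seed Optional integer seed for the bootstrap.
#' @return One-row tibble: `bmc`, `bmdl`, `bmdu`, `bmr`, `reason` (`NA` when
#'   a BMC exists, otherwise why not).
#' @export
bmc <- function(suite, bmr_multiplier = 1.349, n_boot = 1000, seed = NULL) {
  stopifnot(inherits(suite, "zf_suite"), bmr_multiplier > 0, n_boot >= 0)
  winner <- suite_winner(suite)
  bmr <- bmr_multiplier # control SD = 1 in standardized units
  if (winner$name == "cnst") {
    return(tibble(bmc = NA_real_, bmdl = NA_real_, bmdu = NA_real_,
                  bmr = bmr, reason = "constant model won"))
  }
  est <- bmc_crossing(winner$predict, suite$ctx$cmin, suite$ctx$cmax, bmr)
  if (is.na(est)) {
    return(tibble(bmc = NA_real_, bmdl = NA_real_, bmdu = NA_real_,
                  bmr = bmr, reason = "no crossing in tested range"))
  }
  bmdl <- bmdu <- NA_real_
  if (n_boot > 0) {
    run_boot <- function() {
      idx_by_grp <- split(seq_len(nrow(suite$data)), suite$data$cc)
      vapply(seq_len(n_boot), function(b) {
        idx <- unlist(lapply(idx_by_grp, function(ii) {
          ii[sample.int(length(ii), replace = TRUE)]
        }))
        cc_b <- suite$data$cc[idx]
        resp_b <- suite$data$resp[idx]
        fit_b <- fit_one_model(winner$name, winner$model, cc_b, resp_b,
                               suite$ctx, suite$tdf)
        if (is.null(fit_b)) return(NA_real_)
        bmc_crossing(fit_b$predict, suite$ctx$cmin, suite$ctx$cmax, bmr)
      }, numeric(1))
    }
    boots <- if (is.null(seed)) run_boot() else withr::with_seed(seed, run_boot())
    ok <- boots[!is.na(boots)]
    if (length(ok) >= max(20, 0.05 * n_boot)) {
      qs <- unname(quantile(ok, c(0.05, 0.95), type = 7))
      bmdl <- qs[1]; bmdu <- qs[2]
    }
  }
  tibble(bmc = est, bmdl = bmdl, bmdu = bmdu, bmr = bmr, reason = NA_character_)
}

#' Fit, score, and summarize one endpoint's concentration-response
#'
#' Convenience wrapper chaining [fit_suite()], [hitcall()], and [bmc()] for
#' one endpoint's standardized responses.
#'
#' @inheritParams fit_suite
#' @param cutoff Response cutoff in control-SD units.
#' @param bmr_multiplier BMR in control-SD units (default 1.349).
#' @param n_boot Bootstrap refits for the BMC bounds.
#' @param hit_threshold Hitcall at or above which the endpoint is called
#'   active (default 0.9).
#' @param seed Optional seed for the bootstrap.
#' @param endpoint Optional endpoint label carried into the summaries.
#' @return A `zf_concresp` object; see [tidy.zf_concresp()] and
#'   [glance.zf_concresp()].
#' @export
fit_concresp <- function(data, cutoff = 1, bmr_multiplier = 1.349,
                         n_boot = 1000, hit_threshold = 0.9, seed = NULL,
                         endpoint = NA_character_) {
  suite <- fit_suite(data)
  hc <- hitcall(suite, cutoff)
  bm <- bmc(suite, bmr_multiplier, n_boot = n_boot, seed = seed)
  structure(
    list(
      endpoint = endpoint, suite = suite, hit = hc, bmc = bm,
      cutoff = cutoff, hit_threshold = hit_threshold,
      active = hc$hitcall >= hit_threshold
    ),
    class = "zf_concresp"
  )
}

#' @export
print.zf_concresp <- function(x, ...) {
  cat(sprintf(
    "<zf_concresp>%s winner=%s hitcall=%.3f%s%s\n",
    if (is.na(x$endpoint)) "" else paste0(" ", x$endpoint),
    x$hit$winner, x$hit$hitcall,
    if (x$active) " ACTIVE" else "",
    if (is.na(x$bmc$bmc)) "" else sprintf(" BMC=%.3g uM", x$bmc$bmc)
  ))
  invisible(x)
}

#' Per-model summaries of a concentration-response fit
#'
#' @param x A [fit_concresp()] object.
#' @param ... Unused.
#' @return Tibble with one row per fitted model: `model`, `npar`, `loglik`,
#'   `aic`, `akaike_weight`, `top`.
#' @export
tidy.zf_concresp <- function(x, ...) {
  x$suite$tbl %>%
    mutate(akaike_weight = akaike_weights(.data$aic)) %>%
    select("model", "npar", "loglik", "aic", "akaike_weight", "top",
           "top_signed", "sigma") %>%
    arrange(.data$aic)
}

#' One-row summary of a concentration-response fit
#'
#' @param x A [fit_concresp()] object.
#' @param ... Unused.
#' @return One-row tibble: `endpoint`, `winner`, `w1`-`w3`, `hitcall`,
#'   `active`, `bmc`, `bmdl`, `bmdu`, `bmr`, `cutoff`, `n`.
#' @export
glance.zf_concresp <- function(x, ...) {
  tibble(
    endpoint = x$endpoint, winner = x$hit$winner,
    w1 = x$hit$w1, w2 = x$hit$w2, w3 = x$hit$w3,
    hitcall = x$hit$hitcall, active = x$active,
    bmc = x$bmc$bmc, bmdl = x$bmc$bmdl, bmdu = x$bmc$bmdu,
    bmr = x$bmc$bmr, cutoff = x$cutoff, n = nrow(x$suite$data)
  )
}
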