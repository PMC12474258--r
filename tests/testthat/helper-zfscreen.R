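# Shared fixtures and independent oracles for the test suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent, naive transcription of the 13 endpoint formulas. Deliberately
# written as plain arithmetic on the two phase vectors, sharing no code with
# the package implementation.
naive_endpoints <- function(l, d) {
  m <- length(l)
  n <- length(d)
  auc <- function(v) {
    total <- 0
    for (i in seq_len(length(v) - 1)) total <- total + (v[i] + v[i + 1]) / 2
    total
  }
  light_avg <- sum(l) / m
  dark_avg <- sum(d) / n
  c(
    avgSL = light_avg,
    avgSD = dark_avg,
    avgST = sum(c(l, d)) / (m + n),
    hbt1L = (l[m] - l[1]) / (m - 1),
    hbt1D = (d[n] - d[1]) / (n - 1),
    hbt2L = (l[m] - l[2]) / (m - 2) - (l[m - 1] - l[1]) / (m - 2),
    hbt2D = (d[n] - d[2]) / (n - 2) - (d[n - 1] - d[1]) / (n - 2),
    RoAL = max(l) / (min(l) + 1),
    RoAD = max(d) / (min(d) + 1),
    strtlA = d[1] - l[m],
    strtlAavg = d[1] - light_avg,
    strtlF = d[1] / max(l[m], 0.02),
    AUC_r = auc(d) / max(auc(l), 0.02)
  )
}

# random phase vectors with the right-skewed look of real activity data
random_phases <- function(m = NULL, n = NULL) {
  m <- m %||% sample(3:25, 1)
  n <- n %||% sample(3:25, 1)
  list(l = rgamma(m, shape = 2, scale = 2), d = rgamma(n, shape = 2, scale = 4))
}

# bin tibble for a single larva from phase vectors
bins_from_phases <- function(l, d, acc = numeric(0), larva_id = "larva1",
                             conc_uM = 0, bin_min = 2) {
  dist <- c(acc, l, d)
  tibble::tibble(
    larva_id = larva_id,
    conc_uM = conc_uM,
    bin_start_min = bin_min * (seq_along(dist) - 1),
    phase = rep(c("acclimation", "light", "dark"),
                c(length(acc), length(l), length(d))),
    distance_cm = dist
  )
}

# balanced phase-means table with configurable group means
phase_means_table <- function(n_per_group, conc = c(0, 1, 10, 100),
                              light_mu = 3, dark_mu = 8, sd = 1,
                              group_shift = rep(0, length(conc))) {
  purrr::map_dfr(seq_along(conc), function(g) {
    tibble::tibble(
      larva_id = paste0("g", g, "_", seq_len(n_per_group)),
      conc_uM = conc[g],
      light = rnorm(n_per_group, light_mu + group_shift[g], sd),
      dark = rnorm(n_per_group, dark_mu + group_shift[g], sd)
    )
  }) |>
    tidyr::pivot_longer(c("light", "dark"),
                        names_to = "phase", values_to = "distance")
}

sample_skewness <- function(x) mean((x - mean(x))^3) / sd(x)^3

# inverse Box-Cox: builds data with a known true lambda
inv_boxcox <- function(z, lambda) {
  if (abs(lambda) < 1e-12) exp(z) else (1 + lambda * z)^(1 / lambda)
}

lambda_recovery_sample <- function(lambda, n = 641) {
  z <- rnorm(n,
    mean = if (lambda < 0) -1 else 2,
    sd = if (lambda < 0) 0.45 else 0.6
  )
  if (lambda > 0) z <- pmax(z, -1 / lambda + 0.05)
  if (lambda < 0) z <- pmin(z, -1 / lambda - 0.05)
  inv_boxcox(z, lambda)
}

# standard simulation scenarios used across tests: the baseline (null)
# plate and the dark-suppression active chemical
null_config <- function(...) sim_config(...)
dark_suppression_config <- function(emax = 0.6, ac50 = 3, hill = 2, ...) {
  sim_config(
    effects = list(list(driver = "dark_level", emax = emax, ac50 = ac50,
                        hill = hill)),
    chemical = "dark_suppressor", ...
  )
}

# Cache for expensive simulation-heavy summaries shared between test blocks
.zf_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .zf_test_cache)) {
    assign(key, force(expr), envir = .zf_test_cache)
  }
  get(key, envir = .zf_test_cache)
}

# Screens of seeded null plates against a frozen reference; returns a list
# with the per-plate active endpoint sets. Shared by the null-rate and
# end-to-end checks.
null_screen_actives <- function(n_plates, ref) {
  purrr::map(seq_len(n_plates), function(i) {
    pl <- simulate_plate(null_config(), seed = 1000 + i)
    ep <- compute_endpoints(pl$bins)
    sc <- suppressMessages(screen_chemical(ep, ref, n_boot = 0))
    sc$results$endpoint[sc$results$active]
  })
}

frozen_reference <- function() {
  cached("reference", simulate_vehicle_reference(null_config(), 641, seed = 7))
}
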