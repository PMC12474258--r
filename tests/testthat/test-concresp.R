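std_design <- function(n = 16, conc_lvls = 100 * 10^(-0.5 * (4:0))) {
  rep(c(0, conc_lvls), each = n)
}

hill_resp <- function(conc, top, ga, p) {
  ifelse(conc == 0, 0, top / (1 + (ga / conc)^p))
}

test_that("the constant model wins on pure noise", {
  withr::local_seed(301)
  conc <- std_design()
  d <- tibble::tibble(conc = conc, resp = rnorm(length(conc)))
  s <- suppressMessages(fit_suite(d))
  expect_equal(zfscreen:::suite_winner(s)$name, "cnst")
})

test_that("near-noiseless Hill data recover top within 1% and AC50 within 5%", {
  withr::local_seed(302)
  conc <- std_design()
  d <- tibble::tibble(
    conc = conc,
    resp = hill_resp(conc, top = 5, ga = 1, p = 2) + rnorm(length(conc), 0, 1e-6)
  )
  s <- suppressMessages(fit_suite(d))
  hp <- s$fits$hill$par
  expect_lt(abs(hp$tp - 5) / 5, 0.01)
  expect_lt(abs(hp$ga - 1) / 1, 0.05)
})

test_that("AIC follows its definition for every fitted model", {
  withr::local_seed(303)
  conc <- std_design()
  d <- tibble::tibble(conc = conc, resp = rnorm(length(conc), 0, 1))
  s <- suppressMessages(fit_suite(d))
  expect_equal(s$tbl$aic, 2 * s$tbl$npar - 2 * s$tbl$loglik, tolerance = 1e-12)
  # equal log-likelihood at different k implies an AIC gap of exactly 2 dk
  expect_equal((2 * 3 - 2 * 5) - (2 * 2 - 2 * 5), 2)
})

test_that("hitcall stays small on flat null data and saturates on strong signal", {
  withr::local_seed(304)
  conc <- std_design()
  null_fit <- suppressMessages(
    fit_suite(tibble::tibble(conc = conc, resp = rnorm(length(conc))))
  )
  hc0 <- hitcall(null_fit, cutoff = 1)
  expect_lt(hc0$hitcall, 0.1)

  strong <- suppressMessages(fit_suite(tibble::tibble(
    conc = conc,
    resp = hill_resp(conc, top = 5, ga = 1, p = 2) +
      rnorm(length(conc), 0, 0.3)
  )))
  hc1 <- hitcall(strong, cutoff = 1)
  expect_gt(hc1$hitcall, 0.99)
  for (h in list(hc0, hc1)) {
    expect_true(all(unlist(h[c("w1", "w2", "w3")]) >= 0))
    expect_true(all(unlist(h[c("w1", "w2", "w3")]) <= 1))
  }
})

test_that("a hitcall exactly at the threshold is called active", {
  fake <- structure(
    list(endpoint = "avgSD", hit = list(hitcall = 0.9, winner = "hill",
                                        w1 = 1, w2 = 0.9, w3 = 1),
         bmc = tibble::tibble(bmc = 1, bmdl = NA, bmdu = NA, bmr = 1.349,
                              reason = NA),
         cutoff = 1, hit_threshold = 0.9, active = 0.9 >= 0.9),
    class = "zf_concresp"
  )
  expect_true(fake$active)
  # and the constructor applies the same rule
  withr::local_seed(305)
  conc <- std_design()
  fit <- suppressMessages(fit_concresp(
    tibble::tibble(conc = conc,
                   resp = hill_resp(conc, 5, 1, 2) + rnorm(length(conc), 0, 0.3)),
    cutoff = 1, n_boot = 0
  ))
  expect_identical(fit$active, fit$hit$hitcall >= fit$hit_threshold)
})

test_that("BMC inverts the Hill form analytically", {
  conc <- rep(c(0, 100 * 10^(-0.5 * (7:0))), each = 16)
  d <- tibble::tibble(conc = conc, resp = hill_resp(conc, top = 5, ga = 1, p = 1))
  s <- suppressMessages(fit_suite(d))
  b <- bmc(s, bmr_multiplier = 1, n_boot = 0)
  expect_lt(abs(b$bmc - 0.25) / 0.25, 0.01)
})

test_that("a curve whose top never reaches the BMR yields no BMC", {
  withr::local_seed(306)
  conc <- std_design()
  d <- tibble::tibble(
    conc = conc,
    resp = hill_resp(conc, top = 0.8, ga = 3, p = 2) + rnorm(length(conc), 0, 0.05)
  )
  s <- suppressMessages(fit_suite(d))
  b <- bmc(s, bmr_multiplier = 1.349, n_boot = 0)
  expect_true(is.na(b$bmc))
  expect_match(b$reason, "no crossing")
})

test_that("bootstrap bounds bracket the BMC estimate", {
  withr::local_seed(307)
  conc <- std_design()
  ok <- replicate(10, {
    d <- tibble::tibble(
      conc = conc,
      resp = hill_resp(conc, top = -4, ga = 3, p = 2) + rnorm(length(conc), 0, 0.8)
    )
    s <- suppressMessages(fit_suite(d))
    b <- bmc(s, bmr_multiplier = 1.349, n_boot = 100)
    is.na(b$bmc) || (b$bmdl <= b$bmc && b$bmc <= b$bmdu)
  })
  expect_gte(mean(ok), 0.9)
})

test_that("hitcall is monotone non-decreasing in injected effect size", {
  conc <- std_design()
  emaxes <- c(0, 1, 2, 3.5, 5)
  hcs <- vapply(emaxes, function(top) {
    withr::with_seed(308, {
      noise <- rnorm(length(conc), 0, 0.8)
      d <- tibble::tibble(conc = conc,
                          resp = hill_resp(conc, top, ga = 3, p = 2) + noise)
      s <- suppressMessages(fit_suite(d))
      hitcall(s, cutoff = 1)$hitcall
    })
  }, numeric(1))
  expect_true(all(hcs >= 0 & hcs <= 1))
  expect_true(all(diff(hcs) >= -1e-6))
})

test_that("screening a single-endpoint effect marks exactly that pattern", {
  withr::local_seed(309)
  ref <- frozen_reference()
  cfg <- dark_suppression_config()
  pl <- simulate_plate(cfg, seed = 310)
  ep <- compute_endpoints(pl$bins)
  sc <- suppressMessages(screen_chemical(ep, ref, n_boot = 0))
  expect_equal(nrow(sc$results), 13)
  expect_true(all(sc$results$hitcall >= 0 & sc$results$hitcall <= 1))
  expect_true("avgSD" %in% sc$results$endpoint[sc$results$active])
  hm <- screen_heatmap(sc)
  expect_equal(sum(hm$active), sum(sc$results$active))
  expect_equal(unique(hm$chemical), "dark_suppressor")
})

test_that("fit_suite validates its input contract", {
  expect_error(fit_suite(tibble::tibble(conc = c(0, 1, 1), resp = c(0, 1, 2))),
               "2 distinct nonzero")
  expect_error(fit_suite(tibble::tibble(conc = c(0, 1, 10), resp = c(0, NA, 2))),
               "finite")
  expect_error(fit_suite(tibble::tibble(conc = c(-1, 1, 10), resp = c(0, 1, 2))),
               ">= 0")
})
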