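# textbook mixed-design sums-of-squares oracle for a balanced layout,
# computed straight from cell means (shares nothing with rm_anova internals)
textbook_mixed_anova <- function(df) {
  wide <- tidyr::pivot_wider(df, id_cols = c("larva_id", "conc_uM"),
                             names_from = "phase", values_from = "distance")
  y <- c(wide$light, wide$dark)
  subj <- rep(wide$larva_id, 2)
  grp <- rep(wide$conc_uM, 2)
  ph <- rep(c("light", "dark"), each = nrow(wide))
  grand <- mean(y)
  a <- length(unique(grp)); b <- 2
  n <- nrow(wide) / a # per-group subjects (balanced)
  grp_mean <- tapply(y, grp, mean)
  ph_mean <- tapply(y, ph, mean)
  cell_mean <- tapply(y, list(grp, ph), mean)
  subj_means <- tapply(y, subj, mean)
  subj_grp <- tapply(grp, subj, function(g) g[1])
  ss_conc <- b * n * sum((grp_mean - grand)^2)
  ss_subj <- b * sum((subj_means - grp_mean[as.character(subj_grp)])^2)
  ss_phase <- a * n * sum((ph_mean - grand)^2)
  ss_int <- n * sum((sweep(sweep(cell_mean, 1, grp_mean), 2, ph_mean) + grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_errw <- ss_tot - ss_conc - ss_subj - ss_phase - ss_int
  list(
    F_conc = (ss_conc / (a - 1)) / (ss_subj / (a * n - a)),
    F_phase = (ss_phase / (b - 1)) / (ss_errw / (a * n - a)),
    F_int = (ss_int / ((a - 1) * (b - 1))) / (ss_errw / (a * n - a))
  )
}

test_that("a 12-value integer fixture matches the textbook decomposition", {
  fixture <- tibble::tibble(
    larva_id = rep(c("a", "b", "c", "d", "e", "f"), each = 2),
    conc_uM = rep(c(0, 0, 0, 10, 10, 10), each = 2),
    phase = rep(c("light", "dark"), times = 6),
    distance = c(3, 9, 4, 8, 5, 10, 2, 5, 1, 6, 3, 4)
  )
  fit <- rm_anova(fixture)
  oracle <- textbook_mixed_anova(fixture)
  tab <- tidy(fit)
  expect_equal(tab$statistic[tab$term == "conc"], oracle$F_conc,
               tolerance = 1e-9)
  expect_equal(tab$statistic[tab$term == "phase"], oracle$F_phase,
               tolerance = 1e-9)
  expect_equal(tab$statistic[tab$term == "conc:phase"], oracle$F_int,
               tolerance = 1e-9)
})

test_that("rm_anova agrees with aov's Error-stratum decomposition", {
  withr::local_seed(401)
  for (i in 1:50) {
    tb <- phase_means_table(n_per_group = sample(4:10, 1),
                            group_shift = rnorm(4, 0, 0.3))
    fit <- rm_anova(tb)
    a <- summary(stats::aov(distance ~ factor(conc_uM) * phase + Error(larva_id),
                            data = tb))
    F_between <- a[["Error: larva_id"]][[1]]$`F value`[1]
    F_within <- a[["Error: Within"]][[1]]$`F value`[1:2]
    tab <- tidy(fit)
    expect_equal(tab$statistic[tab$term == "conc"], F_between,
                 tolerance = 1e-6)
    expect_equal(tab$statistic[tab$term == "phase"], F_within[1],
                 tolerance = 1e-6)
    expect_equal(tab$statistic[tab$term == "conc:phase"], F_within[2],
                 tolerance = 1e-6)
  }
})

test_that("null simulations reject at close to the nominal 5% rate", {
  withr::local_seed(402)
  rejections <- replicate(500, {
    tb <- phase_means_table(n_per_group = 24, conc = c(0, 1, 10, 100))
    glance(rm_anova(tb))$p_conc <= 0.05
  })
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("a pure phase contrast shows a phase effect but no group effect", {
  withr::local_seed(403)
  hits <- replicate(20, {
    tb <- phase_means_table(n_per_group = 16, light_mu = 3, dark_mu = 8)
    g <- glance(rm_anova(tb))
    c(phase = g$p_phase <= 0.05, conc = g$p_conc <= 0.05)
  })
  expect_gt(mean(hits["phase", ]), 0.9)
  expect_lt(mean(hits["conc", ]), 0.5)
})

test_that("LSD flags a shifted group but not an identical one", {
  withr::local_seed(404)
  flagged <- replicate(20, {
    tb <- phase_means_table(n_per_group = 24, conc = c(0, 1, 10),
                            group_shift = c(0, 0, 2))
    fit <- rm_anova(tb)
    g <- glance(fit)
    if (!(g$p_conc <= 0.05 || g$p_interaction <= 0.05)) return(c(NA, NA))
    l <- fishers_lsd(fit)
    c(shifted = l$significant[l$conc_uM == 10],
      same = l$significant[l$conc_uM == 1])
  })
  flagged <- flagged[, !is.na(flagged[1, ]), drop = FALSE]
  expect_gt(mean(flagged["shifted", ]), 0.9)
  expect_lt(mean(flagged["same", ]), 0.3)
})

test_that("LSD refuses to run when the omnibus gate fails", {
  withr::local_seed(405)
  repeat {
    tb <- phase_means_table(n_per_group = 12)
    fit <- rm_anova(tb)
    g <- glance(fit)
    if (g$p_conc > 0.05 && g$p_interaction > 0.05) break
  }
  expect_error(fishers_lsd(fit), "gated")
})

test_that("each LSD p-value equals a pooled-variance t-test on subject means", {
  withr::local_seed(406)
  tb <- phase_means_table(n_per_group = 16, conc = c(0, 1, 10),
                          group_shift = c(0, 1, 2))
  fit <- rm_anova(tb)
  l <- fishers_lsd(fit)
  wide <- tidyr::pivot_wider(tb, id_cols = c("larva_id", "conc_uM"),
                             names_from = "phase", values_from = "distance")
  m <- (wide$light + wide$dark) / 2
  grp <- factor(wide$conc_uM)
  mse <- sum(tapply(m, grp, function(v) sum((v - mean(v))^2))) /
    (length(m) - nlevels(grp))
  df <- length(m) - nlevels(grp)
  for (lev in c("1", "10")) {
    diff <- mean(m[grp == lev]) - mean(m[grp == "0"])
    se <- sqrt(mse * (1 / sum(grp == lev) + 1 / sum(grp == "0")))
    p_manual <- 2 * pt(-abs(diff / se), df)
    expect_equal(l$p.value[l$conc_uM == as.numeric(lev)], p_manual,
                 tolerance = 1e-12)
  }
})

test_that("rm_anova rejects degenerate designs", {
  tb <- phase_means_table(n_per_group = 3, conc = c(0, 10))
  tb$distance <- 1 # zero variance everywhere
  expect_error(rm_anova(tb), "degenerate")
  one_group <- phase_means_table(n_per_group = 5, conc = 0)
  expect_error(rm_anova(one_group), "2 concentration groups")
  tiny <- phase_means_table(n_per_group = 2, conc = c(0, 10))
  expect_error(rm_anova(tiny), "3 larvae")
})
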