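obs_row <- function(alive = TRUE, hatched = TRUE, malformations = "",
                    severity = "none", conc_uM = 10, well = "A1",
                    plate_id = "p1") {
  tibble::tibble(plate_id = plate_id, well = well, conc_uM = conc_uM,
                 alive = alive, hatched = hatched,
                 malformations = malformations, severity = severity)
}

test_that("status classification follows the precedence order", {
  expect_equal(
    as.character(classify_status(
      obs_row(alive = FALSE, malformations = "spinal", severity = "severe")
    )$status),
    "dead"
  )
  expect_equal(
    as.character(classify_status(
      obs_row(hatched = FALSE)
    )$status),
    "not_hatched"
  )
  expect_equal(
    as.character(classify_status(
      obs_row(malformations = "spinal", severity = "mild")
    )$status),
    "abnormal"
  )
  expect_equal(
    as.character(classify_status(
      obs_row(malformations = "spinal;craniofacial", severity = "severe")
    )$status),
    "severely_abnormal"
  )
  expect_equal(as.character(classify_status(obs_row())$status), "normal")
})

test_that("classification is total on random observations and order-invariant", {
  withr::local_seed(501)
  mals <- malformation_levels()
  obs <- purrr::map_dfr(1:200, function(i) {
    k <- sample(0:3, 1)
    m <- paste(sample(mals, k), collapse = ";")
    obs_row(
      alive = runif(1) < 0.8, hatched = runif(1) < 0.8,
      malformations = m,
      severity = if (k == 0) "none" else sample(c("mild", "severe"), 1),
      conc_uM = sample(c(0, 1, 10), 1), well = paste0("W", i)
    )
  })
  cl <- classify_status(obs)
  expect_true(all(!is.na(cl$status)))
  t1 <- tally_status(cl)
  t2 <- tally_status(cl[sample(nrow(cl)), ])
  expect_equal(dplyr::arrange(t1, conc_uM, status),
               dplyr::arrange(t2, conc_uM, status))
  # inclusion implies a normal classification
  inc <- behavior_inclusion(obs)
  expect_true(all(as.character(cl$status[inc$include]) == "normal"))
})

test_that("worked 8-well plates reproduce the published tallies", {
  # 4 not hatched, 2 mildly abnormal, 1 severely abnormal, 1 normal
  omeprazole_like <- dplyr::bind_rows(
    purrr::map_dfr(1:4, ~ obs_row(hatched = FALSE, conc_uM = 100,
                                  well = paste0("A", .x))),
    purrr::map_dfr(5:6, ~ obs_row(malformations = "spinal", severity = "mild",
                                  conc_uM = 100, well = paste0("A", .x))),
    obs_row(malformations = "spinal", severity = "severe", conc_uM = 100,
            well = "A7"),
    obs_row(conc_uM = 100, well = "A8")
  )
  t <- tally_status(omeprazole_like)
  pct <- setNames(t$pct, as.character(t$status))
  expect_equal(pct[["not_hatched"]], 50.0)
  expect_equal(pct[["abnormal"]], 25.0)
  expect_equal(pct[["severely_abnormal"]], 12.5)
  expect_equal(pct[["normal"]], 12.5)
  expect_equal(sum(t$pct), 100, tolerance = 1e-9)

  all_dead <- purrr::map_dfr(1:28, ~ obs_row(alive = FALSE, conc_uM = 40,
                                             well = paste0("W", .x)))
  td <- tally_status(all_dead)
  expect_equal(td$pct[td$status == "dead"], 100)

  all_normal <- purrr::map_dfr(1:8, ~ obs_row(conc_uM = 1, well = paste0("W", .x)))
  tn <- tally_status(all_normal)
  expect_equal(tn$pct[tn$status == "normal"], 100)
})

test_that("plate QC fails only when controls are strictly worse than threshold", {
  mk_ctrl <- function(n_bad, n = 16) {
    dplyr::bind_rows(
      purrr::map_dfr(seq_len(n_bad),
                     ~ obs_row(malformations = "spinal", severity = "mild",
                               conc_uM = 0, well = paste0("B", .x))),
      purrr::map_dfr(seq_len(n - n_bad) + n_bad,
                     ~ obs_row(conc_uM = 0, well = paste0("B", .x)))
    )
  }
  expect_true(plate_qc(mk_ctrl(2))$pass)   # 12.5%
  expect_false(plate_qc(mk_ctrl(3))$pass)  # 18.75%
  # exactly at the threshold passes (failure requires strict exceedance)
  exactly <- mk_ctrl(3, n = 20) # 15.0%
  expect_true(plate_qc(exactly)$pass)
  expect_error(plate_qc(obs_row(conc_uM = 10)), "no vehicle")
})

test_that("behavior inclusion requires live, hatched, fully normal larvae", {
  expect_true(behavior_inclusion(obs_row())$include)
  expect_false(behavior_inclusion(
    obs_row(malformations = "swim_bladder_not_inflated", severity = "mild")
  )$include)
  expect_false(behavior_inclusion(obs_row(alive = FALSE))$include)
  expect_false(behavior_inclusion(obs_row(hatched = FALSE))$include)
})

test_that("the dilution series reproduces the plate concentrations", {
  s <- build_series(25, 8, 250)
  expect_equal(s$final_uM[1], 100)
  expect_equal(s$final_uM[8], 100 * 10^(-3.5))
  # the exact bottom value rounds to the conventional 0.03 at one
  # significant figure, 0.032 at two
  expect_equal(signif(s$final_uM[8], 1), 0.03)
  expect_equal(s$final_uM_display[8], 0.032)
  expect_equal(build_series(10, 1, 250)$final_uM, 40)
  ratios <- s$final_uM[-8] / s$final_uM[-1]
  expect_equal(ratios, rep(10^0.5, 7), tolerance = 1e-12)
  expect_error(build_series(-1), "> 0")
})

test_that("rinse residuals follow the retained-fraction power law", {
  expect_equal(rinse_residual(5, 0.5), 3.125)
  expect_equal(round(rinse_residual(5, 0.5)), 3)
  expect_equal(rinse_residual(0, 0.5), 100)
  expect_equal(rinse_residual(1, 0.5), 50)
})

test_that("observation validation catches inconsistent records", {
  expect_error(classify_status(obs_row(malformations = "fins")), "unknown")
  expect_error(classify_status(obs_row(severity = "mild")), "severity")
})
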