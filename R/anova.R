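#' Per-larva phase means from a binned profile table
#'
#' Collapses each larva's light and dark bins to the mean distance moved per
#' bin in each phase, the input of the traditional repeated-measures
#' analysis. Acclimation bins are dropped.
#'
#' @param bins Long-format bin tibble (see [compute_endpoints()]).
#' @return Tibble with columns `larva_id`, `conc_uM`, `phase`, `distance`
#'   (cm/bin), two rows per larva.
#' @export
phase_means <- function(bins) {
  validate_profile_bins(bins)
  bins %>%
    filter(.data$phase %in% c("light", "dark")) %>%
    group_by(.data$larva_id, .data$conc_uM, .data$phase) %>%
    summarise(distance = mean(.data$distance_cm), .groups = "drop")
}

validate_phase_means <- function(table) {
  need <- c("larva_id", "conc_uM", "phase", "distance")
  if (!all(need %in% names(table))) {
    abort(paste0("phase-means table needs columns: ", paste(need, collapse = ", ")))
  }
  counts <- table %>% dplyr::count(.data$larva_id)
  if (any(counts$n != 2)) {
    abort("each larva must have exactly two rows (one light, one dark)")
  }
  wide <- table %>%
    tidyr::pivot_wider(
      id_cols = c("larva_id", "conc_uM"),
      names_from = "phase", values_from = "distance"
    )
  if (!all(c("light", "dark") %in% names(wide)) ||
      anyNA(wide$light) || anyNA(wide$dark)) {
    abort("each larva needs one light and one dark phase mean")
  }
  wide
}

#' Repeated-measures ANOVA on phase means
#'
#' The traditional analysis: a mixed-design ANOVA of mean distance moved
#' with concentration as the between-subject factor and phase (light vs
#' dark) as the within-subject factor, each larva serving as its own
#' block. With only two within-subject levels no sphericity correction is
#' needed. The decomposition is computed explicitly from subject means (the
#' between stratum) and within-subject phase differences (the within
#' stratum); F statistics use the stratum-appropriate error terms.
#'
#' @param table Phase-means tibble from [phase_means()]: columns `larva_id`,
#'   `conc_uM`, `phase` (`"light"`/`"dark"`), `distance`.
#' @return A `zf_rm_anova` object. [tidy()] returns the ANOVA table
#'   (term, df, sumsq, meansq, statistic, p.value); [glance()] returns the
#'   three p-values in one row.
#' @export
rm_anova <- function(table) {
  wide <- validate_phase_means(table)
  grp <- factor(wide$conc_uM)
  a <- nlevels(grp)
  if (a < 2) abort("need >= 2 concentration groups")
  n_g <- table(grp)
  if (any(n_g < 3)) abort("need >= 3 larvae per concentration group")
  N <- nrow(wide)
  b <- 2 # phases

  m <- (wide$light + wide$dark) / 2 # subject means
  h <- (wide$dark - wide$light) / 2 # half phase differences

  # between-subject stratum (x b to stay on the per-observation scale)
  m_bar <- mean(m)
  m_g <- tapply(m, grp, mean)
  ss_conc <- b * sum(n_g * (m_g - m_bar)^2)
  ss_subj <- b * sum((m - m_g[grp])^2)
  df_conc <- a - 1
  df_subj <- N - a

  # within-subject stratum
  h_bar <- mean(h)
  h_g <- tapply(h, grp, mean)
  ss_phase <- b * N * h_bar^2
  ss_int <- b * sum(n_g * (h_g - h_bar)^2)
  ss_errw <- b * sum((h - h_g[grp])^2)
  df_phase <- b - 1
  df_int <- a - 1
  df_errw <- N - a

  if (ss_subj <= 1e-12 || ss_errw <= 1e-12) abort("degenerate data")

  ms <- function(ss, df) ss / df
  tab <- tibble(
    term = c("conc", "subjects(conc)", "phase", "conc:phase", "phase:subjects(conc)"),
    df = c(df_conc, df_subj, df_phase, df_int, df_errw),
    sumsq = c(ss_conc, ss_subj, ss_phase, ss_int, ss_errw),
    meansq = .data$sumsq / .data$df,
    statistic = c(
      ms(ss_conc, df_conc) / ms(ss_subj, df_subj), NA,
      ms(ss_phase, df_phase) / ms(ss_errw, df_errw),
      ms(ss_int, df_int) / ms(ss_errw, df_errw), NA
    ),
    p.value = ifelse(
      is.na(.data$statistic), NA,
      pf(.data$statistic, .data$df,
         c(df_subj, NA, df_errw, df_errw, NA), lower.tail = FALSE)
    )
  )
  structure(
    list(table = tab, wide = wide, grp = grp,
         mse_subject_means = ss_subj / b / df_subj, df_subj = df_subj),
    class = "zf_rm_anova"
  )
}

#' @export
print.zf_rm_anova <- function(x, ...) {
  cat("<zf_rm_anova> mixed-design ANOVA (phase within, concentration between)\n")
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}

#' @rdname rm_anova
#' @param x A `zf_rm_anova` object.
#' @param ... Unused.
#' @export
tidy.zf_rm_anova <- function(x, ...) x$table

#' @rdname rm_anova
#' @export
glance.zf_rm_anova <- function(x, ...) {
  p <- function(term) x$table$p.value[x$table$term == term]
  tibble(
    p_conc = p("conc"), p_phase = p("phase"), p_interaction = p("conc:phase")
  )
}

#' Fisher's LSD comparisons of each treatment with vehicle
#'
#' Gated post hoc: runs only when the omnibus ANOVA shows an overall
#' concentration effect or a concentration-by-phase interaction at
#' p <= 0.05; otherwise it refuses. Comparisons are unadjusted
#' pooled-variance t-tests of each treatment group against the vehicle on
#' each larva's total average activity (the mean over both phases), using
#' the ANOVA's between-subject error mean square and its degrees of
#' freedom.
#'
#' @param fit A [rm_anova()] object.
#' @param alpha Omnibus gate and significance level (default 0.05).
#' @return Tibble with one row per treatment: `conc_uM`, `diff` (treatment
#'   minus vehicle mean total activity), `statistic`, `df`, `p.value`,
#'   `significant`.
#' @export
fishers_lsd <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "zf_rm_anova"))
  g <- glance(fit)
  if (!(g$p_conc <= alpha || g$p_interaction <= alpha)) {
    abort("LSD gated by omnibus test (no concentration or interaction effect at alpha)")
  }
  wide <- fit$wide
  m <- (wide$light + wide$dark) / 2
  grp <- fit$grp
  if (!"0" %in% levels(grp)) abort("no vehicle group (conc_uM == 0) present")
  mse <- fit$mse_subject_means
  df <- fit$df_subj
  n_g <- table(grp)
  m_g <- tapply(m, grp, mean)
  treated <- setdiff(levels(grp), "0")
  purrr::map_dfr(treated, function(lev) {
    se <- sqrt(mse * (1 / n_g[[lev]] + 1 / n_g[["0"]]))
    tstat <- (m_g[[lev]] - m_g[["0"]]) / se
    pval <- 2 * pt(-abs(tstat), df)
    tibble(
      conc_uM = as.numeric(lev), diff = m_g[[lev]] - m_g[["0"]],
      statistic = tstat, df = df, p.value = pval,
      significant = pval <= alpha
    )
  })
}
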