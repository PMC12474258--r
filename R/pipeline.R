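#' Pipeline configuration
#'
#' Bundles the tunable analysis constants: the assay protocol, the response
#' cutoff and BMR multipliers (control-SD units), the hitcall activity
#' threshold, the bootstrap count for BMC bounds, the plate-QC threshold,
#' and the seed.
#'
#' @param protocol An [assay_protocol()].
#' @param cutoff_multiplier Response cutoff, control-SD units (default 1).
#' @param bmr_multiplier BMR, control-SD units (default 1.349).
#' @param hit_threshold Hitcall at or above which an endpoint is active
#'   (default 0.9).
#' @param n_boot Bootstrap refits per endpoint for BMC bounds.
#' @param qc_threshold Fraction of non-normal controls beyond which a plate
#'   fails QC (default 0.15).
#' @param alpha Significance level of the traditional analysis (default
#'   0.05).
#' @param seed Integer seed used for every stochastic step.
#' @return A `zf_pipeline_config` list.
#' @export
pipeline_config <- function(protocol = assay_protocol(),
                            cutoff_multiplier = 1, bmr_multiplier = 1.349,
                            hit_threshold = 0.9, n_boot = 200,
                            qc_threshold = 0.15, alpha = 0.05, seed = 1) {
  stopifnot(
    cutoff_multiplier > 0, bmr_multiplier > 0,
    hit_threshold >= 0, hit_threshold <= 1,
    n_boot >= 0, qc_threshold >= 0, qc_threshold < 1,
    alpha > 0, alpha < 1
  )
  structure(
    list(
      protocol = protocol, cutoff_multiplier = cutoff_multiplier,
      bmr_multiplier = bmr_multiplier, hit_threshold = hit_threshold,
      n_boot = n_boot, qc_threshold = qc_threshold, alpha = alpha,
      seed = as.integer(seed)
    ),
    class = "zf_pipeline_config"
  )
}

#' Run both analyses of the screen on one dataset
#'
#' The full pipeline: plate QC on the developmental observations (failed
#' plates are excluded with a logged reason), behavior-inclusion filtering,
#' endpoint extraction, vehicle-reference fitting (unless a frozen
#' reference is supplied), the 13-endpoint concentration-response screen
#' (hitcall + BMC per endpoint), and the parallel traditional analysis
#' (repeated-measures ANOVA with gated Fisher's LSD), plus the
#' developmental-toxicity status tallies.
#'
#' @param bins Long-format bin tibble (columns `plate_id`, `well`,
#'   `larva_id`, `chemical`, `conc_uM`, `bin_start_min`, `phase`,
#'   `distance_cm`), or a `zf_plate` from [simulate_plate()] (in which case
#'   `observations` is taken from it).
#' @param observations Observation tibble (see [classify_status()]) with
#'   `plate_id`, `well`, `conc_uM`; optional when `bins` is a `zf_plate`.
#' @param config A [pipeline_config()].
#' @param reference Optional frozen [fit_vehicle_reference()]; when `NULL`
#'   the reference is fit on this dataset's vehicle larvae.
#' @return A `zf_screen_run` list: `results` (13-endpoint table), `heatmap`,
#'   `anova` (tidy ANOVA table), `lsd` (comparisons, or `NULL` when gated
#'   off), `qc`, `tally`, `log` (character vector of per-decision lines),
#'   `reference`, `config_hash`, `seed`. Result tables carry `seed` and
#'   `config_hash` columns.
#' @export
run_screen <- function(bins, observations = NULL, config = pipeline_config(),
                       reference = NULL) {
  stopifnot(inherits(config, "zf_pipeline_config"))
  if (inherits(bins, "zf_plate")) {
    observations <- observations %||% bins$observations
    bins <- bins$bins
  }
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  cfg_hash <- rlang::hash(config)
  note("config hash %s, seed %d", cfg_hash, config$seed)

  qc <- NULL
  tally <- NULL
  if (!is.null(observations)) {
    observations <- classify_status(observations)
    qc <- plate_qc(observations, threshold = config$qc_threshold)
    for (p in qc$plate_id[!qc$pass]) {
      note("plate %s failed QC (>%g%% abnormal controls); excluded",
           p, 100 * config$qc_threshold)
    }
    keep <- qc$plate_id[qc$pass]
    if (!length(keep)) abort("all plates failed QC")
    if ("plate_id" %in% names(bins)) {
      bins <- bins %>% filter(.data$plate_id %in% keep)
    }
    observations <- observations %>% filter(.data$plate_id %in% keep)
    tally <- tally_status(observations)
  }
  if (nrow(bins) == 0) abort("no behavioral data after QC")

  endpoints <- compute_endpoints(bins)
  if (is.null(reference)) {
    reference <- fit_vehicle_reference(
      endpoints, cutoff_multiplier = config$cutoff_multiplier
    )
    note("vehicle reference fit on %d control larvae",
         reference$n_controls[1])
  } else {
    note("using frozen vehicle reference (n = %d controls)",
         reference$n_controls[1])
  }

  screen <- withr::with_seed(
    config$seed,
    screen_chemical(
      endpoints, reference,
      bmr_multiplier = config$bmr_multiplier, n_boot = config$n_boot,
      hit_threshold = config$hit_threshold
    )
  )
  for (i in seq_len(nrow(screen$results))) {
    r <- screen$results[i, ]
    if (is.na(r$bmc)) {
      note("endpoint %s: winner %s, hitcall %.3f, no BMC", r$endpoint,
           r$winner, r$hitcall)
    } else {
      note("endpoint %s: winner %s, hitcall %.3f, BMC %.3g uM", r$endpoint,
           r$winner, r$hitcall, r$bmc)
    }
  }

  pm <- phase_means(bins)
  anova_fit <- rm_anova(pm)
  g <- glance(anova_fit)
  lsd <- NULL
  if (isTRUE(g$p_conc <= config$alpha || g$p_interaction <= config$alpha)) {
    lsd <- fishers_lsd(anova_fit, alpha = config$alpha)
    note("omnibus significant (p_conc = %.3g); LSD run", g$p_conc)
  } else {
    note("omnibus not significant (p_conc = %.3g); LSD gated off", g$p_conc)
  }

  stamp <- function(tbl) {
    if (is.null(tbl)) return(NULL)
    tbl %>% mutate(seed = config$seed, config_hash = cfg_hash)
  }
  structure(
    list(
      results = stamp(screen$results),
      heatmap = stamp(screen_heatmap(screen)),
      screen = screen,
      anova = stamp(tidy(anova_fit)),
      anova_fit = anova_fit,
      lsd = stamp(lsd),
      qc = stamp(qc),
      tally = stamp(tally),
      reference = reference,
      log = log_lines,
      config = config,
      config_hash = cfg_hash,
      seed = config$seed
    ),
    class = "zf_screen_run"
  )
}

#' @export
print.zf_screen_run <- function(x, ...) {
  cat("<zf_screen_run>\n")
  print(x$screen)
  cat(sprintf("  ANOVA: p_conc = %.3g, p_phase = %.3g, p_interaction = %.3g\n",
              glance(x$anova_fit)$p_conc, glance(x$anova_fit)$p_phase,
              glance(x$anova_fit)$p_interaction))
  invisible(x)
}

#' Write the result bundle of a screen run to CSV files
#'
#' @param run A [run_screen()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen_run <- function(run, dir) {
  stopifnot(inherits(run, "zf_screen_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- function(tbl, name) {
    if (!is.null(tbl)) {
      readr::write_csv(tbl, file.path(dir, paste0(name, ".csv")))
    }
  }
  out(run$results, "results")
  out(run$heatmap, "heatmap")
  out(run$anova, "anova")
  out(run$lsd, "lsd")
  out(run$qc, "qc")
  out(run$tally, "tally")
  writeLines(run$log, file.path(dir, "run_log.txt"))
  write_vehicle_reference(run$reference, file.path(dir, "vehicle_reference.json"))
  invisible(dir)
}

#' Read a long-format bin table from CSV
#'
#' @param path CSV with columns `plate_id`, `well`, `larva_id`, `chemical`,
#'   `conc_uM`, `bin_start_min`, `phase`, `distance_cm`.
#' @return A bin tibble.
#' @export
read_bins_csv <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      plate_id = readr::col_character(), well = readr::col_character(),
      larva_id = readr::col_character(), chemical = readr::col_character(),
      conc_uM = readr::col_double(), bin_start_min = readr::col_double(),
      phase = readr::col_character(), distance_cm = readr::col_double()
    )
  )
}

#' Read a well-observation table from CSV
#'
#' @param path CSV with columns `plate_id`, `well`, `conc_uM`, `alive`,
#'   `hatched`, `malformations`, `severity` (and optionally `chemical`).
#' @return An observation tibble.
#' @export
read_observations_csv <- function(path) {
  obs <- readr::read_csv(path, col_types = readr::cols())
  obs$malformations <- as.character(obs$malformations %||% "")
  obs$malformations[is.na(obs$malformations)] <- ""
  obs
}
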