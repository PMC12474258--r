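#' Names of the thirteen behavioral endpoints
#'
#' @return Character vector of the 13 endpoint names, in canonical order:
#'   average speed in the light (`avgSL`), dark (`avgSD`) and both phases
#'   (`avgST`); first- and second-order habituation slopes per phase
#'   (`hbt1L`, `hbt1D`, `hbt2L`, `hbt2D`); max/min activity ratios (`RoAL`,
#'   `RoAD`); startle acceleration (`strtlA`), adjusted startle
#'   (`strtlAavg`), startle magnitude (`strtlF`); and the dark:light
#'   area-under-curve ratio (`AUC_r`).
#' @export
endpoint_names <- function() {
  c(
    "avgSL", "avgSD", "avgST",
    "hbt1L", "hbt1D", "hbt2L", "hbt2D",
    "RoAL", "RoAD",
    "strtlA", "strtlAavg", "strtlF",
    "AUC_r"
  )
}

# trapezoidal area under the curve over bin index 1..n
trapz_auc <- function(x) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] + x[-n]) / 2)
}

# the 13 endpoint formulas for one larva, given light-phase and dark-phase
# bin distances (acclimation excluded upstream)
endpoints_one <- function(l, d, eps = eps_den) {
  m <- length(l)
  n <- length(d)
  if (m < 3) abort("need at least 3 light-phase bins")
  if (n < 3) abort("need at least 3 dark-phase bins")
  if (anyNA(l) || anyNA(d)) abort("NaN/NA distance in profile")
  avgSL <- mean(l)
  avgSD <- mean(d)
  c(
    avgSL = avgSL,
    avgSD = avgSD,
    avgST = mean(c(l, d)),
    hbt1L = (l[m] - l[1]) / (m - 1),
    hbt1D = (d[n] - d[1]) / (n - 1),
    hbt2L = ((l[m] - l[2]) - (l[m - 1] - l[1])) / (m - 2),
    hbt2D = ((d[n] - d[2]) - (d[n - 1] - d[1])) / (n - 2),
    RoAL = max(l) / (min(l) + 1),
    RoAD = max(d) / (min(d) + 1),
    strtlA = d[1] - l[m],
    strtlAavg = d[1] - avgSL,
    strtlF = d[1] / max(l[m], eps),
    AUC_r = trapz_auc(d) / max(trapz_auc(l), eps)
  )
}

validate_profile_bins <- function(bins) {
  need <- c("bin_start_min", "phase", "distance_cm")
  missing <- setdiff(need, names(bins))
  if (length(missing)) {
    abort(paste0("bins table missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(bins$distance_cm)) || anyNA(bins$distance_cm)) {
    abort("all distances must be finite and non-missing")
  }
  if (any(bins$distance_cm < 0)) abort("distances must be >= 0")
  invisible(bins)
}

check_one_profile <- function(start_min, phase) {
  if (is.unsorted(start_min, strictly = TRUE)) {
    abort("bins must be strictly ordered by bin_start_min")
  }
  w <- diff(start_min)
  if (length(w) && max(w) - min(w) > 1e-9) {
    abort("bins must have constant width")
  }
  ph <- as.character(phase)
  idx <- match(ph, phase_levels)
  if (anyNA(idx)) abort("phase must be one of acclimation/light/dark")
  if (is.unsorted(idx)) {
    abort("phases must appear in the order acclimation -> light -> dark, each contiguous")
  }
  invisible(NULL)
}

#' Compute the thirteen behavioral endpoints per larva
#'
#' Reduces each larva's phase-labelled binned locomotor trace to the
#' 13-endpoint behavioral vector. With light bins \eqn{l_1..l_m} and dark
#' bins \eqn{d_1..d_n}: the average speeds are phase means; habituation 1 is
#' the first-to-last bin slope per bin index, \eqn{(l_m - l_1)/(m-1)};
#' habituation 2 is the difference between the second-to-last and
#' first-to-second-to-last slopes; the activity ratio is
#' \eqn{\max/( \min + 1)}; the startle endpoints compare the first dark bin
#' with the last light bin (difference, difference from the light mean, and
#' ratio); and `AUC_r` is the trapezoidal dark area under the curve over the
#' light one. Acclimation bins are excluded from every endpoint. Ratio
#' denominators that could vanish (`strtlF`, `AUC_r`) are floored at the
#' 0.02 cm tracking noise floor.
#'
#' @param bins Long-format tibble with one row per larva and 2-min bin:
#'   columns `bin_start_min`, `phase` (`"acclimation"`/`"light"`/`"dark"`),
#'   `distance_cm`, plus identifier columns (at least `larva_id`; any of
#'   `plate_id`, `well`, `chemical`, `conc_uM` are carried through).
#'
#' @return A tibble with one row per larva: the identifier columns followed
#'   by the 13 endpoint columns (see [endpoint_names()]).
#' @examples
#' prof <- tibble::tibble(
#'   larva_id = "a", conc_uM = 0,
#'   bin_start_min = seq(0, 14, by = 2),
#'   phase = rep(c("light", "dark"), each = 4),
#'   distance_cm = c(1, 2, 3, 4, 8, 6, 4, 2)
#' )
#' compute_endpoints(prof)
#' @export
compute_endpoints <- function(bins) {
  validate_profile_bins(bins)
  if (!"larva_id" %in% names(bins)) abort("bins table needs a larva_id column")
  id_cols <- intersect(
    c("plate_id", "well", "larva_id", "chemical", "conc_uM"),
    names(bins)
  )
  bins %>%
    group_by(across(all_of(id_cols))) %>%
    arrange(.data$bin_start_min, .by_group = TRUE) %>%
    summarise(
      ep = {
        check_one_profile(.data$bin_start_min, .data$phase)
        l <- .data$distance_cm[.data$phase == "light"]
        d <- .data$distance_cm[.data$phase == "dark"]
        if (length(l) < 3) abort("fewer than 3 bins in the light phase")
        if (length(d) < 3) abort("fewer than 3 bins in the dark phase")
        list(endpoints_one(l, d))
      },
      .groups = "drop"
    ) %>%
    tidyr::unnest_wider("ep")
}

#' Bin raw tracking displacements into a phase-labelled locomotor profile
#'
#' Sums per-sample displacements into fixed-width time bins, applying the
#' minimum distance-moved filter first: displacements below `min_move`
#' (default the 0.02 cm tracking noise floor) are zeroed before summation,
#' so sub-threshold jitter never accumulates. Bins are half-open
#' `[start, start + width)` and labelled with the protocol phase of their
#' start time.
#'
#' @param samples Tibble of tracked samples: columns `time_min` (minutes from
#'   recording start, monotone non-decreasing within each larva) and
#'   `dist_cm` (displacement since the previous sample, cm), plus optional
#'   identifier columns (`larva_id`, `plate_id`, `well`, `chemical`,
#'   `conc_uM`) which group the stream and are carried through.
#' @param bin_width Bin width in minutes (default 2).
#' @param min_move Minimum displacement (cm) counted as true locomotion;
#'   samples below it contribute zero. `0` disables the filter.
#' @param protocol A [assay_protocol()] object used to label phases.
#'
#' @return A tibble with one row per larva and bin: identifier columns,
#'   `bin_start_min`, `phase`, `distance_cm`.
#' @examples
#' s <- tibble::tibble(
#'   larva_id = "a",
#'   time_min = c(0.1, 0.5, 1.0, 1.5),
#'   dist_cm = c(0.01, 0.05, 0.01, 0.10)
#' )
#' bin_track(s, bin_width = 2, min_move = 0.02)
#' @export
bin_track <- function(samples, bin_width = 2, min_move = 0.02,
                      protocol = assay_protocol(bin_min = bin_width)) {
  if (is.null(samples) || nrow(samples) == 0) abort("no samples")
  stopifnot(min_move >= 0, bin_width > 0)
  need <- c("time_min", "dist_cm")
  if (!all(need %in% names(samples))) {
    abort("samples need time_min and dist_cm columns")
  }
  id_cols <- intersect(
    c("plate_id", "well", "larva_id", "chemical", "conc_uM"),
    names(samples)
  )
  samples %>%
    group_by(across(all_of(id_cols))) %>%
    summarise(
      binned = {
        if (is.unsorted(.data$time_min)) abort("timestamps must be monotone")
        d <- ifelse(.data$dist_cm < min_move, 0, .data$dist_cm)
        start <- floor(.data$time_min / bin_width) * bin_width
        list(tibble(
          bin_start_min = sort(unique(start)),
          distance_cm = as.numeric(tapply(d, start, sum))
        ))
      },
      .groups = "drop"
    ) %>%
    tidyr::unnest("binned") %>%
    mutate(phase = phase_at(protocol, .data$bin_start_min)) %>%
    select(all_of(id_cols), "bin_start_min", "phase", "distance_cm")
}
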