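#' Observed-status categories
#'
#' @return Character vector of the five mutually exclusive well statuses in
#'   precedence order: `dead`, `not_hatched`, `severely_abnormal`,
#'   `abnormal`, `normal`.
#' @export
status_levels <- function() {
  c("dead", "not_hatched", "severely_abnormal", "abnormal", "normal")
}

#' Malformation vocabulary
#'
#' @return Character vector of the recorded malformation categories:
#'   craniofacial, spinal, abdominal and thoracic malformations, an
#'   uninflated swim bladder, abnormal position in the water column, and
#'   pigmentation changes.
#' @export
malformation_levels <- function() {
  c("craniofacial", "spinal", "abdominal", "thoracic",
    "swim_bladder_not_inflated", "abnormal_water_column_position",
    "pigmentation_change")
}

parse_malformations <- function(x) {
  if (is.list(x)) return(lapply(x, function(m) m[nzchar(m)]))
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
         function(m) trimws(m[nzchar(trimws(m))]))
}

validate_observations <- function(obs) {
  need <- c("alive", "hatched", "malformations", "severity")
  if (!all(need %in% names(obs))) {
    abort(paste0("observation table needs columns: ", paste(need, collapse = ", ")))
  }
  mal <- parse_malformations(obs$malformations)
  bad <- unique(setdiff(unlist(mal), malformation_levels()))
  if (length(bad)) {
    abort(paste0("unknown malformation(s): ", paste(bad, collapse = ", ")))
  }
  if (!all(obs$severity %in% c("none", "mild", "severe"))) {
    abort("severity must be none, mild, or severe")
  }
  if (any(lengths(mal) == 0 & obs$severity != "none")) {
    abort("severity must be none when no malformations are recorded")
  }
  mal
}

#' Classify each well into a single observed status
#'
#' Collapses raw per-well observations (alive, hatched, malformation set,
#' observer severity call) into one of five mutually exclusive statuses with
#' precedence dead > not hatched > severely abnormal > abnormal > normal.
#' Morphology cannot be fully scored inside the chorion, so non-hatching
#' outranks the malformation calls.
#'
#' @param obs Observation tibble: columns `alive` (logical), `hatched`
#'   (logical), `malformations` (semicolon-separated string or list column
#'   drawn from [malformation_levels()]; empty for none), `severity`
#'   (`"none"`/`"mild"`/`"severe"`), plus any identifier columns.
#' @return `obs` with a `status` factor column (levels [status_levels()]).
#' @export
classify_status <- function(obs) {
  mal <- validate_observations(obs)
  has_mal <- lengths(mal) > 0
  status <- dplyr::case_when(
    !obs$alive ~ "dead",
    !obs$hatched ~ "not_hatched",
    obs$severity == "severe" ~ "severely_abnormal",
    has_mal ~ "abnormal",
    TRUE ~ "normal"
  )
  obs %>% mutate(status = factor(status, levels = status_levels()))
}

#' Tally observed statuses per concentration
#'
#' @param obs Observation tibble; classified with [classify_status()] first
#'   if no `status` column is present. Needs a `conc_uM` column.
#' @return Tibble with one row per concentration and status: `conc_uM`,
#'   `status`, `n`, `pct` (percentages sum to 100 within each
#'   concentration; report to one decimal for display).
#' @export
tally_status <- function(obs) {
  if (!"status" %in% names(obs)) obs <- classify_status(obs)
  if (!"conc_uM" %in% names(obs)) abort("need a conc_uM column")
  if (nrow(obs) == 0) abort("empty observation table")
  obs %>%
    mutate(status = factor(.data$status, levels = status_levels())) %>%
    dplyr::count(.data$conc_uM, .data$status, .drop = FALSE, name = "n") %>%
    group_by(.data$conc_uM) %>%
    mutate(pct = 100 * .data$n / sum(.data$n)) %>%
    ungroup()
}

#' Plate-level quality control on vehicle controls
#'
#' A plate fails when strictly more than the threshold share (default 15%)
#' of its vehicle-control wells deviate from normal in any way (dead, not
#' hatched, or malformed); failed plates are excluded from analysis.
#'
#' @param obs Classified observation tibble with `conc_uM` (0 marks vehicle
#'   controls) and optionally `plate_id`.
#' @param threshold Fraction of non-normal controls tolerated (default
#'   0.15); failure requires strictly exceeding it.
#' @return Tibble with one row per plate: `plate_id`, `n_control`,
#'   `frac_abnormal`, `pass`.
#' @export
plate_qc <- function(obs, threshold = 0.15) {
  if (!"status" %in% names(obs)) obs <- classify_status(obs)
  if (!"plate_id" %in% names(obs)) obs$plate_id <- "plate1"
  ctrl <- obs %>% filter(.data$conc_uM == 0)
  if (nrow(ctrl) == 0) abort("no vehicle-control wells")
  ctrl %>%
    group_by(.data$plate_id) %>%
    summarise(
      n_control = n(),
      frac_abnormal = mean(.data$status != "normal"),
      pass = .data$frac_abnormal <= threshold,
      .groups = "drop"
    )
}

#' Behavior-analysis inclusion filter
#'
#' Only live, hatched, morphologically normal larvae (which includes an
#' inflated swim bladder, since an uninflated one is recorded as a
#' malformation) enter the behavior analysis.
#'
#' @param obs Observation tibble (see [classify_status()]).
#' @return `obs` with a logical `include` column.
#' @export
behavior_inclusion <- function(obs) {
  mal <- validate_observations(obs)
  obs %>% mutate(include = .data$alive & .data$hatched & lengths(mal) == 0)
}

#' Semi-log dilution series arithmetic
#'
#' Builds the stock series (constant log10 step of 0.5 down from the top
#' stock) and the final in-well concentrations after plate dilution.
#'
#' @param top_mM Top stock concentration in mM (> 0).
#' @param n_points Number of points in the series (default 8).
#' @param dilution Plate dilution factor (default 250).
#' @return Tibble with `point`, `stock_mM`, `final_uM` (exact), and
#'   `final_uM_display` (2 significant figures).
#' @examples
#' build_series(25, 8, 250) # 100 uM top well, ~0.03 uM bottom
#' @export
build_series <- function(top_mM, n_points = 8, dilution = 250) {
  if (!is.numeric(top_mM) || top_mM <= 0) abort("top concentration must be > 0")
  stopifnot(n_points >= 1, dilution > 0)
  k <- seq_len(n_points) - 1
  stock <- top_mM * 10^(-0.5 * k)
  final <- stock * 1000 / dilution
  tibble(
    point = k + 1, stock_mM = stock, final_uM = final,
    final_uM_display = signif(final, 2)
  )
}

#' Residual concentration after serial rinses
#'
#' Each rinse replaces half the well volume (more generally retains
#' `retained` of the solution), so `rinses` consecutive rinses leave
#' `100 * retained^rinses` percent of the original concentration; five 50%
#' rinses leave 3.125%, i.e. approximately 3%.
#'
#' @param rinses Number of rinses (>= 0).
#' @param retained Fraction retained per rinse, in `[0, 1]` (default 0.5).
#' @return Percent of the original concentration remaining.
#' @examples
#' rinse_residual(5, 0.5)
#' @export
rinse_residual <- function(rinses, retained = 0.5) {
  stopifnot(rinses >= 0, retained >= 0, retained <= 1)
  100 * retained^rinses
}
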