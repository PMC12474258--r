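#' Fit the vehicle-control reference for all endpoints
#'
#' Fits, per endpoint, an optimized Box-Cox transformation
#' (see [fit_boxcox()]) on vehicle-control larvae, records the mean and SD of
#' the transformed controls, and sets the response cutoff. Standardized
#' responses are then
#' \eqn{r = (g(x) - center)/scale} with \eqn{g} the shifted Box-Cox
#' transform, so controls map to mean 0, SD 1, and a single cutoff (in
#' control-SD units) is comparable across all 13 endpoints.
#'
#' The reference is intended to be fit once on a designated vehicle pool
#' (historical or per-study) and then frozen; serialize it with
#' [write_vehicle_reference()].
#'
#' @param endpoints Endpoint tibble from [compute_endpoints()]. Rows with
#'   `conc_uM == 0` are the vehicle controls unless `controls` is given.
#' @param controls Optional logical vector marking control rows explicitly.
#' @param cutoff_multiplier Response cutoff in control-SD units (default 1).
#' @return A `vehicle_reference` object: a tibble with one row per endpoint
#'   and columns `endpoint`, `lambda`, `shift`, `center`, `scale`, `cutoff`,
#'   `n_controls`.
#' @export
fit_vehicle_reference <- function(endpoints, controls = NULL,
                                  cutoff_multiplier = 1) {
  if (cutoff_multiplier <= 0) abort("cutoff multiplier must be > 0")
  eps <- endpoint_names()
  missing <- setdiff(eps, names(endpoints))
  if (length(missing)) {
    abort(paste0("endpoint table missing: ", paste(missing, collapse = ", ")))
  }
  if (is.null(controls)) {
    if (!"conc_uM" %in% names(endpoints)) {
      abort("need a conc_uM column (or an explicit `controls` vector)")
    }
    controls <- endpoints$conc_uM == 0
  }
  ctrl <- endpoints[controls, , drop = FALSE]
  if (nrow(ctrl) < 20) abort("insufficient controls (need >= 20 larvae)")
  ref <- purrr::map_dfr(eps, function(e) {
    x <- ctrl[[e]]
    bc <- fit_boxcox(x)
    y <- boxcox_transform(x, bc$lambda, bc$shift)
    tibble(
      endpoint = e,
      lambda = bc$lambda,
      shift = bc$shift,
      center = mean(y),
      scale = sd(y),
      cutoff = cutoff_multiplier,
      n_controls = length(x)
    )
  })
  if (any(ref$scale <= 0)) abort("degenerate control distribution (zero scale)")
  structure(ref, class = c("vehicle_reference", class(ref)))
}

#' Set the response cutoff of a fitted reference
#'
#' Because responses are standardized to control SD 1, the cutoff in
#' standardized units simply equals the multiplier. The default multiplier 1
#' places the cutoff at one control SD; 1.349 matches the conventional
#' continuous benchmark-response band.
#'
#' @param reference A [fit_vehicle_reference()] object.
#' @param multiplier Positive cutoff multiplier (control-SD units).
#' @return The reference with its `cutoff` column set to `multiplier`.
#' @export
estimate_cutoff <- function(reference, multiplier = 1) {
  stopifnot(inherits(reference, "vehicle_reference"))
  if (!is.numeric(multiplier) || length(multiplier) != 1 || multiplier <= 0) {
    abort("cutoff multiplier must be a single positive number")
  }
  reference$cutoff <- multiplier
  reference
}

#' Standardize endpoint values against the vehicle reference
#'
#' Applies, per endpoint, the frozen Box-Cox transform and centers/scales by
#' the control mean and SD, so vehicle controls map to approximately
#' N(0, 1). Treated values that fall at or below the transform's domain
#' (`x + shift <= 0`, possible when a treatment pushes an endpoint below the
#' control minimum) are floored at the positivity floor and flagged.
#'
#' @param endpoints Endpoint tibble from [compute_endpoints()].
#' @param reference A fitted [fit_vehicle_reference()].
#' @return A long tibble: identifier columns, `endpoint`, `value` (raw),
#'   `response` (standardized), `floored` (logical flag), `cutoff`.
#' @export
apply_reference <- function(endpoints, reference) {
  stopifnot(inherits(reference, "vehicle_reference"))
  id_cols <- intersect(
    c("plate_id", "well", "larva_id", "chemical", "conc_uM"),
    names(endpoints)
  )
  long <- endpoints %>%
    select(all_of(c(id_cols, endpoint_names()))) %>%
    tidyr::pivot_longer(all_of(endpoint_names()),
      names_to = "endpoint", values_to = "value"
    ) %>%
    left_join(as_tibble(reference), by = "endpoint")
  long %>%
    mutate(
      xs = .data$value + .data$shift,
      floored = .data$xs <= 0,
      xs = pmax(.data$xs, eps_pos),
      response = (purrr::pmap_dbl(
        list(.data$xs, .data$lambda),
        function(x, l) if (abs(l) < 1e-12) log(x) else (x^l - 1) / l
      ) - .data$center) / .data$scale
    ) %>%
    select(all_of(id_cols), "endpoint", "value", "response", "floored", "cutoff")
}

#' Serialize a vehicle reference to JSON
#'
#' @param reference A [fit_vehicle_reference()] object.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_vehicle_reference <- function(reference, path) {
  stopifnot(inherits(reference, "vehicle_reference"))
  jsonlite::write_json(
    list(
      format = "zfscreen/vehicle_reference",
      endpoints = as.data.frame(reference)
    ),
    path,
    digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' Read a vehicle reference from JSON
#'
#' @param path File written by [write_vehicle_reference()].
#' @return A `vehicle_reference` object.
#' @export
read_vehicle_reference <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- as_tibble(doc$endpoints)
  structure(ref, class = c("vehicle_reference", class(ref)))
}
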