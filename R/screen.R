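#' Screen one chemical across all thirteen endpoints
#'
#' Standardizes each larva's endpoint vector against the vehicle reference,
#' then fits the concentration-response suite, computes the continuous
#' hitcall, and estimates the BMC for every endpoint, producing the
#' chemical-by-endpoint activity table behind the screening heatmap.
#' Endpoints with fewer than two distinct nonzero concentration groups are
#' skipped with a message.
#'
#' @param endpoints Endpoint tibble from [compute_endpoints()] containing
#'   the treated larvae and (for standardization context) a `conc_uM`
#'   column; vehicle rows (`conc_uM == 0`) are included in the fits.
#' @param reference A fitted [fit_vehicle_reference()].
#' @param bmr_multiplier BMR in control-SD units (default 1.349).
#' @param n_boot Bootstrap refits per endpoint for the BMC bounds (default
#'   200 for routine screening; see [bmc()] for final-reporting bounds).
#' @param hit_threshold Hitcall activity threshold (default 0.9).
#' @param seed Optional seed for the bootstraps.
#' @return A `zf_screen` object with `$results` (one row per endpoint:
#'   hitcall, weights, active flag, BMC/BMDL/BMDU), `$fits` (named list of
#'   `zf_concresp`), and `$chemical`.
#' @export
screen_chemical <- function(endpoints, reference, bmr_multiplier = 1.349,
                            n_boot = 200, hit_threshold = 0.9, seed = NULL) {
  stopifnot(inherits(reference, "vehicle_reference"))
  responses <- apply_reference(endpoints, reference)
  chem <- unique(endpoints$chemical[endpoints$conc_uM > 0])
  chem <- if (length(chem)) chem[1] else NA_character_
  fits <- list()
  rows <- list()
  for (e in endpoint_names()) {
    d <- responses %>%
      filter(.data$endpoint == e) %>%
      select(conc = "conc_uM", resp = "response")
    cutoff_e <- reference$cutoff[reference$endpoint == e]
    if (length(unique(d$conc[d$conc > 0])) < 2) {
      inform(paste0("endpoint ", e, " skipped: < 2 nonzero concentration groups"))
      next
    }
    fit <- tryCatch(
      fit_concresp(d,
        cutoff = cutoff_e, bmr_multiplier = bmr_multiplier,
        n_boot = n_boot, hit_threshold = hit_threshold, seed = seed,
        endpoint = e
      ),
      error = function(err) {
        inform(paste0("endpoint ", e, " skipped: ", conditionMessage(err)))
        NULL
      }
    )
    if (is.null(fit)) next
    fits[[e]] <- fit
    rows[[e]] <- glance(fit)
  }
  if (!length(rows)) abort("no endpoint could be fit")
  results <- bind_rows(rows) %>% mutate(chemical = chem, .before = 1)
  structure(
    list(chemical = chem, results = results, fits = fits,
         reference = reference),
    class = "zf_screen"
  )
}

#' @export
print.zf_screen <- function(x, ...) {
  act <- x$results$endpoint[x$results$active]
  cat(sprintf(
    "<zf_screen> %s: %d/%d endpoints active%s\n",
    x$chemical, length(act), nrow(x$results),
    if (length(act)) paste0(" (", paste(act, collapse = ", "), ")") else ""
  ))
  invisible(x)
}

#' Chemical-by-endpoint activity matrix from one or more screens
#'
#' @param ... `zf_screen` objects (or a single list of them).
#' @return Tibble with one row per chemical-endpoint pair: `chemical`,
#'   `endpoint`, `hitcall`, `active`, `bmc`.
#' @export
screen_heatmap <- function(...) {
  screens <- list(...)
  if (length(screens) == 1 && !inherits(screens[[1]], "zf_screen")) {
    screens <- screens[[1]]
  }
  purrr::map_dfr(screens, function(s) {
    s$results %>% select("chemical", "endpoint", "hitcall", "active", "bmc")
  })
}

#' @export
tidy.zf_screen <- function(x, ...) x$results

#' @export
glance.zf_screen <- function(x, ...) {
  tibble(
    chemical = x$chemical,
    n_endpoints = nrow(x$results),
    n_active = sum(x$results$active),
    min_bmc = if (any(x$results$active & !is.na(x$results$bmc))) {
      min(x$results$bmc[x$results$active], na.rm = TRUE)
    } else NA_real_
  )
}
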