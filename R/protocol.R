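#' Assay protocol description
#'
#' The light-dark transition protocol: a dark acclimation period, an
#' illuminated phase, and an abrupt return to dark, with locomotor distance
#' summed into fixed-width time bins. The defaults are the standard
#' 20 min acclimation (12 lux) / 40 min light (3500 lux) / 40 min dark
#' (12 lux) design with 2-min bins, which yields 10 acclimation, 20 light and
#' 20 dark bins per larva.
#'
#' @param acclimation_min Minutes of dark acclimation before the light phase.
#' @param light_min Minutes of the illuminated phase.
#' @param dark_min Minutes of the final dark phase.
#' @param bin_min Bin width in minutes. Phase durations must be divisible by
#'   the bin width.
#' @param lux_light,lux_dark Illuminance metadata (lux); carried along for
#'   reporting only, never used in computation.
#'
#' @return An object of class `zf_protocol`: a list with the phase durations,
#'   bin width, per-phase bin counts and lux metadata.
#' @examples
#' assay_protocol()
#' @export
assay_protocol <- function(acclimation_min = 20, light_min = 40, dark_min = 40,
                           bin_min = 2, lux_light = 3500, lux_dark = 12) {
  stopifnot(acclimation_min >= 0, light_min > 0, dark_min > 0, bin_min > 0)
  for (dur in c(acclimation_min, light_min, dark_min)) {
    if (abs(dur / bin_min - round(dur / bin_min)) > 1e-9) {
      abort("phase durations must be divisible by the bin width")
    }
  }
  structure(
    list(
      acclimation_min = acclimation_min,
      light_min = light_min,
      dark_min = dark_min,
      bin_min = bin_min,
      n_acclimation = as.integer(round(acclimation_min / bin_min)),
      n_light = as.integer(round(light_min / bin_min)),
      n_dark = as.integer(round(dark_min / bin_min)),
      lux_light = lux_light,
      lux_dark = lux_dark
    ),
    class = "zf_protocol"
  )
}

#' @export
print.zf_protocol <- function(x, ...) {
  cat(sprintf(
    "<zf_protocol> %g min acclimation (%g lux) / %g min light (%g lux) / %g min dark (%g lux), %g-min bins\n",
    x$acclimation_min, x$lux_dark, x$light_min, x$lux_light, x$dark_min,
    x$lux_dark, x$bin_min
  ))
  invisible(x)
}

# phase label for a bin start time (minutes from recording start)
phase_at <- function(protocol, start_min) {
  dplyr::case_when(
    start_min < protocol$acclimation_min ~ "acclimation",
    start_min < protocol$acclimation_min + protocol$light_min ~ "light",
    TRUE ~ "dark"
  )
}

phase_levels <- c("acclimation", "light", "dark")

# tracking noise floor (cm): the minimum distance the video tracker registers
# as true locomotion; also used as the denominator floor for ratio endpoints.
eps_den <- 0.02

# positivity floor used by the shifted Box-Cox transform
eps_pos <- 1e-6
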