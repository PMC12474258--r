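#' Locomotor profile line plot
#'
#' Mean distance moved per 2-min bin by concentration group, with the phase
#' transitions marked — the standard way a light-dark transition experiment
#' is eyeballed.
#'
#' @param bins Long-format bin tibble.
#' @return A ggplot object.
#' @export
plot_locomotor_profile <- function(bins) {
  validate_profile_bins(bins)
  df <- bins %>%
    group_by(.data$conc_uM, .data$bin_start_min, .data$phase) %>%
    summarise(distance_cm = mean(.data$distance_cm), .groups = "drop") %>%
    mutate(group = factor(.data$conc_uM))
  trans <- df %>%
    group_by(.data$phase) %>%
    summarise(start = min(.data$bin_start_min), .groups = "drop") %>%
    filter(.data$phase != "acclimation")
  ggplot2::ggplot(df, ggplot2::aes(.data$bin_start_min, .data$distance_cm,
                                   colour = .data$group)) +
    ggplot2::geom_vline(xintercept = trans$start, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "Time (min)", y = "Distance moved (cm / 2 min)",
      colour = "Conc (µM)"
    ) +
    ggplot2::theme_minimal()
}

#' Concentration-response diagnostic plot
#'
#' The per-endpoint benchmark-concentration graph: individual standardized
#' responses, concentration-group means, the cutoff band around zero, the
#' benchmark response line, the winning fitted curve, and the BMC with its
#' bootstrap confidence band when available.
#'
#' @param object A [fit_concresp()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zf_concresp <- function(object, ...) {
  suite <- object$suite
  d <- suite$data
  winner <- suite_winner(suite)
  grid <- exp(seq(log(suite$ctx$cmin), log(suite$ctx$cmax), length.out = 200))
  curve <- tibble(conc = grid, resp = winner$predict(grid))
  means <- d %>%
    group_by(.data$cc) %>%
    summarise(resp = mean(.data$resp), .groups = "drop")
  bm <- object$bmc
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$cc, .data$resp)) +
    ggplot2::annotate("rect",
      xmin = -Inf, xmax = Inf, ymin = -object$cutoff, ymax = object$cutoff,
      alpha = 0.15, fill = "steelblue"
    ) +
    ggplot2::geom_hline(yintercept = c(-bm$bmr, bm$bmr), linetype = "dashed") +
    ggplot2::geom_point(size = 0.7, colour = "grey30") +
    ggplot2::geom_point(data = means, colour = "blue", size = 2.5) +
    ggplot2::geom_line(data = curve, ggplot2::aes(.data$conc, .data$resp)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Concentration (µM)", y = "Standardized response",
      title = if (is.na(object$endpoint)) NULL else object$endpoint,
      subtitle = sprintf("winner %s, hitcall %.2f%s", object$hit$winner,
                         object$hit$hitcall,
                         if (object$active) " (active)" else "")
    ) +
    ggplot2::theme_minimal()
  if (!is.na(bm$bmc)) {
    if (!is.na(bm$bmdl) && !is.na(bm$bmdu)) {
      p <- p + ggplot2::annotate("rect",
        xmin = bm$bmdl, xmax = bm$bmdu, ymin = -Inf, ymax = Inf,
        alpha = 0.15, fill = "red"
      )
    }
    p <- p + ggplot2::geom_vline(xintercept = bm$bmc, colour = "red",
                                 linetype = "dashed")
  }
  p
}

#' Screening heatmap
#'
#' Chemical-by-endpoint tiles shaded by hitcall, with active cells (hitcall
#' at or above the threshold) outlined.
#'
#' @param object A `zf_screen` object (or use [screen_heatmap()] output with
#'   [plot_screen_heatmap()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zf_screen <- function(object, ...) {
  plot_screen_heatmap(screen_heatmap(object))
}

#' @rdname autoplot.zf_screen
#' @param heatmap A [screen_heatmap()] tibble.
#' @export
plot_screen_heatmap <- function(heatmap) {
  heatmap <- heatmap %>%
    mutate(endpoint = factor(.data$endpoint, levels = endpoint_names()))
  ggplot2::ggplot(heatmap, ggplot2::aes(.data$endpoint, .data$chemical,
                                        fill = .data$hitcall)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::geom_tile(
      data = heatmap %>% filter(.data$active),
      fill = NA, colour = "black", linewidth = 0.8
    ) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "hitcall") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Developmental-toxicity status bar plot
#'
#' Stacked percent-affected bars per concentration, one bar segment per
#' observed status.
#'
#' @param tally A [tally_status()] tibble.
#' @return A ggplot object.
#' @export
plot_status_tally <- function(tally) {
  tally %>%
    mutate(conc = factor(.data$conc_uM)) %>%
    ggplot2::ggplot(ggplot2::aes(.data$conc, .data$pct, fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Concentration (µM)", y = "Percent of larvae",
                  fill = "Status") +
    ggplot2::theme_minimal()
}
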