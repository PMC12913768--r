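#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted IM trajectory
#'
#' Effective sizes and migration rate through time on log axes, with the
#' cumulative migration probability as a secondary panel-friendly column.
#'
#' @param object An `im_fit`.
#' @param scaling A [scaling_config()] (x axis in years).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.im_fit <- function(object, scaling = scaling_config(), ...) {
  tr <- object$trajectory
  long <- dplyr::bind_rows(
    tibble::tibble(time = tr$left * scaling$g, value = tr$im_N1,
                   series = "im_N1"),
    tibble::tibble(time = tr$left * scaling$g, value = tr$im_N2,
                   series = "im_N2"),
    tibble::tibble(time = tr$left * scaling$g,
                   value = pmax(tr$m, 1e-12), series = "m")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_step(ggplot2::aes(colour = .data$series)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~ .data$series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "years before present", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot percentile envelopes of trajectory collections
#'
#' @param object An `envelope_summary` from [envelope()].
#' @param what `"ne"` or `"m"`.
#' @param ... Unused.
#' @return A ggplot with median, inner (12.5-87.5%) and outer (2.5-97.5%)
#'   bands.
#' @export
autoplot.envelope_summary <- function(object, what = c("ne", "m"), ...) {
  what <- match.arg(what)
  cols <- paste0(what, c("_lo_outer", "_lo_inner", "_median",
                         "_hi_inner", "_hi_outer"))
  df <- tibble::tibble(
    time = object$time_years,
    lo_outer = object[[cols[1]]], lo_inner = object[[cols[2]]],
    median = object[[cols[3]]],
    hi_inner = object[[cols[4]]], hi_outer = object[[cols[5]]]
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo_outer,
                                      ymax = .data$hi_outer), alpha = 0.2) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo_inner,
                                      ymax = .data$hi_inner), alpha = 0.35) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "years before present",
                  y = if (what == "ne") "effective size" else
                    "migration rate (per generation)") +
    ggplot2::theme_minimal()
}

#' Plot observed and model coalescence-rate curves
#'
#' @param object A [rate_curves()] tibble.
#' @param ... Unused.
#' @return A ggplot of the three hazard curves on log axes.
#' @export
autoplot.rate_curves <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              dplyr::starts_with("lambda"),
                              names_to = "curve", values_to = "hazard")
  ggplot2::ggplot(long, ggplot2::aes(.data$left, .data$hazard,
                                     colour = .data$curve)) +
    ggplot2::geom_step(na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generations before present",
                  y = "coalescence hazard (per generation)") +
    ggplot2::theme_minimal()
}
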