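#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_point geom_errorbarh
#'   geom_hline geom_vline geom_abline labs scale_x_log10 theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Kaplan-Meier plot
#'
#' Step survivor curves per stratum with the log-rank p in the subtitle.
#'
#' @param object An `ai_km` object from [km_logrank()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ai_km <- function(object, ...) {
  ggplot(object$curves, aes(x = .data$time, y = .data$surv,
                            colour = .data$stratum)) +
    geom_step() +
    labs(x = "time (days)", y = "survival probability",
         colour = "stratum",
         subtitle = sprintf("log-rank p = %.3g", object$p_value)) +
    theme_minimal()
}

#' Forest plot of a meta-analysis
#'
#' Per-stratum hazard ratios with 95% intervals and the combined estimate.
#'
#' @param object An `ai_meta` object from [meta_fixed_effect()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ai_meta <- function(object, ...) {
  per <- dplyr::mutate(object$per_stratum,
                       conf_low = exp(.data$estimate - 1.96 * .data$se),
                       conf_high = exp(.data$estimate + 1.96 * .data$se))
  combined <- tibble::tibble(stratum = "combined", hr = object$hr,
                             conf_low = object$conf_low,
                             conf_high = object$conf_high)
  dat <- dplyr::bind_rows(per[, c("stratum", "hr", "conf_low", "conf_high")],
                          combined)
  dat$stratum <- factor(dat$stratum, levels = rev(dat$stratum))
  ggplot(dat, aes(x = .data$hr, y = .data$stratum)) +
    geom_point() +
    geom_errorbarh(aes(xmin = .data$conf_low, xmax = .data$conf_high),
                   height = 0.2) +
    geom_vline(xintercept = 1, linetype = "dashed") +
    scale_x_log10() +
    labs(x = "hazard ratio (log scale)", y = NULL,
         subtitle = sprintf("%s-effect HR %.2f [%.2f, %.2f]",
                            object$method, object$hr, object$conf_low,
                            object$conf_high)) +
    theme_minimal()
}

#' A/I ratio vs TIL score quadrant scatter
#'
#' Scatter of the A/I ratio against the TIL score with the median split
#' lines, optionally coloured by a per-sample label (e.g. response).
#'
#' @param outcome Tibble from [outcome_table()].
#' @param colour_by Optional column name used for point colour.
#' @return A ggplot.
#' @export
plot_quadrant <- function(outcome, colour_by = NULL) {
  p <- ggplot(outcome, aes(x = .data$til_score, y = .data$ai_ratio)) +
    geom_hline(yintercept = median(outcome$ai_ratio, na.rm = TRUE),
               linetype = "dashed") +
    geom_vline(xintercept = median(outcome$til_score, na.rm = TRUE),
               linetype = "dashed") +
    labs(x = "TIL score", y = "A/I ratio") +
    theme_minimal()
  if (is.null(colour_by)) p + geom_point()
  else p + geom_point(aes(colour = .data[[colour_by]]))
}

#' Adaptive vs innate score scatter with the diagonal
#'
#' Scatter of per-sample adaptive (A) against innate (I) scores with the
#' A = I diagonal; points below the diagonal have more innate than
#' adaptive signal (A/I ratio < 1).
#'
#' @param profile Tibble with `A` and `I` columns.
#' @param colour_by Optional column name used for point colour.
#' @return A ggplot.
#' @export
plot_diagonal <- function(profile, colour_by = NULL) {
  p <- ggplot(profile, aes(x = .data$I, y = .data$A)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    labs(x = "innate score I", y = "adaptive score A") +
    theme_minimal()
  if (is.null(colour_by)) p + geom_point()
  else p + geom_point(aes(colour = .data[[colour_by]]))
}
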