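#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Trace plots for a fitted MSTCAR model
#'
#' Draws MCMC traces, coloured by chain, for a set of scalar parameters
#' (by default `rho`, the variances, and the first intercept).
#'
#' @param object a [fit_mstcar()] result.
#' @param parameters character vector of term names as produced by
#'   [tidy.mstcar_fit()]; `NULL` picks a small default set.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mstcar_fit <- function(object, parameters = NULL, ...) {
  K <- dim(object$beta)[2]
  vals <- list("beta[1,1]" = object$beta[, 1, 1], rho = object$rho)
  for (k in seq_len(K)) vals[[paste0("tau2[", k, "]")]] <- object$tau2[, k]
  if (!is.null(parameters)) vals <- vals[names(vals) %in% parameters]
  df <- purrr::imap(vals, function(v, nm) {
    tibble::tibble(parameter = nm, chain = factor(object$chain),
                   value = v)
  })
  df <- dplyr::bind_rows(df)
  df <- dplyr::mutate(dplyr::group_by(df, .data$parameter, .data$chain),
                      draw = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$draw, y = .data$value,
                                   colour = .data$chain)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "stored draw", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot rate series with credible ribbons
#'
#' Time series of age-standardized rates (per 100,000) with 95% credible
#' ribbons for a selection of units; suppressed series are masked.
#'
#' @param summary rate-summary tibble ([summarize_rates()], optionally
#'   after [apply_suppression()]).
#' @param units unit ids to show (default: first 9).
#' @return a ggplot object.
#' @export
plot_rate_series <- function(summary, units = NULL) {
  summary <- mask_suppressed(summary)
  if (is.null(units)) units <- utils::head(unique(summary$unit_id), 9)
  df <- summary[summary$unit_id %in% units, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$rate_per_100k,
                                   colour = .data$group,
                                   fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~unit_id) +
    ggplot2::labs(y = "deaths per 100,000", x = NULL) +
    ggplot2::theme_minimal()
}

#' Distribution of county trends per interval
#'
#' Boxplot-style view of the unit-level annual percent change by group and
#' interval from a [interval_report()] result.
#'
#' @param object a `trend_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.trend_report <- function(object, ...) {
  ggplot2::ggplot(object$units,
                  ggplot2::aes(x = .data$interval, y = .data$apc,
                               fill = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "annual percent change (%)") +
    ggplot2::theme_minimal()
}
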