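#' Annual percent change by log-linear regression
#'
#' Ordinary least squares of `ln(rate)` on calendar year; the annual percent
#' change is `100 * (exp(slope) - 1)`. Both interval endpoints are included
#' in the regression.
#'
#' @param rates positive rates, one per year.
#' @param years calendar years (same length, at least 2 distinct).
#' @return the APC in percent per year.
#' @examples
#' loglinear_apc(100 * 0.98^(0:10), 2000:2010)  # exactly -2
#' @export
loglinear_apc <- function(rates, years = seq_along(rates)) {
  if (length(rates) != length(years) || length(rates) < 2)
    stop("need at least two (rate, year) pairs")
  if (any(rates <= 0)) stop("rates must be positive to take logs")
  x <- years - mean(years)
  slope <- sum(x * log(rates)) / sum(x^2)
  100 * (exp(slope) - 1)
}

# vectorized OLS slopes of log-rates on years: draws is S x T_interval
ols_slopes <- function(log_draws, years) {
  x <- years - mean(years)
  as.vector(log_draws %*% x) / sum(x^2)
}

#' Posterior trend for one unit's rate draws
#'
#' Applies the log-linear APC regression to every posterior draw's time
#' series over an interval and summarizes the resulting APC draws by their
#' median and 2.5/97.5 percentiles. Total percent change over the interval
#' is computed at the draw level, `100 * (exp(slope * (end - start)) - 1)`,
#' and then summarized, so its uncertainty is preserved.
#'
#' @param draws matrix `[S draws x T years]` of positive rates.
#' @param years calendar years labelling the columns.
#' @param interval `c(start_year, end_year)`, both inclusive; defaults to
#'   the full series.
#' @return one-row tibble: `apc, apc_lo, apc_hi, total_change,
#'   total_lo, total_hi, prob_increasing, increasing, n_years`.
#' @export
posterior_trend <- function(draws, years, interval = range(years)) {
  if (interval[2] <= interval[1]) stop("interval must span > 0 years")
  sel <- years >= interval[1] & years <= interval[2]
  if (sum(sel) < 2) stop("interval covers fewer than 2 observed years")
  yrs <- years[sel]
  sub <- draws[, sel, drop = FALSE]
  if (any(sub <= 0)) stop("rates must be positive to take logs")
  slopes <- ols_slopes(log(sub), yrs)
  apc_draws <- 100 * (exp(slopes) - 1)
  span <- interval[2] - interval[1]
  total_draws <- 100 * (exp(slopes * span) - 1)
  qa <- stats::quantile(apc_draws, c(0.5, 0.025, 0.975), names = FALSE)
  qt <- stats::quantile(total_draws, c(0.5, 0.025, 0.975), names = FALSE)
  tibble::tibble(
    apc = qa[1], apc_lo = qa[2], apc_hi = qa[3],
    total_change = qt[1], total_lo = qt[2], total_hi = qt[3],
    prob_increasing = mean(slopes > 0),
    increasing = qa[1] > 0,
    n_years = sum(sel)
  )
}

# normalize the `intervals` argument to a list of c(start, end)
as_intervals <- function(intervals) {
  if (is.numeric(intervals) && length(intervals) == 2)
    intervals <- list(intervals)
  lapply(intervals, function(iv) {
    iv <- as.numeric(iv)
    if (length(iv) != 2 || iv[2] <= iv[1])
      stop("each interval must be c(start, end) with end > start")
    iv
  })
}

interval_label <- function(iv) paste0(iv[1], "-", iv[2])

# (unit, group) pairs to drop, from an apply_suppression() summary
suppressed_pairs <- function(suppression) {
  if (is.null(suppression)) return(NULL)
  dplyr::distinct(suppression[suppression$suppressed, ],
                  .data$unit_id, .data$group)
}

#' Trend estimates for all units, margins and intervals
#'
#' Runs [posterior_trend()] for every unit and margin group of a
#' `rate_draws` object over each requested interval. Units suppressed in
#' `suppression` (see [apply_suppression()]) are omitted: no trend is
#' reported for a suppressed series.
#'
#' @param std a `rate_draws` object from [age_standardize()].
#' @param intervals list of `c(start, end)` year pairs (inclusive;
#'   adjacent intervals may share a boundary year).
#' @param suppression optional suppression summary tibble.
#' @return tibble with one row per (unit, group, interval):
#'   `unit_id, group, interval, start_year, end_year` plus the
#'   [posterior_trend()] columns.
#' @export
estimate_trends <- function(std, intervals = list(range(std$years)),
                            suppression = NULL) {
  stopifnot(inherits(std, "rate_draws"))
  intervals <- as_intervals(intervals)
  drop <- suppressed_pairs(suppression)
  out <- list()
  for (mg in names(std$draws)) {
    arr <- std$draws[[mg]]
    keep_units <- std$unit_ids
    if (!is.null(drop)) {
      keep_units <- setdiff(keep_units, drop$unit_id[drop$group == mg])
    }
    for (iv in intervals) {
      sel <- std$years >= iv[1] & std$years <= iv[2]
      if (sum(sel) < 2) stop("interval ", interval_label(iv),
                             " covers fewer than 2 observed years")
      for (u in keep_units) {
        i <- match(u, std$unit_ids)
        tr <- posterior_trend(arr[, i, ], std$years, iv)
        out[[length(out) + 1L]] <- tibble::tibble(
          unit_id = u, group = mg, interval = interval_label(iv),
          start_year = iv[1], end_year = iv[2], tr)
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Share of units with increasing rates
#'
#' The headline statistic "percent of counties with increasing death
#' rates", with posterior uncertainty: for each posterior draw, the
#' fraction of (unsuppressed) units whose interval slope is positive is
#' computed; the fractions are then summarized across draws by their median
#' and 2.5/97.5 percentiles.
#'
#' @inheritParams estimate_trends
#' @return tibble `group, interval, pct_increasing, pct_lo, pct_hi,
#'   n_units` (percent scale, 0-100).
#' @export
percent_increasing <- function(std, intervals = list(range(std$years)),
                               suppression = NULL) {
  stopifnot(inherits(std, "rate_draws"))
  intervals <- as_intervals(intervals)
  drop <- suppressed_pairs(suppression)
  out <- list()
  for (mg in names(std$draws)) {
    arr <- std$draws[[mg]]
    keep <- std$unit_ids
    if (!is.null(drop)) keep <- setdiff(keep, drop$unit_id[drop$group == mg])
    if (!length(keep)) stop("all units suppressed in margin ", mg)
    ki <- match(keep, std$unit_ids)
    for (iv in intervals) {
      sel <- std$years >= iv[1] & std$years <= iv[2]
      yrs <- std$years[sel]
      x <- yrs - mean(yrs)
      S <- dim(arr)[1]
      # slopes[s, u] for all kept units at once
      sl <- matrix(0, S, length(ki))
      for (j in seq_along(ki)) {
        sl[, j] <- (log(arr[, ki[j], sel, drop = TRUE]) %*% x) / sum(x^2)
      }
      frac <- rowMeans(sl > 0) * 100
      q <- stats::quantile(frac, c(0.5, 0.025, 0.975), names = FALSE)
      out[[length(out) + 1L]] <- tibble::tibble(
        group = mg, interval = interval_label(iv),
        pct_increasing = q[1], pct_lo = q[2], pct_hi = q[3],
        n_units = length(ki))
    }
  }
  dplyr::bind_rows(out)
}

#' Tidy trend report across units
#'
#' Assembles the per-unit trend table into a report: the unit-level rows
#' plus distributional summaries (median and quartiles across units of the
#' APC and total change, and the share of units classified increasing) per
#' (group, interval).
#'
#' @param trends tibble from [estimate_trends()].
#' @return list of class `trend_report` with elements `units` (the input)
#'   and `summary` (one row per group x interval).
#' @export
interval_report <- function(trends) {
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  summary <- dplyr::summarise(
    dplyr::group_by(trends, .data$group, .data$interval),
    n_units = dplyr::n(),
    apc_q25 = qs(.data$apc)[1],
    apc_median = qs(.data$apc)[2],
    apc_q75 = qs(.data$apc)[3],
    total_q25 = qs(.data$total_change)[1],
    total_median = qs(.data$total_change)[2],
    total_q75 = qs(.data$total_change)[3],
    pct_classified_increasing = 100 * mean(.data$increasing),
    .groups = "drop"
  )
  structure(list(units = trends, summary = summary),
            class = "trend_report")
}

#' @export
print.trend_report <- function(x, ...) {
  cat("<trend_report> ", nrow(x$units), " unit-level rows\n", sep = "")
  print(x$summary)
  invisible(x)
}
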