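#' The 2000 US standard population (standard million)
#'
#' Age distribution of the year-2000 US standard million in the published
#' age bands, used for direct age-standardization of death rates. Weights
#' are the band populations divided by the total.
#'
#' @return a tibble `age_band, population, weight`.
#' @export
us_standard_population_2000 <- function() {
  tb <- tibble::tibble(
    age_band = c("<1", "1-4", "5-14", "15-24", "25-34", "35-44",
                 "45-54", "55-64", "65-74", "75-84", "85+"),
    population = c(13818, 55317, 145565, 138646, 135573, 162613,
                   134834, 87247, 66037, 44842, 15508)
  )
  tb$weight <- tb$population / sum(tb$population)
  tb
}

#' Standard-population weights for a set of age bands
#'
#' Selects the requested bands from a standard-population table and
#' renormalizes their weights to sum to one, which is how a direct
#' standardization restricted to (say) ages 45 and older is weighted.
#'
#' @param age_bands character vector of band labels.
#' @param std standard-population tibble (`age_band`, `weight` or
#'   `population`); defaults to [us_standard_population_2000()].
#' @return named numeric weights summing to 1, in `age_bands` order.
#' @export
standard_weights <- function(age_bands, std = us_standard_population_2000()) {
  i <- match(age_bands, std$age_band)
  if (anyNA(i))
    stop("age band(s) not found in the standard population: ",
         paste(age_bands[is.na(i)], collapse = ", "))
  w <- if ("weight" %in% names(std)) std$weight[i] else std$population[i]
  w <- w / sum(w)
  stats::setNames(w, age_bands)
}

#' Direct age-standardization of posterior rate draws
#'
#' Collapses age-specific rate draws to age-standardized draws,
#' `rate = sum_a w_a * lambda_a`, within every margin defined by the
#' non-age columns of the group descriptor (e.g. gender). The operation is
#' linear and applied draw by draw, so any later aggregation or
#' summarization still averages over the full posterior. If `groups` has a
#' single row per margin the "standardization" is the identity.
#'
#' @param fit a [fit_mstcar()] result (with stored `lambda` draws), or a
#'   list with elements `lambda` (`[S, N, K, T]`), `group_labels`,
#'   `unit_ids`, `years`, `chain`.
#' @param std standard-population tibble; see [standard_weights()].
#' @param groups group descriptor tibble with columns `group`, `age_band`,
#'   and optionally margin columns (e.g. `gender`). Defaults to the tibble
#'   carried by the fit. Every modeled group label must appear once.
#' @param by character vector of margin columns; defaults to all columns of
#'   `groups` other than `group` and `age_band`.
#' @return object of class `rate_draws`: list with `draws` (named list of
#'   `[S, N, T]` arrays, one per margin label), `unit_ids`, `years`,
#'   `chain`, `members` (named list mapping margin label to its model
#'   groups), `weights` (the weights used).
#' @export
age_standardize <- function(fit, std = us_standard_population_2000(),
                            groups = NULL, by = NULL) {
  if (is.null(groups)) groups <- fit$groups
  if (is.null(groups) || !"group" %in% names(groups))
    stop("a group descriptor tibble with a `group` column is required")
  groups <- tibble::as_tibble(groups)
  labels <- fit$group_labels
  if (!setequal(groups$group, labels))
    stop("group descriptor does not match modeled groups; unmatched: ",
         paste(c(setdiff(labels, groups$group),
                 setdiff(groups$group, labels)), collapse = ", "))
  if (!"age_band" %in% names(groups)) groups$age_band <- groups$group
  if (is.null(by))
    by <- setdiff(names(groups), c("group", "age_band"))
  margin <- if (length(by)) {
    do.call(paste, c(groups[by], sep = "_"))
  } else rep("all", nrow(groups))
  groups$.margin <- margin

  if (is.null(fit$lambda)) stop("fit carries no rate draws (save_lambda)")
  d <- dim(fit$lambda)
  kidx <- stats::setNames(seq_along(labels), labels)
  draws <- list(); members <- list(); weights <- list()
  for (mg in unique(margin)) {
    rows <- groups[groups$.margin == mg, ]
    w <- standard_weights(rows$age_band, std)
    arr <- array(0, c(d[1], d[2], d[4]))
    for (j in seq_len(nrow(rows))) {
      arr <- arr + w[j] * fit$lambda[, , kidx[[rows$group[j]]], ]
    }
    draws[[mg]] <- arr
    members[[mg]] <- rows$group
    weights[[mg]] <- w
  }
  structure(list(draws = draws, unit_ids = fit$unit_ids,
                 years = fit$years, chain = fit$chain,
                 members = members, weights = weights),
            class = "rate_draws")
}

#' @export
print.rate_draws <- function(x, ...) {
  cat("<rate_draws> ", length(x$draws), " margin(s): ",
      paste(names(x$draws), collapse = ", "), "; ",
      dim(x$draws[[1]])[1], " draws x ", length(x$unit_ids), " units x ",
      length(x$years), " years\n", sep = "")
  invisible(x)
}

# percentile summary of one draw vector: median and 2.5/97.5 percentiles
# by linear interpolation (quantile type 7)
draw_summary <- function(v) {
  q <- stats::quantile(v, c(0.5, 0.025, 0.975), names = FALSE, type = 7)
  c(point = q[1], lo = q[2], hi = q[3])
}

#' Summarize rate draws into medians and credible intervals
#'
#' For every (unit, margin group, year) cell, reports the posterior median
#' and the equal-tailed 95% credible interval (2.5 and 97.5 percentiles,
#' linear-interpolation quantiles), scaled to deaths per 100,000
#' person-years.
#'
#' @param std a `rate_draws` object from [age_standardize()].
#' @param per scaling of reported rates (default 1e5 = per 100,000).
#' @return tibble `unit_id, group, year, rate_per_100k, ci_low, ci_high`.
#' @export
summarize_rates <- function(std, per = 1e5) {
  stopifnot(inherits(std, "rate_draws"))
  out <- list()
  for (mg in names(std$draws)) {
    arr <- std$draws[[mg]] * per
    if (!all(is.finite(arr))) stop("non-finite rate draws in margin ", mg)
    if (dim(arr)[1] < 2) stop("need at least 2 draws to summarize")
    d <- dim(arr)
    qs <- apply(arr, c(2, 3), draw_summary)  # 3 x N x T
    out[[mg]] <- tibble::tibble(
      unit_id = rep(std$unit_ids, times = d[3]),
      group = mg,
      year = rep(std$years, each = d[2]),
      rate_per_100k = as.vector(qs[1, , ]),
      ci_low = as.vector(qs[2, , ]),
      ci_high = as.vector(qs[3, , ])
    )
  }
  dplyr::bind_rows(out)
}

#' Apply reliability and small-population suppression
#'
#' Implements the two suppression rules for reported rates, at the
#' (unit, group) level over the whole study period so that the same set of
#' counties is retained in every year:
#'
#' 1. *Reliability*: every year's credible-interval width must be smaller
#'    than its point estimate (`ci_high - ci_low < point`);
#' 2. *Population*: the annual population must exceed 100 people in all
#'    years (a year with exactly 100 people triggers suppression).
#'
#' A (unit, group) series failing either rule in any year is suppressed for
#' the entire period.
#'
#' @param summary rate-summary tibble from [summarize_rates()].
#' @param populations mortality table (or any tibble with `unit_id, group,
#'   year, population`); group labels may be the modeled (age-specific)
#'   groups, in which case `groups` maps them onto the summary's margins
#'   and populations are summed within a margin.
#' @param groups optional group descriptor used to aggregate `populations`
#'   onto the summary's margin labels.
#' @return `summary` with logical columns `reliable` and `suppressed`
#'   added; all rows retained.
#' @export
apply_suppression <- function(summary, populations, groups = NULL) {
  pop <- tibble::as_tibble(populations)[c("unit_id", "group", "year",
                                          "population")]
  if (!is.null(groups) && !all(pop$group %in% summary$group)) {
    groups <- tibble::as_tibble(groups)
    by <- setdiff(names(groups), c("group", "age_band"))
    margin <- if (length(by)) do.call(paste, c(groups[by], sep = "_"))
              else rep("all", nrow(groups))
    map <- stats::setNames(margin, groups$group)
    pop$group <- unname(map[pop$group])
    pop <- dplyr::summarise(
      dplyr::group_by(pop, .data$unit_id, .data$group, .data$year),
      population = sum(.data$population), .groups = "drop")
  }
  missing_pop <- dplyr::anti_join(
    dplyr::distinct(summary, .data$unit_id, .data$group),
    dplyr::distinct(pop, .data$unit_id, .data$group),
    by = c("unit_id", "group"))
  if (nrow(missing_pop))
    stop("no population series for ", nrow(missing_pop),
         " (unit, group) pair(s), e.g. ", missing_pop$unit_id[1], "/",
         missing_pop$group[1])

  pop_min <- dplyr::summarise(dplyr::group_by(pop, .data$unit_id,
                                              .data$group),
                              min_pop = min(.data$population),
                              .groups = "drop")
  out <- dplyr::mutate(summary,
                       reliable_year = (.data$ci_high - .data$ci_low) <
                         .data$rate_per_100k)
  out <- dplyr::group_by(out, .data$unit_id, .data$group)
  out <- dplyr::mutate(out, reliable = all(.data$reliable_year))
  out <- dplyr::ungroup(out)
  out <- dplyr::left_join(out, pop_min, by = c("unit_id", "group"))
  out <- dplyr::mutate(out,
                       suppressed = !.data$reliable | .data$min_pop <= 100)
  dplyr::select(out, -"reliable_year", -"min_pop")
}

#' Mask suppressed rows for publication
#'
#' Sets the rate and interval columns of suppressed rows to `NA` while
#' keeping the rows (so the output shape is stable and the suppression is
#' visible).
#'
#' @param summary output of [apply_suppression()].
#' @return the same tibble with suppressed estimates blanked.
#' @export
mask_suppressed <- function(summary) {
  if (!"suppressed" %in% names(summary)) return(summary)
  for (col in intersect(c("rate_per_100k", "ci_low", "ci_high"),
                        names(summary))) {
    summary[[col]][summary$suppressed] <- NA_real_
  }
  summary
}
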