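#' Read a tidy mortality table
#'
#' Reads a delimited table with columns `unit_id, group, year, deaths,
#' population` (one row per county, demographic group and calendar year)
#' and validates it. Missing (unit, group, year) combinations are treated
#' as zero-population cells, with the number of filled cells reported in a
#' warning.
#'
#' @param path path to a CSV file.
#' @return a tibble with the five canonical columns, completed to the full
#'   unit x group x year cross.
#' @export
read_mortality_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_mortality_table(df)
}

#' Write a tidy mortality table
#' @param data mortality tibble.
#' @param path output CSV path.
#' @export
write_mortality_table <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Validate and complete a mortality table
#'
#' Checks the invariants of the canonical mortality table: required columns,
#' no duplicate (unit, group, year) rows, contiguous years, non-negative
#' counts, and no deaths in zero-population cells. Missing cells are filled
#' with `population = 0, deaths = 0` (with a warning giving the count).
#'
#' @param data data frame with columns `unit_id, group, year, deaths,
#'   population`.
#' @return completed tibble, sorted by (year, group, unit).
#' @export
validate_mortality_table <- function(data) {
  need <- c("unit_id", "group", "year", "deaths", "population")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("mortality table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  data <- tibble::as_tibble(data)[need]
  data$unit_id <- as.character(data$unit_id)
  data$group <- as.character(data$group)
  key <- paste(data$unit_id, data$group, data$year)
  if (anyDuplicated(key))
    stop("duplicate (unit_id, group, year) row(s): ",
         key[duplicated(key)][1])
  if (any(data$deaths < 0)) stop("negative death counts")
  if (any(data$population < 0)) stop("negative populations")
  bad <- data$deaths > 0 & data$population == 0
  if (any(bad))
    stop("deaths > 0 with population = 0 in ", sum(bad), " cell(s), e.g. ",
         key[bad][1])
  yrs <- sort(unique(data$year))
  if (length(yrs) > 1 && !all(diff(yrs) == 1))
    stop("years must be contiguous")
  full <- tidyr::expand_grid(
    unit_id = sort(unique(data$unit_id)),
    group = sort(unique(data$group)),
    year = yrs
  )
  out <- dplyr::left_join(full, data, by = c("unit_id", "group", "year"))
  n_missing <- sum(is.na(out$population))
  if (n_missing > 0) {
    warning(n_missing, " missing cell(s) filled with population = 0")
    out$population[is.na(out$population)] <- 0
    out$deaths[is.na(out$deaths)] <- 0L
  }
  dplyr::arrange(out, .data$year, .data$group, .data$unit_id)
}

# tidy table -> dense [N, K, T] arrays keyed to a unit/group/year ordering
mortality_arrays <- function(data, unit_ids = NULL, groups = NULL,
                             years = NULL) {
  data <- validate_mortality_table(data)
  if (is.null(unit_ids)) unit_ids <- sort(unique(data$unit_id))
  if (is.null(groups)) groups <- sort(unique(data$group))
  if (is.null(years)) years <- sort(unique(data$year))
  N <- length(unit_ids); K <- length(groups); T <- length(years)
  i <- match(data$unit_id, unit_ids)
  k <- match(data$group, groups)
  t <- match(data$year, years)
  if (anyNA(i)) stop("unit id(s) absent from the graph: ",
                     data$unit_id[is.na(i)][1])
  if (anyNA(k) || anyNA(t)) stop("group/year outside the declared sets")
  Y <- array(0L, c(N, K, T), dimnames = list(unit_ids, groups, years))
  n <- array(0, c(N, K, T), dimnames = list(unit_ids, groups, years))
  idx <- cbind(i, k, t)
  Y[idx] <- as.integer(data$deaths)
  n[idx] <- data$population
  list(Y = Y, n = n, unit_ids = unit_ids, groups = groups, years = years)
}

#' Run the full pipeline: simulate, fit, summarize, trends, report
#'
#' Config-driven driver tying the stages together. The config is a named
#' list (or path to a YAML file) with elements:
#'
#' * `scenario`: arguments to [make_scenario()] (or `data`/`adjacency`/
#'   `groups` paths to fit existing files instead of simulating),
#' * `control`: arguments to [mstcar_control()],
#' * `priors`: arguments to [mstcar_priors()],
#' * `intervals`: list of `c(start, end)` year pairs (defaults to the four
#'   decade-ish intervals),
#' * `seed`: root seed for every stage,
#' * `output_dir`: where CSV summaries and the JSON manifest are written.
#'
#' Every output carries the config hash, so a rerun with the same config
#' and seed reproduces it exactly.
#'
#' @param config named list or YAML path.
#' @return a list with `fit`, `rates` (suppressed rate summaries), `trends`,
#'   `report`, `percent_increasing`, and `manifest`, invisibly writing CSVs
#'   when `output_dir` is set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  cfg_hash <- rlang::hash(config)

  if (!is.null(config$data)) {
    data <- read_mortality_table(config$data)
    graph <- read_adjacency(config$adjacency)
    groups <- tibble::as_tibble(utils::read.csv(config$groups))
    truth <- NULL
  } else {
    scen_args <- config$scenario %||% list(preset = "tiny")
    scen_args$seed <- scen_args$seed %||% seed
    scen <- do.call(make_scenario, scen_args)
    data <- scen$data; graph <- scen$graph; groups <- scen$groups
    truth <- scen$truth
  }

  control <- do.call(mstcar_control,
                     c(config$control %||% list(),
                       if (is.null(config$control$seed)) list(seed = seed)))
  priors_args <- config$priors %||% list()
  fit <- fit_mstcar(data, graph, priors = priors_args, control = control)

  std <- age_standardize(fit, groups = groups)
  rates <- summarize_rates(std)
  rates <- apply_suppression(rates, data, groups = groups)

  years <- sort(unique(data$year))
  intervals <- config$intervals %||% default_intervals(years)
  trends <- estimate_trends(std, intervals = intervals,
                            suppression = rates)
  report <- interval_report(trends)
  pct <- percent_increasing(std, intervals = intervals,
                            suppression = rates)

  manifest <- list(config_hash = cfg_hash, seed = seed,
                   n_units = length(graph$unit_ids),
                   groups = groups$group, years = years,
                   control = unclass(control),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  out <- list(fit = fit, rates = rates, trends = trends, report = report,
              percent_increasing = pct, manifest = manifest, truth = truth)

  if (!is.null(config$output_dir)) {
    dir <- config$output_dir
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(mask_suppressed(rates), file.path(dir, "rates.csv"),
                     row.names = FALSE)
    utils::write.csv(trends, file.path(dir, "trends.csv"), row.names = FALSE)
    utils::write.csv(report$summary, file.path(dir, "report.csv"),
                     row.names = FALSE)
    utils::write.csv(pct, file.path(dir, "percent_increasing.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    saveRDS(fit, file.path(dir, "fit.rds"))
  }
  invisible(out)
}

# default trend intervals: the four decade-ish spans when the series covers
# 1979-2017, otherwise thirds of the observed span
default_intervals <- function(years) {
  if (min(years) <= 1979 && max(years) >= 2017) {
    list(c(1979, 1990), c(1990, 2000), c(2000, 2010), c(2010, 2017))
  } else {
    lo <- min(years); hi <- max(years)
    cuts <- unique(round(seq(lo, hi, length.out = min(4, hi - lo + 1))))
    purrr::map(seq_len(length(cuts) - 1), ~ c(cuts[.x], cuts[.x + 1]))
  }
}
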