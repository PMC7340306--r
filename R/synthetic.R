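#' Ground-truth parameters for the MSTCAR generative model
#'
#' Bundles the parameters of the generative law used by the simulator:
#' group-by-year log-rate intercepts `beta` (K x T), lognormal cell variances
#' `tau2` (length K), between-group covariance `G` (K x K, symmetric positive
#' definite), and the AR(1) coefficient `rho` in (0, 1).
#'
#' @param beta numeric matrix K x T of log-rate intercepts.
#' @param tau2 positive numeric vector, length K.
#' @param G K x K symmetric positive-definite matrix (between-group
#'   covariance of the spatiotemporal effects).
#' @param rho AR(1) coefficient, strictly inside (0, 1).
#' @return a list of class `true_parameters`.
#' @export
true_parameters <- function(beta, tau2, G, rho) {
  beta <- as.matrix(beta)
  K <- nrow(beta)
  tau2 <- rep_len(as.numeric(tau2), K)
  G <- as.matrix(G)
  if (!isTRUE(all.equal(G, t(G), tolerance = 1e-8)))
    stop("`G` must be symmetric")
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0) && any(G != 0))
    stop("`G` must be positive definite (or exactly zero)")
  if (nrow(G) != K) stop("dim(G) must match nrow(beta)")
  if (length(rho) != 1 || rho <= 0 || rho >= 1)
    stop("`rho` must lie strictly in (0, 1)")
  if (any(tau2 <= 0)) stop("`tau2` must be positive")
  structure(list(beta = beta, tau2 = tau2, G = G, rho = rho, K = K,
                 T = ncol(beta)),
            class = "true_parameters")
}

# Cholesky factor of the stationary AR(1) covariance (unit marginal variance):
# Sigma[t,s] = rho^|t-s|.
ar1_cov_chol <- function(rho, T) {
  if (T == 1) return(matrix(1, 1, 1))
  S <- rho^abs(outer(seq_len(T), seq_len(T), "-"))
  t(chol(S))
}

# Precision matrix of the same stationary AR(1) process (tridiagonal).
ar1_precision <- function(rho, T) {
  if (T == 1) return(matrix(1, 1, 1))
  d <- c(1, rep(1 + rho^2, T - 2), 1)
  P <- diag(d)
  for (t in seq_len(T - 1)) {
    P[t, t + 1] <- -rho
    P[t + 1, t] <- -rho
  }
  P / (1 - rho^2)
}

#' Simulate MSTCAR random effects
#'
#' Draws the spatiotemporal random-effect array Z (units x groups x years)
#' from the multivariate space-time CAR law: intrinsic CAR across the county
#' graph, stationary AR(1) with coefficient `rho` across years, and
#' cross-group covariance `G`. The intrinsic CAR is improper, so the draw is
#' taken on the constrained subspace via the spectral (generalized-inverse)
#' factorization of the CAR precision `Q`: only eigenvectors with positive
#' eigenvalue carry variance, which enforces a sum-to-zero constraint within
#' every connected component for every (group, year).
#'
#' @param graph a [county_graph()].
#' @param params a [true_parameters()] object (or a list with `G`, `rho`).
#' @param T number of years; defaults to `ncol(params$beta)`.
#' @return numeric array `[N, K, T]` with dimnames from the graph.
#' @export
simulate_mstcar_effects <- function(graph, params, T = params$T) {
  stopifnot(inherits(graph, "county_graph"))
  G <- as.matrix(params$G)
  rho <- params$rho
  K <- nrow(G)
  if (length(rho) != 1 || rho <= 0 || rho >= 1)
    stop("`rho` must lie strictly in (0, 1)")
  N <- length(graph$unit_ids)
  Z <- array(0, dim = c(N, K, T),
             dimnames = list(graph$unit_ids, NULL, NULL))
  if (all(G == 0)) return(Z)  # zero-variance limit
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("`G` must be positive definite")

  prec <- car_precision(graph)
  eQ <- eigen(as.matrix(prec$Q), symmetric = TRUE)
  pos <- eQ$values > max(eQ$values) * 1e-9
  lam <- eQ$values[pos]
  V <- eQ$vectors[, pos, drop = FALSE]

  LG <- t(chol(G))
  LP <- ar1_cov_chol(rho, T)
  # each retained spatial eigenvector carries a K x T matrix-normal
  # coefficient with covariance (1/lambda_s) * G (rows) and AR(1) (cols)
  for (s in seq_along(lam)) {
    E <- matrix(stats::rnorm(K * T), K, T)
    C <- (LG %*% E %*% t(LP)) / sqrt(lam[s])
    for (k in seq_len(K)) Z[, k, ] <- Z[, k, ] + outer(V[, s], C[k, ])
  }
  Z
}

#' Simulate mortality counts from the generative model
#'
#' Given effects `Z` and parameters, draws cell log-rates
#' `ln lambda ~ N(beta_kt + Z_ikt, tau_k^2)` and deaths
#' `Y ~ Poisson(n * lambda)`. Cells with zero population yield zero deaths.
#'
#' @param Z effect array `[N, K, T]` from [simulate_mstcar_effects()].
#' @param params a [true_parameters()] object.
#' @param n population array `[N, K, T]` of person-years (non-negative).
#' @return a list with `Y` (integer array), `n`, `log_lambda` (the realized
#'   true log-rates), all `[N, K, T]`.
#' @export
simulate_counts <- function(Z, params, n) {
  dZ <- dim(Z)
  if (!identical(dim(n), dZ)) stop("`n` and `Z` shapes must agree")
  if (any(n < 0)) stop("populations must be non-negative")
  N <- dZ[1]; K <- dZ[2]; T <- dZ[3]
  if (nrow(params$beta) != K || ncol(params$beta) != T)
    stop("`params$beta` must be K x T")
  beta_full <- aperm(array(params$beta, dim = c(K, T, N)), c(3, 1, 2))
  tau_full <- aperm(array(sqrt(params$tau2), dim = c(K, T, N)), c(3, 1, 2))
  log_lambda <- beta_full + Z + stats::rnorm(length(Z)) * tau_full
  Y <- array(0L, dim = dZ, dimnames = dimnames(Z))
  pos <- n > 0
  Y[pos] <- stats::rpois(sum(pos), n[pos] * exp(log_lambda[pos]))
  list(Y = Y, n = n, log_lambda = log_lambda)
}

#' Heavy-tailed county population scenario
#'
#' Draws per-unit base populations log-uniformly between `min_pop` and
#' `max_pop`, mimicking the heavy right skew of county populations, then
#' splits them across groups and perturbs them mildly over years. A fraction
#' `small_pop_fraction` of units is forced to have group populations at or
#' below 100 in at least one year, so that the reliability/suppression rules
#' have something to bite on.
#'
#' @param N,K,T dimensions (units, groups, years).
#' @param min_pop,max_pop bounds of the log-uniform base population.
#' @param small_pop_fraction proportion of units given populations near or
#'   below the 100-person reliability threshold.
#' @return population array `[N, K, T]`.
#' @export
population_scenario <- function(N, K, T, min_pop = 50, max_pop = 5e5,
                                small_pop_fraction = 0.1) {
  base <- exp(stats::runif(N, log(min_pop), log(max_pop)))
  n_small <- round(small_pop_fraction * N)
  if (small_pop_fraction > 0) n_small <- max(1L, n_small)
  if (n_small > 0) {
    small_units <- sample.int(N, n_small)
    base[small_units] <- stats::runif(n_small, 40, 100)
  }
  share <- matrix(stats::runif(N * K, 0.5, 1.5), N, K)
  share <- share / rowSums(share)
  n <- array(0, dim = c(N, K, T))
  for (t in seq_len(T)) {
    drift <- matrix(stats::runif(N * K, 0.9, 1.1), N, K)
    n[, , t] <- round(base * share * drift)
  }
  n
}

#' Scenario presets: simulated dataset plus ground truth
#'
#' Generates a self-contained synthetic mortality dataset from the MSTCAR
#' generative model with known parameters: a county graph, a tidy
#' mortality table, a group-descriptor table, and the true parameters and
#' effects. Presets:
#'
#' * `"tiny"`: 3 x 3 grid, K = 1, T = 4 — smoke tests.
#' * `"small"`: 10 x 10 grid, K = 2, T = 10 — parameter-recovery studies.
#' * `"national"`: 15 x 15 grid (225 units), K = 6 (2 genders x 3 ten-year age
#'   bands: 45-54, 55-64, 65-74), T = 39 (years 1979-2017) — the shape of a
#'   national county-level CHD mortality analysis.
#'
#' Every argument can be overridden; `preset = NULL` with explicit
#' dimensions gives a fully custom scenario.
#'
#' @param preset one of `"tiny"`, `"small"`, `"national"`, or `NULL`.
#' @param nrows,ncols grid dimensions (units N = nrows * ncols).
#' @param K,T number of groups and years.
#' @param beta K x T matrix of true log-rate intercepts; defaults to a
#'   group-specific level with a gentle national decline.
#' @param tau2,G,rho generative parameters (see [true_parameters()]).
#' @param years calendar labels, length T.
#' @param small_pop_fraction,min_pop,max_pop see [population_scenario()].
#' @param seed integer seed; the whole scenario is reproducible from it.
#' @return a list of class `mstcar_scenario`: `graph`, `data` (tibble
#'   `unit_id, group, year, deaths, population`), `groups` (tibble
#'   `group, gender, age_band`), `truth` (list: `params`, `Z`,
#'   `log_lambda`), `years`.
#' @examples
#' scen <- make_scenario("tiny", seed = 1)
#' dim_sum <- nrow(scen$data) # 9 units x 1 group x 4 years = 36 rows
#' @export
make_scenario <- function(preset = c("tiny", "small", "national"),
                          nrows = NULL, ncols = NULL, K = NULL, T = NULL,
                          beta = NULL, tau2 = NULL, G = NULL, rho = NULL,
                          years = NULL, small_pop_fraction = NULL,
                          min_pop = 50, max_pop = 5e5, seed = 1L) {
  defaults <- list(
    tiny  = list(nrows = 3, ncols = 3, K = 1, T = 4,
                 rho = 0.8, small_pop_fraction = 0.2),
    small = list(nrows = 10, ncols = 10, K = 2, T = 10,
                 rho = 0.8, small_pop_fraction = 0.1),
    national = list(nrows = 15, ncols = 15, K = 6, T = 39,
                 rho = 0.9, small_pop_fraction = 0.08)
  )
  if (!is.null(preset)) {
    preset <- match.arg(preset)
    d <- defaults[[preset]]
    if (is.null(nrows)) nrows <- d$nrows
    if (is.null(ncols)) ncols <- d$ncols
    if (is.null(K)) K <- d$K
    if (is.null(T)) T <- d$T
    if (is.null(rho)) rho <- d$rho
    if (is.null(small_pop_fraction)) small_pop_fraction <- d$small_pop_fraction
  }
  if (is.null(nrows) || is.null(ncols) || is.null(K) || is.null(T))
    stop("without a preset, `nrows`, `ncols`, `K` and `T` are required")
  if (is.null(rho)) rho <- 0.8
  if (is.null(small_pop_fraction)) small_pop_fraction <- 0.1
  if (is.null(years)) {
    years <- if (T == 39) 1979:2017 else seq_len(T) + 2000 - 1
  }
  if (length(years) != T) stop("`years` must have length T")

  groups <- scenario_groups(K)

  if (is.null(beta)) {
    # group-specific levels (older bands die faster) with a gentle decline
    # that flattens late in the period, echoing national CHD trends
    lev <- log(0.002) + 0.8 * (as.integer(factor(groups$age_band)) - 1) -
      0.2 * (groups$gender == "women")
    tgrid <- seq_len(T)
    slope <- -0.02 * pmin(tgrid - 1, max(1, round(0.8 * T)))
    beta <- outer(lev, rep(1, T)) + outer(rep(1, K), slope)
  }
  beta <- as.matrix(beta)
  if (nrow(beta) != K || ncol(beta) != T) stop("`beta` must be K x T")
  if (is.null(tau2)) tau2 <- rep(0.01, K)
  if (is.null(G)) {
    G <- matrix(0.5, K, K); diag(G) <- 1
    G <- 0.05 * G
  }
  params <- true_parameters(beta, tau2, G, rho)

  set.seed(seed %% .Machine$integer.max)
  graph <- grid_graph(nrows, ncols)
  Z <- simulate_mstcar_effects(graph, params, T)
  n <- population_scenario(nrows * ncols, K, T,
                           min_pop = min_pop, max_pop = max_pop,
                           small_pop_fraction = small_pop_fraction)
  dimnames(n) <- dimnames(Z)
  sim <- simulate_counts(Z, params, n)

  data <- arrays_to_table(sim$Y, sim$n, graph$unit_ids, groups$group, years)
  structure(
    list(graph = graph, data = data, groups = groups,
         truth = list(params = params, Z = Z, log_lambda = sim$log_lambda),
         years = years, seed = seed),
    class = "mstcar_scenario"
  )
}

# group descriptors: K = 1 ungendered single band; even K crossed
# gender x age bands; otherwise age bands only
scenario_groups <- function(K) {
  bands_all <- c("45-54", "55-64", "65-74", "75-84", "85+")
  if (K == 1) {
    tibble::tibble(group = "all", gender = "all", age_band = "45-54")
  } else if (K %% 2 == 0) {
    nb <- K / 2
    bands <- bands_all[seq_len(nb)]
    tibble::tibble(
      group = paste(rep(c("men", "women"), each = nb), rep(bands, 2),
                    sep = "_"),
      gender = rep(c("men", "women"), each = nb),
      age_band = rep(bands, 2)
    )
  } else {
    bands <- bands_all[seq_len(K)]
    tibble::tibble(group = paste0("all_", bands), gender = "all",
                   age_band = bands)
  }
}

arrays_to_table <- function(Y, n, unit_ids, group_labels, years) {
  d <- dim(Y)
  tibble::tibble(
    unit_id = rep(unit_ids, times = d[2] * d[3]),
    group = rep(rep(group_labels, each = d[1]), times = d[3]),
    year = rep(years, each = d[1] * d[2]),
    deaths = as.integer(Y),
    population = as.numeric(n)
  )
}

#' @export
print.mstcar_scenario <- function(x, ...) {
  d <- c(length(x$graph$unit_ids), nrow(x$groups), length(x$years))
  cat("<mstcar_scenario> ", d[1], " units x ", d[2], " groups x ", d[3],
      " years (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a scenario to disk
#'
#' Serializes a scenario in the same delimited formats the fitting stage
#' reads: mortality table (CSV), adjacency (neighbour list), group table
#' (CSV) and a ground-truth sidecar (JSON).
#'
#' @param scenario a [make_scenario()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(scenario$data, file.path(dir, "mortality.csv"),
                   row.names = FALSE)
  utils::write.csv(scenario$groups, file.path(dir, "groups.csv"),
                   row.names = FALSE)
  write_adjacency(scenario$graph, file.path(dir, "adjacency.txt"))
  truth <- list(
    beta = scenario$truth$params$beta,
    tau2 = scenario$truth$params$tau2,
    G = scenario$truth$params$G,
    rho = scenario$truth$params$rho,
    seed = scenario$seed,
    years = scenario$years
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
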