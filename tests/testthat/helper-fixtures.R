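# shared fixtures: small graphs and mortality tables built in code

path_graph3 <- function() {
  county_graph(data.frame(unit_id = c("A", "B"), neighbor_id = c("B", "C")))
}

# single unit, single group mortality table
one_unit_table <- function(Y, n, years = seq(2000, length.out = length(Y))) {
  tibble::tibble(unit_id = "u1", group = "g", year = years,
                 deaths = Y, population = n)
}

# 3x3 grid with constant populations and Poisson counts at a flat rate
grid_table <- function(rate = 0.01, n = 1e4, T = 3, seed = 1,
                       graph = grid_graph(3, 3)) {
  set.seed(seed)
  units <- graph$unit_ids
  tibble::tibble(
    unit_id = rep(units, T),
    group = "all",
    year = rep(seq(2000, length.out = T), each = length(units)),
    deaths = stats::rpois(length(units) * T, n * rate),
    population = n
  )
}

# rate_draws object built by hand (draws[[margin]] is [S, N, T])
fake_rate_draws <- function(draws, unit_ids = NULL, years = NULL) {
  d <- dim(draws[[1]])
  structure(list(
    draws = draws,
    unit_ids = unit_ids %||% paste0("u", seq_len(d[2])),
    years = years %||% seq(2000, length.out = d[3]),
    chain = rep(1L, d[1]),
    members = as.list(names(draws)),
    weights = NULL
  ), class = "rate_draws")
}

`%||%` <- rlang::`%||%`
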