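# unit tests of the sampler building blocks; distributional correctness of
# each Gibbs block is tested in test-acceptance.R

make_dat <- function(tab, graph) {
  mstcar:::mortality_arrays(tab, unit_ids = sort(graph$unit_ids))
}

test_that("initial state uses smoothed empirical log-rates", {
  tab <- one_unit_table(Y = 5L, n = 1000)
  dat <- make_dat(tab, county_graph(data.frame(), units = "u1"))
  pri <- mstcar:::resolve_priors(mstcar_priors(), 1L)
  st <- mstcar:::init_state(dat, pri)
  expect_equal(st$log_lambda[1, 1, 1], log(5.5 / 1001))
  expect_equal(st$beta[1, 1], log(5.5 / 1001))
  expect_true(all(st$Z == 0))

  # chains are overdispersed when jittered
  set.seed(1); a <- mstcar:::init_state(dat, pri, jitter = 0.05)
  set.seed(2); b <- mstcar:::init_state(dat, pri, jitter = 0.05)
  expect_false(identical(a$log_lambda, b$log_lambda))

  # a group with no population anywhere is unestimable
  tab0 <- dplyr::bind_rows(
    tab, tibble::tibble(unit_id = "u1", group = "dead", year = 2000,
                        deaths = 0L, population = 0))
  dat0 <- make_dat(tab0, county_graph(data.frame(), units = "u1"))
  expect_error(mstcar:::init_state(dat0, mstcar:::resolve_priors(mstcar_priors(), 2L)),
               "dead")
})

test_that("log-rate Metropolis: prior draws at n = 0, freeze at sd -> 0,
           and agreement with 1-D quadrature", {
  g <- county_graph(data.frame(), units = c("u1", "u2"))
  tab <- tibble::tibble(unit_id = c("u1", "u2"), group = "g", year = 2000,
                        deaths = c(3L, 0L), population = c(1000, 0))
  dat <- make_dat(tab, g)
  st <- list(log_lambda = array(c(-5, -5), c(2, 1, 1)),
             beta = matrix(-5.5, 1, 1), Z = array(0, c(2, 1, 1)),
             tau2 = 0.4, G = matrix(0.1, 1, 1), rho = 0.5)

  # near-zero proposal sd: every in-bounds proposal accepted, chain frozen
  set.seed(1)
  up <- mstcar:::update_log_lambda(st, dat, rep(1e-8, 2))
  expect_equal(up$accept, 1)
  expect_equal(up$state$log_lambda[1, 1, 1], -5, tolerance = 1e-6)

  # long-run moments: data cell matches quadrature of the full conditional,
  # no-data cell matches its prior normal
  set.seed(2)
  cur <- st
  draws <- matrix(NA_real_, 20000, 2)
  for (i in seq_len(nrow(draws))) {
    cur <- mstcar:::update_log_lambda(cur, dat, rep(0.5, 2))$state
    draws[i, ] <- cur$log_lambda[, 1, 1]
  }
  lgrid <- seq(-12, 0, length.out = 4001)
  lp <- 3 * lgrid - 1000 * exp(lgrid) +
    stats::dnorm(lgrid, -5.5, sqrt(0.4), log = TRUE)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  expect_equal(mean(draws[, 1]), sum(w * lgrid), tolerance = 0.01)
  expect_equal(mean(draws[, 2]), -5.5, tolerance = 0.02)
  expect_equal(stats::sd(draws[, 2]), sqrt(0.4), tolerance = 0.02)
})

test_that("intercept update matches conjugate algebra in limiting cases", {
  g <- county_graph(data.frame(), units = "u1")
  dat <- make_dat(one_unit_table(2L, 500), g)
  r <- 0.8  # residual log_lambda - Z
  st <- list(log_lambda = array(r, c(1, 1, 1)), beta = matrix(0, 1, 1),
             Z = array(0, c(1, 1, 1)), tau2 = 1, G = matrix(1), rho = 0.5)
  # N = 1, tau2 = 1, prior N(0, 100): posterior mean = 100 r / 101
  set.seed(3)
  draws <- replicate(10000, mstcar:::update_beta(st, mstcar_priors())$beta[1, 1])
  expect_equal(mean(draws), 100 * r / 101, tolerance = 0.05)
  expect_equal(stats::var(draws), 1 / (1 + 1 / 100), tolerance = 0.05)
  # flat-prior limit: posterior mean -> residual mean
  flat <- mstcar_priors(beta_prior_var = 1e12)
  draws2 <- replicate(10000, mstcar:::update_beta(st, flat)$beta[1, 1])
  expect_equal(mean(draws2), r, tolerance = 0.05)
})

test_that("variance update has the conjugate gamma shape and rate", {
  # zero residuals with a = b = 0.001: posterior rate equals the prior rate,
  # shape = a + NT/2; check via the exact moments of the precision draws
  g <- grid_graph(2, 5)
  tab <- grid_table(T = 1, graph = g, n = 100)
  dat <- make_dat(tab, g)
  st <- list(log_lambda = array(-4.6, c(10, 1, 1)),
             beta = matrix(-4.6, 1, 1), Z = array(0, c(10, 1, 1)),
             tau2 = 1, G = matrix(1), rho = 0.5)
  pri <- mstcar_priors(tau2_shape = 0.001, tau2_rate = 0.001)
  set.seed(4)
  prec <- replicate(5000, 1 / mstcar:::update_tau2(st, pri)$tau2)
  # N*T = 10 cells -> shape = 0.001 + 5, rate = 0.001
  expect_equal(mean(prec), 5.001 / 0.001, tolerance = 0.05 * 5001)
  expect_equal(stats::var(prec) / mean(prec)^2, 1 / 5.001, tolerance = 0.1)
})

test_that("spatial-effect sweep keeps the sum-to-zero constraint and the
           analytic two-unit conditional", {
  g2 <- county_graph(data.frame(a = "A", b = "B"))
  s2 <- mstcar:::mstcar_structure(g2)
  dat2 <- list(Y = array(c(2L, 3L), c(2, 1, 1)),
               n = array(c(500, 600), c(2, 1, 1)))
  st <- list(log_lambda = array(c(-5.2, -4.9), c(2, 1, 1)),
             beta = matrix(-5, 1, 1), Z = array(c(0.05, -0.12), c(2, 1, 1)),
             tau2 = 0.3, G = matrix(0.2, 1, 1), rho = 0.5)
  # first colour class (unit A) is drawn conditionally on B's old value:
  # precision 1/G + 1/tau2, mean the precision-weighted combination
  phi <- 1 / 0.2 + 1 / 0.3
  mu <- ((-0.12) / 0.2 + (st$log_lambda[1, 1, 1] - (-5)) / 0.3) / phi
  set.seed(5)
  draws <- replicate(10000,
    mstcar:::update_Z(st, dat2, s2, center = FALSE)$Z[1, 1, 1])
  expect_equal(mean(draws), mu, tolerance = 0.1)
  expect_equal(stats::var(draws), 1 / phi, tolerance = 0.1)

  # with centering, the constraint holds after every sweep
  Zc <- mstcar:::update_Z(st, dat2, s2, center = TRUE)$Z
  expect_equal(sum(Zc[, 1, 1]), 0, tolerance = 1e-12)
})

test_that("AR(1) coefficient update reduces to its prior when T = 1 and
           rejects proposals outside (0, 1)", {
  g <- grid_graph(2, 2)
  s <- mstcar:::mstcar_structure(g)
  pri <- mstcar:::resolve_priors(mstcar_priors(rho_a = 2, rho_b = 5), 1L)
  st <- list(Z = array(rnorm(4, 0, 0.1), c(4, 1, 1)), G = matrix(0.2),
             tau2 = 0.1, rho = 0.5)
  set.seed(6)
  rhos <- numeric(20000)
  cur <- st
  for (i in seq_along(rhos)) {
    cur <- mstcar:::update_rho(cur, s, pri, 0.3)$state
    rhos[i] <- cur$rho
  }
  expect_true(all(rhos > 0 & rhos < 1))
  # T = 1: the likelihood is flat in rho, so draws follow Beta(2, 5)
  expect_equal(mean(rhos), 2 / 7, tolerance = 0.02)
  expect_equal(stats::var(rhos), 2 * 5 / (49 * 8), tolerance = 0.1)
})

test_that("rho concentrates near the generating value for long series", {
  set.seed(3)
  g <- grid_graph(8, 8)
  p <- true_parameters(beta = matrix(-5, 1, 40), tau2 = 0.01,
                       G = matrix(0.3, 1, 1), rho = 0.9)
  Z <- simulate_mstcar_effects(g, p, 40)
  s <- mstcar:::mstcar_structure(g)
  pri <- mstcar:::resolve_priors(mstcar_priors(), 1L)
  cur <- list(Z = Z, G = matrix(0.3, 1, 1), tau2 = 0.01, rho = 0.5)
  rhos <- numeric(2000)
  for (i in seq_along(rhos)) {
    cur <- mstcar:::update_rho(cur, s, pri, 0.03)$state
    rhos[i] <- cur$rho
  }
  expect_equal(mean(rhos[1001:2000]), 0.9, tolerance = 0.02)
})

test_that("group covariance posterior mean recovers the generating G", {
  set.seed(11)
  g <- grid_graph(8, 8)
  Gtrue <- matrix(c(0.3, 0.12, 0.12, 0.2), 2)
  p <- true_parameters(beta = matrix(-5, 2, 30), tau2 = c(0.01, 0.01),
                       G = Gtrue, rho = 0.7)
  Z <- simulate_mstcar_effects(g, p, 30)
  s <- mstcar:::mstcar_structure(g)
  pri <- mstcar:::resolve_priors(mstcar_priors(), 2L)
  cur <- list(Z = Z, G = diag(2), tau2 = c(0.01, 0.01), rho = 0.7)
  Gs <- array(NA_real_, c(500, 2, 2))
  for (i in 1:500) {
    cur <- mstcar:::update_G(cur, s, pri)
    Gs[i, , ] <- cur$G
  }
  Gbar <- apply(Gs[101:500, , ], c(2, 3), mean)
  expect_equal(Gbar, Gtrue, tolerance = 0.1)
})

test_that("the sampler stores the documented number of draws and is
           bit-reproducible", {
  tab <- grid_table(T = 3)
  g <- grid_graph(3, 3)
  ctl <- mstcar_control(n_chains = 2, n_iter = 60, n_burnin = 30, thin = 3,
                        seed = 7)
  fit <- fit_mstcar(tab, g, control = ctl)
  expect_equal(length(fit$rho), 2 * floor((60 - 30) / 3))
  expect_equal(dim(fit$lambda), c(20, 9, 1, 3))
  expect_true(all(fit$lambda > 0))

  fit2 <- fit_mstcar(tab, g, control = ctl)
  expect_identical(fit$lambda, fit2$lambda)
  expect_identical(fit$rho, fit2$rho)
})

test_that("posterior summaries are invariant to unit relabelling order", {
  tab <- grid_table(T = 3)
  g <- grid_graph(3, 3)
  ctl <- mstcar_control(n_chains = 1, n_iter = 80, n_burnin = 40, thin = 1,
                        seed = 8)
  fit_a <- fit_mstcar(tab, g, control = ctl)

  # permute the rows of the table and the declared order of graph units
  set.seed(1)
  tab_p <- tab[sample.int(nrow(tab)), ]
  perm <- sample(g$unit_ids)
  edges <- do.call(rbind, lapply(perm, function(u) {
    nb <- g$neighbors[[u]]
    nb <- nb[nb > u]  # each undirected edge once
    if (length(nb)) data.frame(unit_id = u, neighbor_id = nb) else NULL
  }))
  g_p <- county_graph(edges, units = perm)
  fit_b <- fit_mstcar(tab_p, g_p, control = ctl)
  expect_identical(fit_a$unit_ids, fit_b$unit_ids)
  expect_identical(fit_a$lambda, fit_b$lambda)
})

test_that("convergence diagnostics flag separated chains and pass mixed ones", {
  # duplicated chains add no between-chain variance: the split statistic
  # equals the single-chain value and sits at 1 up to sampling noise
  set.seed(20)
  x <- rep(rnorm(50), 2)
  expect_equal(mstcar:::split_rhat(x, rep(1:2, each = 50)), 1,
               tolerance = 0.06)
  # shifted chains: large Rhat
  set.seed(21)
  y <- c(rnorm(50), rnorm(50) + 10)
  expect_gt(mstcar:::split_rhat(y, rep(1:2, each = 50)), 1.1)

  tab <- grid_table(T = 3)
  fit <- fit_mstcar(tab, grid_graph(3, 3),
                    control = mstcar_control(n_chains = 2, n_iter = 1500,
                                             n_burnin = 750, thin = 1,
                                             seed = 9))
  rep <- convergence_report(fit)
  expect_true(all(c("parameter", "rhat", "flagged") %in% names(rep)))
  expect_lt(mean(rep$flagged), 0.2)  # a well-mixed tiny model mostly passes

  fit1 <- fit_mstcar(tab, grid_graph(3, 3),
                     control = mstcar_control(n_chains = 1, n_iter = 100,
                                              n_burnin = 50, thin = 1,
                                              seed = 10))
  expect_warning(convergence_report(fit1), "single chain")
})

test_that("tidy and glance expose posterior summaries", {
  tab <- grid_table(T = 3)
  fit <- fit_mstcar(tab, grid_graph(3, 3),
                    control = mstcar_control(n_chains = 2, n_iter = 100,
                                             n_burnin = 50, thin = 1,
                                             seed = 11))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high", "rhat")
                  %in% names(td)))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_draws, 100L)
  expect_s3_class(autoplot(fit), "ggplot")
})
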