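# Internal machinery of the Metropolis-within-Gibbs sampler.
#
# Model:
#   Y_ikt ~ Poisson(n_ikt * lambda_ikt)
#   ln lambda_ikt ~ N(beta_kt + Z_ikt, tau_k^2)
#   beta_kt ~ N(0, beta_prior_var)
#   1/tau_k^2 ~ Gamma(a, b)
#   Z ~ MSTCAR: intrinsic CAR (precision Q) in space x AR(1) (coefficient
#       rho, stationary, unit marginal variance) in time x G across groups,
#       with per-component sum-to-zero constraints
#   G ~ Inverse-Wishart(iw_df, iw_scale),  rho ~ Beta(a_rho, b_rho)
#
# Layout conventions: state arrays are [N, K, T]; the N x (K*T) matricization
# matrix(Z, N, K*T) has group fastest within year, so the Kronecker prior
# precision on one county's (K*T)-vector is kron(P_AR1, solve(G)).

# precompute graph-derived quantities used every sweep
mstcar_structure <- function(graph) {
  units <- sort(graph$unit_ids)
  nbr <- graph$neighbors[units]
  m <- vapply(nbr, length, integer(1))
  comp <- graph_components(units, nbr)
  N <- length(units)
  idx <- stats::setNames(seq_len(N), units)
  from <- rep(seq_len(N), times = lengths(nbr))
  to <- unname(idx[unlist(nbr, use.names = FALSE)])
  W <- Matrix::sparseMatrix(i = from, j = to, x = 1, dims = c(N, N))
  Q <- Matrix::Diagonal(N, as.numeric(m)) - W
  if (length(from)) {
    ig <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
    ig <- igraph::simplify(igraph::add_vertices(
      ig, max(0, N - igraph::vcount(ig))))
    colors <- as.integer(igraph::greedy_vertex_coloring(ig))
  } else {
    colors <- rep(1L, N)
  }
  comp_idx <- split(seq_len(N), comp)
  color_groups <- lapply(split(seq_len(N), colors), function(ix) {
    split(ix, m[ix])
  })
  list(unit_ids = units, m = m, W = W, Q = Q, component = comp,
       comp_idx = comp_idx, n_comp = max(comp), colors = colors,
       color_groups = color_groups, N = N,
       rankQ = N - max(comp))
}

# expand a length-K vector across the [N, K, T] layout (as a plain vector)
expand_k <- function(x, N, T) rep(rep(x, each = N), times = T)
# expand a K x T matrix across the [N, K, T] layout
expand_kt <- function(x, N) rep(as.vector(x), each = N)

#' Initialize a sampler state
#'
#' Log-rates start at the smoothed empirical rates `ln((Y + 0.5)/(n + 1))`
#' where population is positive and at the group-year mean of those values
#' elsewhere; intercepts at the group-year mean log-rate; spatial effects at
#' zero; variance parameters at prior-plausible values. The `jitter`
#' argument overdisperses initial values across chains.
#'
#' @param dat list from `mortality_arrays()`.
#' @param priors resolved [mstcar_priors()].
#' @param jitter sd of the normal jitter added to initial log-rates and
#'   intercepts (0 = none).
#' @return a state list (`log_lambda`, `beta`, `Z`, `tau2`, `G`, `rho`).
#' @keywords internal
init_state <- function(dat, priors, jitter = 0) {
  Y <- dat$Y; n <- dat$n
  d <- dim(Y); N <- d[1]; K <- d[2]; T <- d[3]
  group_dead <- apply(n, 2, sum) == 0
  if (any(group_dead))
    stop("group(s) with zero population everywhere: ",
         paste(dat$groups[group_dead], collapse = ", "))
  ll <- array(NA_real_, d)
  pos <- n > 0
  ll[pos] <- log((Y[pos] + 0.5) / (n[pos] + 1))
  ktmean <- apply(ll, c(2, 3), mean, na.rm = TRUE)
  fill <- aperm(array(ktmean, c(K, T, N)), c(3, 1, 2))
  ll[!pos] <- fill[!pos]
  beta <- ktmean
  resid <- ll - fill
  tau2 <- pmax(apply(resid, 2, function(m) stats::var(as.vector(m))), 0.005)
  if (jitter > 0) {
    ll <- ll + stats::rnorm(length(ll), 0, jitter)
    beta <- beta + stats::rnorm(length(beta), 0, jitter)
    tau2 <- tau2 * exp(stats::rnorm(K, 0, jitter))
  }
  list(log_lambda = ll, beta = beta,
       Z = array(0, d), tau2 = tau2,
       G = diag(0.01, K), rho = 0.5)
}

# ---- block updates -------------------------------------------------------

# Random-walk Metropolis on each cell's log-rate. `scale` is the per-cell
# proposal sd (already including the adaptive per-group factor). Proposals
# outside [-30, 5] are rejected (the target is truncated to that range as a
# numerical floor); cells with n = 0 are drawn directly from the prior
# normal. Returns the state plus acceptance counts per group.
update_log_lambda <- function(state, dat, scale) {
  l <- state$log_lambda
  d <- dim(l); N <- d[1]; K <- d[2]; T <- d[3]
  mu <- expand_kt(state$beta, N) + as.vector(state$Z)
  tau2v <- expand_k(state$tau2, N, T)
  lv <- as.vector(l)
  Yv <- as.vector(dat$Y); nv <- as.vector(dat$n)
  pos <- nv > 0

  prop <- lv + stats::rnorm(length(lv)) * scale
  inb <- prop >= -30 & prop <= 5
  logr <- Yv * (prop - lv) - nv * (exp(prop) - exp(lv)) -
    ((prop - mu)^2 - (lv - mu)^2) / (2 * tau2v)
  acc <- pos & inb & (log(stats::runif(length(lv))) < logr)
  lv[acc] <- prop[acc]
  # prior-only cells: exact draw
  if (any(!pos)) {
    lv[!pos] <- mu[!pos] + stats::rnorm(sum(!pos)) * sqrt(tau2v[!pos])
  }
  karr <- rep(rep(seq_len(K), each = N), times = T)
  acc_k <- tapply(acc[pos], karr[pos], mean)
  state$log_lambda <- array(lv, d)
  list(state = state,
       accept = as.numeric(acc_k),
       n_clamped = sum(pos & !inb))
}

# Conjugate normal draw for each group-year intercept given the residuals
# ln lambda - Z: precision N/tau_k^2 + 1/beta_prior_var.
update_beta <- function(state, priors) {
  d <- dim(state$log_lambda); N <- d[1]
  rbar <- apply(state$log_lambda - state$Z, c(2, 3), mean)  # K x T
  prec <- N / state$tau2 + 1 / priors$beta_prior_var        # K
  post_mean <- (N * rbar / state$tau2) / prec
  post_sd <- 1 / sqrt(prec)
  state$beta <- post_mean + matrix(stats::rnorm(length(rbar)), nrow(rbar)) *
    post_sd
  state
}

# Conjugate gamma draw for each group's precision 1/tau_k^2 over all
# modeled cells (N*T per group; prior-only cells carry a ln lambda too).
update_tau2 <- function(state, priors) {
  d <- dim(state$log_lambda); N <- d[1]; K <- d[2]; T <- d[3]
  resid <- state$log_lambda - state$Z -
    aperm(array(state$beta, c(K, T, N)), c(3, 1, 2))
  ssq <- apply(resid^2, 2, sum)
  shape <- priors$tau2_shape + N * T / 2
  rate <- priors$tau2_rate + ssq / 2
  state$tau2 <- 1 / stats::rgamma(K, shape = shape, rate = rate)
  state
}

# Block Gibbs sweep for the spatial effects. Counties are grouped by graph
# color (mutually non-adjacent within a color, so they are conditionally
# independent given the rest) and, within a color, by neighbour count m,
# which indexes the shared conditional precision
#   Phi_m = m * kron(P(rho), G^-1) + I_T kron diag(1/tau^2).
# The linear term is kron(P, G^-1) (sum of neighbours) + residual/tau^2.
update_Z <- function(state, dat, struct, center = TRUE) {
  d <- dim(state$log_lambda); N <- d[1]; K <- d[2]; T <- d[3]
  KT <- K * T
  P <- ar1_precision(state$rho, T)
  Ginv <- chol2inv(chol(state$G))
  PG <- kronecker(P, Ginv)
  dlik <- rep(1 / state$tau2, times = T)

  chol_m <- list()
  for (m in unique(struct$m)) {
    Phi <- m * PG + diag(dlik, KT)
    chol_m[[as.character(m)]] <- chol(Phi)  # upper triangular
  }

  Zmat <- matrix(state$Z, N, KT)
  R <- matrix(state$log_lambda, N, KT) -
    matrix(expand_kt(state$beta, N), N, KT)
  Rd <- R * matrix(dlik, N, KT, byrow = TRUE)

  for (cg in struct$color_groups) {
    ix_all <- unlist(cg, use.names = FALSE)
    S <- as.matrix(struct$W[ix_all, , drop = FALSE] %*% Zmat)
    B <- S %*% PG + Rd[ix_all, , drop = FALSE]
    pos0 <- 0L
    for (mname in names(cg)) {
      ix <- cg[[mname]]
      rows <- pos0 + seq_along(ix); pos0 <- pos0 + length(ix)
      U <- chol_m[[mname]]
      b <- t(B[rows, , drop = FALSE])                      # KT x n
      mu <- backsolve(U, forwardsolve(t(U), b))
      draw <- mu + backsolve(U, matrix(stats::rnorm(KT * length(ix)),
                                       KT, length(ix)))
      Zmat[ix, ] <- t(draw)
    }
  }
  if (center) {
    for (ic in struct$comp_idx) {
      Zs <- Zmat[ic, , drop = FALSE]
      Zmat[ic, ] <- sweep(Zs, 2, colMeans(Zs))
    }
  }
  state$Z <- array(Zmat, d)
  state
}

# tridiagonal cross-products of the spatial quadratic form:
# M_diag[[t]] = Z_t' Q Z_t,  M_off[[t]] = Z_t' Q Z_{t+1}  (K x K each)
z_cross_products <- function(Z, struct) {
  d <- dim(Z); N <- d[1]; K <- d[2]; T <- d[3]
  Zmat <- matrix(Z, N, K * T)
  QZ <- as.matrix(struct$Q %*% Zmat)
  cols <- function(t) (t - 1) * K + seq_len(K)
  M_diag <- vector("list", T)
  M_off <- if (T > 1) vector("list", T - 1) else list()
  for (t in seq_len(T)) {
    M_diag[[t]] <- crossprod(Zmat[, cols(t), drop = FALSE],
                             QZ[, cols(t), drop = FALSE])
    if (t < T)
      M_off[[t]] <- crossprod(Zmat[, cols(t), drop = FALSE],
                              QZ[, cols(t + 1), drop = FALSE])
  }
  list(diag = M_diag, off = M_off)
}

# scale matrix of the G full conditional: S_Z = sum_tt' P_tt' Z_t' Q Z_t'
gibbs_scale_G <- function(cross, P, T) {
  K <- nrow(cross$diag[[1]])
  S <- matrix(0, K, K)
  for (t in seq_len(T)) S <- S + P[t, t] * cross$diag[[t]]
  for (t in seq_len(T - 1L)) {
    if (T == 1) break
    S <- S + P[t, t + 1] * (cross$off[[t]] + t(cross$off[[t]]))
  }
  (S + t(S)) / 2
}

# Conjugate inverse-Wishart draw for the between-group covariance. The
# effective replicate count of the Kronecker prior is T * rank(Q).
update_G <- function(state, struct, priors) {
  T <- dim(state$Z)[3]
  cross <- z_cross_products(state$Z, struct)
  P <- ar1_precision(state$rho, T)
  S_Z <- gibbs_scale_G(cross, P, T)
  df <- priors$iw_df + T * struct$rankQ
  scale <- priors$iw_scale + S_Z
  K <- nrow(scale)
  for (try in 1:3) {
    W <- stats::rWishart(1, df, chol2inv(chol(scale)))[, , 1]
    G <- try(chol2inv(chol(W)), silent = TRUE)
    if (!inherits(G, "try-error") && all(is.finite(G))) {
      state$G <- (G + t(G)) / 2
      return(state)
    }
    scale <- scale + diag(1e-8 * mean(diag(scale)), K)  # jitter retry
    warning("non-SPD Wishart draw; retrying with jitter")
  }
  stop("update_G failed: scale matrix numerically singular")
}

# log full-conditional density of rho (up to a constant): determinant term
# K * rank(Q) * (T-1)/2 * -log(1-rho^2), the quadratic form of Z, and the
# Beta(a, b) prior.
rho_log_target <- function(rho, cross, Ginv, struct, K, T, priors) {
  if (rho <= 0 || rho >= 1) return(-Inf)
  a_diag <- vapply(cross$diag, function(M) sum(Ginv * M), numeric(1))
  qf <- if (T == 1) {
    a_diag[1]
  } else {
    a_off <- vapply(cross$off, function(M) sum(Ginv * t(M)), numeric(1))
    (a_diag[1] + a_diag[T] + (1 + rho^2) * sum(a_diag[-c(1, T)]) -
       2 * rho * sum(a_off)) / (1 - rho^2)
  }
  ldet <- if (T == 1) 0 else -K * struct$rankQ * (T - 1) / 2 * log(1 - rho^2)
  ldet - qf / 2 +
    (priors$rho_a - 1) * log(rho) + (priors$rho_b - 1) * log(1 - rho)
}

# Random-walk Metropolis on rho in (0, 1); proposals outside the support
# are auto-rejected.
update_rho <- function(state, struct, priors, proposal_sd) {
  d <- dim(state$Z); K <- d[2]; T <- d[3]
  cross <- z_cross_products(state$Z, struct)
  Ginv <- chol2inv(chol(state$G))
  cur <- rho_log_target(state$rho, cross, Ginv, struct, K, T, priors)
  prop <- state$rho + stats::rnorm(1, 0, proposal_sd)
  new <- rho_log_target(prop, cross, Ginv, struct, K, T, priors)
  accept <- log(stats::runif(1)) < (new - cur)
  if (accept) state$rho <- prop
  list(state = state, accept = accept)
}

# ---- driver --------------------------------------------------------------

#' Fit the MSTCAR model by Metropolis-within-Gibbs MCMC
#'
#' Runs the sampler on a tidy mortality table over a county graph. Blocks
#' are updated in a fixed order (`log_lambda`, `beta`, `Z`, `tau2`, `G`,
#' `rho`); the log-rate block uses adaptive random-walk Metropolis (target
#' acceptance 0.44, adaptation frozen at the end of burn-in), all other
#' blocks are conjugate except `rho` (random-walk Metropolis on (0, 1)).
#' Chains run sequentially with seeds derived from `control$seed`, so the
#' run is reproducible bit-for-bit.
#'
#' @param data mortality table (`unit_id, group, year, deaths, population`)
#'   or the list returned by `mortality_arrays()`.
#' @param graph a [county_graph()] covering the table's unit ids.
#' @param priors a [mstcar_priors()] object or a list of arguments to it.
#' @param control a [mstcar_control()] object or a list of arguments to it.
#' @param groups optional group-descriptor tibble (columns `group`,
#'   `age_band`, margins such as `gender`), carried along for
#'   standardization.
#' @param init optional named list overriding parts of the initial state
#'   (`log_lambda`, `beta`, `Z`, `tau2`, `G`, `rho`); mainly used to pin
#'   the value of blocks excluded from `control$update`.
#' @return an object of class `mstcar_fit`: thinned post-burn-in draws of
#'   the rates (`lambda`, array `[S, N, K, T]`), `beta` (`[S, K, T]`),
#'   `tau2` (`[S, K]`), `G` (`[S, K, K]`), `rho` (`[S]`), `chain` ids,
#'   acceptance rates, and metadata (`unit_ids`, `groups`, `years`).
#' @examples
#' scen <- make_scenario("tiny", seed = 1)
#' fit <- fit_mstcar(scen$data, scen$graph,
#'                   control = mstcar_control(n_chains = 2, n_iter = 200,
#'                                            n_burnin = 100, seed = 1))
#' dim(fit$lambda)
#' @export
fit_mstcar <- function(data, graph, priors = mstcar_priors(),
                       control = mstcar_control(), groups = NULL,
                       init = NULL) {
  if (!inherits(priors, "mstcar_priors")) priors <- do.call(mstcar_priors, priors)
  if (!inherits(control, "mstcar_control")) control <- do.call(mstcar_control, control)
  struct <- mstcar_structure(graph)
  if (is.data.frame(data)) {
    dat <- mortality_arrays(data, unit_ids = struct$unit_ids)
  } else {
    dat <- data
    if (!identical(sort(dat$unit_ids), struct$unit_ids))
      stop("data unit ids do not match the graph")
  }
  d <- dim(dat$Y); N <- d[1]; K <- d[2]; T <- d[3]
  priors <- resolve_priors(priors, K)

  n_keep <- (control$n_iter - control$n_burnin) %/% control$thin
  S_total <- control$n_chains * n_keep
  draws <- list(
    lambda = if (control$save_lambda)
      array(NA_real_, c(S_total, N, K, T)) else NULL,
    beta = array(NA_real_, c(S_total, K, T)),
    tau2 = matrix(NA_real_, S_total, K),
    G = array(NA_real_, c(S_total, K, K)),
    rho = numeric(S_total),
    chain = integer(S_total)
  )
  accept_lambda <- matrix(0, control$n_chains, K)
  accept_rho <- numeric(control$n_chains)
  n_clamped <- 0L
  do <- function(block) block %in% control$update

  s_out <- 0L
  for (chain in seq_len(control$n_chains)) {
    set.seed((control$seed * 97 + chain) %% .Machine$integer.max)
    state <- init_state(dat, priors,
                        jitter = if (control$n_chains > 1) 0.05 else 0)
    # explicit overrides (used chiefly to pin the blocks that are frozen
    # via control$update)
    for (nm in intersect(names(init),
                         c("log_lambda", "beta", "Z", "tau2", "G", "rho"))) {
      v <- init[[nm]]
      if (nm %in% c("log_lambda", "Z")) v <- array(v, dim = d)
      if (nm == "beta") v <- matrix(v, K, T)
      if (nm == "G") v <- matrix(v, K, K)
      if (nm == "tau2") v <- rep_len(v, K)
      state[[nm]] <- v
    }
    # per-cell proposal scale ~ conditional sd; adapted per-group factor
    base_scale <- 1 / sqrt(as.vector(dat$Y) + 1 / mean(state$tau2) + 0.5)
    log_fac <- rep(0, K)
    kfac <- function() expand_k(exp(log_fac), N, T) * control$proposal_sd *
      base_scale
    scale <- kfac()
    acc_win <- matrix(0, 0, K)
    acc_sum <- rep(0, K); acc_n <- 0L
    rho_acc <- 0L; rho_n <- 0L

    for (iter in seq_len(control$n_iter)) {
      if (do("log_lambda")) {
        up <- update_log_lambda(state, dat, scale)
        state <- up$state
        n_clamped <- n_clamped + up$n_clamped
        acc_sum <- acc_sum + up$accept; acc_n <- acc_n + 1L
        if (control$adapt && iter <= control$n_burnin &&
            iter %% 50 == 0) {
          log_fac <- log_fac + pmin(0.5, pmax(-0.5, acc_sum / acc_n - 0.44))
          scale <- kfac()
          if (iter < control$n_burnin) { acc_sum[] <- 0; acc_n <- 0L }
        }
      }
      if (do("beta")) state <- update_beta(state, priors)
      if (do("Z")) state <- update_Z(state, dat, struct,
                                     center = control$center_Z)
      if (do("tau2")) state <- update_tau2(state, priors)
      if (do("G")) state <- update_G(state, struct, priors)
      if (do("rho")) {
        up <- update_rho(state, struct, priors, control$rho_proposal_sd)
        state <- up$state
        rho_acc <- rho_acc + up$accept; rho_n <- rho_n + 1L
      }

      if (iter > control$n_burnin &&
          (iter - control$n_burnin) %% control$thin == 0) {
        s_out <- s_out + 1L
        if (!is.null(draws$lambda))
          draws$lambda[s_out, , , ] <- exp(state$log_lambda)
        draws$beta[s_out, , ] <- state$beta
        draws$tau2[s_out, ] <- state$tau2
        draws$G[s_out, , ] <- state$G
        draws$rho[s_out] <- state$rho
        draws$chain[s_out] <- chain
        if (!all(is.finite(state$beta)) || !all(is.finite(state$tau2)))
          stop("non-finite state at chain ", chain, " iteration ", iter)
      }
      if (control$verbose && iter %% 100 == 0)
        message("chain ", chain, " iteration ", iter, "/", control$n_iter)
    }
    accept_lambda[chain, ] <- if (acc_n > 0) acc_sum / acc_n else NA
    accept_rho[chain] <- if (rho_n > 0) rho_acc / rho_n else NA
  }

  structure(
    list(lambda = draws$lambda, beta = draws$beta, tau2 = draws$tau2,
         G = draws$G, rho = draws$rho, chain = draws$chain,
         unit_ids = dat$unit_ids, groups = groups %||%
           tibble::tibble(group = dat$groups),
         group_labels = dat$groups, years = dat$years,
         accept_lambda = accept_lambda, accept_rho = accept_rho,
         n_clamped = n_clamped, priors = priors, control = control,
         n_keep = n_keep),
    class = "mstcar_fit"
  )
}

#' @export
print.mstcar_fit <- function(x, ...) {
  d <- c(length(x$unit_ids), length(x$group_labels), length(x$years))
  cat("<mstcar_fit> ", d[1], " units x ", d[2], " groups x ", d[3],
      " years; ", length(x$rho), " draws from ", x$control$n_chains,
      " chain(s)\n", sep = "")
  cat("  mean log-rate acceptance ",
      round(mean(x$accept_lambda, na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}
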