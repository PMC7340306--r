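#' Prior specification for the MSTCAR model
#'
#' Hyperparameters of the hierarchical model:
#' * `beta_prior_var` — variance of the vague normal prior on the group-year
#'   intercepts `beta_kt` (default 100, i.e. N(0, 100));
#' * `tau2_shape`, `tau2_rate` — weakly informative gamma prior on the cell
#'   precisions `1/tau_k^2` (default 0.001/0.001);
#' * `iw_df`, `iw_scale` — inverse-Wishart prior on the between-group
#'   covariance `G`; defaults (`K + 2`, `0.1 * I`) are resolved against the
#'   data when the model is fitted;
#' * `rho_a`, `rho_b` — beta prior on the AR(1) coefficient `rho`
#'   (default Beta(1, 1), uniform on (0, 1)).
#'
#' @param beta_prior_var positive scalar.
#' @param tau2_shape,tau2_rate positive scalars.
#' @param iw_df `NULL` (resolved to `K + 2`) or a scalar `> K - 1`.
#' @param iw_scale `NULL` (resolved to `0.1 * diag(K)`) or a K x K SPD matrix.
#' @param rho_a,rho_b positive scalars.
#' @return a list of class `mstcar_priors`.
#' @export
mstcar_priors <- function(beta_prior_var = 100,
                          tau2_shape = 0.001, tau2_rate = 0.001,
                          iw_df = NULL, iw_scale = NULL,
                          rho_a = 1, rho_b = 1) {
  stopifnot(beta_prior_var > 0, tau2_shape > 0, tau2_rate > 0,
            rho_a > 0, rho_b > 0)
  structure(list(beta_prior_var = beta_prior_var,
                 tau2_shape = tau2_shape, tau2_rate = tau2_rate,
                 iw_df = iw_df, iw_scale = iw_scale,
                 rho_a = rho_a, rho_b = rho_b),
            class = "mstcar_priors")
}

# fill in K-dependent defaults and check dimensions
resolve_priors <- function(priors, K) {
  if (is.null(priors$iw_df)) priors$iw_df <- K + 2
  if (priors$iw_df <= K - 1) stop("`iw_df` must exceed K - 1")
  if (is.null(priors$iw_scale)) priors$iw_scale <- 0.1 * diag(K)
  priors$iw_scale <- as.matrix(priors$iw_scale)
  if (!all(dim(priors$iw_scale) == K))
    stop("`iw_scale` must be K x K")
  priors
}

#' Sampler configuration
#'
#' Controls the Metropolis-within-Gibbs run. Defaults follow common practice
#' for this model class: 4 chains of 6000 iterations, the first 3000
#' discarded as burn-in, retained draws thinned by 3 (1000 kept draws per
#' chain).
#'
#' @param n_chains number of independent chains (run sequentially).
#' @param n_iter iterations per chain.
#' @param n_burnin burn-in iterations discarded (must be `< n_iter`).
#' @param thin thinning interval for stored draws.
#' @param proposal_sd initial random-walk scale multiplier for the
#'   log-rate Metropolis step (per-cell scales are derived from the counts).
#' @param rho_proposal_sd random-walk sd for the AR(1) coefficient.
#' @param adapt adapt the log-rate proposal scales toward a 0.44 acceptance
#'   rate during burn-in (adaptation is frozen afterwards so the post
#'   burn-in chain is a genuine Markov chain).
#' @param update character vector naming the blocks to update; blocks not
#'   listed stay at their initial values. All six by default.
#' @param center_Z re-impose the per-component sum-to-zero constraint on the
#'   spatial effects after every sweep (identifiability of the intercepts).
#' @param save_lambda store the thinned rate draws (needed for
#'   standardization and trends; switch off only for prior diagnostics).
#' @param seed integer root seed; chain c uses stream `seed * 97 + c`.
#' @param verbose print progress every 100 iterations.
#' @return a list of class `mstcar_control`.
#' @export
mstcar_control <- function(n_chains = 4, n_iter = 6000, n_burnin = 3000,
                           thin = 3, proposal_sd = 2.4,
                           rho_proposal_sd = 0.05, adapt = TRUE,
                           update = c("log_lambda", "beta", "Z", "tau2",
                                      "G", "rho"),
                           center_Z = TRUE, save_lambda = TRUE,
                           seed = 1L, verbose = FALSE) {
  stopifnot(n_burnin < n_iter, thin >= 1, n_chains >= 1,
            proposal_sd > 0, rho_proposal_sd > 0)
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin),
                 thin = as.integer(thin),
                 proposal_sd = proposal_sd,
                 rho_proposal_sd = rho_proposal_sd,
                 adapt = isTRUE(adapt),
                 update = update, center_Z = isTRUE(center_Z),
                 save_lambda = isTRUE(save_lambda),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "mstcar_control")
}
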