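#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of a fitted MSTCAR model
#'
#' One row per model parameter (intercepts `beta[k,t]`, variances
#' `tau2[k]`, covariance entries `G[k,k']`, and `rho`) with the posterior
#' median, 95% credible interval and split-chain Rhat.
#'
#' @param x a [fit_mstcar()] result.
#' @param ... unused.
#' @return tibble `term, estimate, conf.low, conf.high, rhat`.
#' @export
tidy.mstcar_fit <- function(x, ...) {
  K <- dim(x$beta)[2]; T <- dim(x$beta)[3]
  vals <- list()
  for (k in seq_len(K)) for (t in seq_len(T))
    vals[[paste0("beta[", k, ",", t, "]")]] <- x$beta[, k, t]
  for (k in seq_len(K)) vals[[paste0("tau2[", k, "]")]] <- x$tau2[, k]
  for (k in seq_len(K)) for (j in k:K)
    vals[[paste0("G[", k, ",", j, "]")]] <- x$G[, k, j]
  vals[["rho"]] <- x$rho
  qs <- t(vapply(vals, draw_summary, numeric(3)))
  rhats <- vapply(vals, split_rhat, numeric(1), chain = x$chain)
  tibble::tibble(term = names(vals), estimate = qs[, 1],
                 conf.low = qs[, 2], conf.high = qs[, 3],
                 rhat = unname(rhats))
}

#' One-row summary of a fitted MSTCAR model
#'
#' @param x a [fit_mstcar()] result.
#' @param ... unused.
#' @return tibble with draw counts, acceptance rates, clamping events and
#'   the worst parameter Rhat.
#' @export
glance.mstcar_fit <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    n_draws = length(x$rho),
    n_chains = x$control$n_chains,
    n_units = length(x$unit_ids),
    n_groups = length(x$group_labels),
    n_years = length(x$years),
    accept_log_lambda = mean(x$accept_lambda, na.rm = TRUE),
    accept_rho = mean(x$accept_rho, na.rm = TRUE),
    n_clamped = x$n_clamped,
    max_rhat = max(td$rhat, na.rm = TRUE)
  )
}
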