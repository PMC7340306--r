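# split-chain potential scale reduction factor (Rhat): each chain is split
# in half and the usual between/within variance ratio computed over the
# resulting 2 * n_chains sequences.
split_rhat <- function(x, chain) {
  pieces <- list()
  for (ch in unique(chain)) {
    v <- x[chain == ch]
    h <- length(v) %/% 2
    if (h < 2) return(NA_real_)
    pieces <- c(pieces, list(v[seq_len(h)], v[(h + 1):(2 * h)]))
  }
  n <- min(lengths(pieces))
  mat <- vapply(pieces, function(v) v[seq_len(n)], numeric(n))
  mns <- colMeans(mat)
  vars <- apply(mat, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(mns)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence diagnostics for a fitted MSTCAR model
#'
#' Computes split-chain potential-scale-reduction statistics (Rhat) for the
#' group-year intercepts, the cell variances, the AR(1) coefficient, and a
#' sample of rate cells, flagging any statistic above 1.1. With a single
#' chain the split halves of that chain are compared, with a warning.
#'
#' @param fit a [fit_mstcar()] result.
#' @param n_lambda_cells how many rate cells to sample for diagnostics.
#' @param trace_dir optional directory; when set, per-parameter trace data
#'   (iteration, chain, value) are written as CSV files for plotting.
#' @return a tibble `parameter, rhat, flagged` (flagged = Rhat > 1.1).
#' @export
convergence_report <- function(fit, n_lambda_cells = 10, trace_dir = NULL) {
  stopifnot(inherits(fit, "mstcar_fit"))
  if (length(unique(fit$chain)) < 2)
    warning("single chain: using within-chain split halves only")
  K <- dim(fit$beta)[2]; T <- dim(fit$beta)[3]
  out <- list()
  for (k in seq_len(K)) for (t in seq_len(T)) {
    out[[paste0("beta[", k, ",", t, "]")]] <- fit$beta[, k, t]
  }
  for (k in seq_len(K)) out[[paste0("tau2[", k, "]")]] <- fit$tau2[, k]
  if (stats::sd(fit$rho) > 0) out[["rho"]] <- fit$rho
  if (!is.null(fit$lambda)) {
    d <- dim(fit$lambda)
    set.seed(1)
    cells <- unique(cbind(sample.int(d[2], n_lambda_cells, replace = TRUE),
                          sample.int(d[3], n_lambda_cells, replace = TRUE),
                          sample.int(d[4], n_lambda_cells, replace = TRUE)))
    for (r in seq_len(nrow(cells))) {
      nm <- paste0("lambda[", paste(cells[r, ], collapse = ","), "]")
      out[[nm]] <- fit$lambda[, cells[r, 1], cells[r, 2], cells[r, 3]]
    }
  }
  if (!is.null(trace_dir)) {
    dir.create(trace_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      fn <- file.path(trace_dir, paste0(gsub("[^A-Za-z0-9]+", "_", nm),
                                        ".csv"))
      utils::write.csv(
        data.frame(draw = seq_along(out[[nm]]), chain = fit$chain,
                   value = out[[nm]]),
        fn, row.names = FALSE)
    }
  }
  rhats <- vapply(out, split_rhat, numeric(1), chain = fit$chain)
  tibble::tibble(parameter = names(out), rhat = unname(rhats),
                 flagged = !is.na(rhats) & rhats > 1.1)
}
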