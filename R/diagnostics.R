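#' Split-\eqn{\hat{R}} convergence diagnostic
#'
#' Potential scale reduction factor computed on split chains: each chain is
#' cut in half and the usual between/within variance ratio is taken over the
#' resulting `2 * chains` sequences, so that non-stationarity within a chain
#' is detected as well as disagreement between chains.
#'
#' @param draws numeric matrix, `iterations x chains`, post-warmup draws of a
#'   single scalar parameter.
#' @return the split-\eqn{\hat{R}} estimate (scalar, `>= 1` up to noise).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  splits <- do.call(cbind, lapply(seq_len(ncol(draws)), function(c) {
    cbind(draws[seq_len(half), c], draws[(n - half + 1):n, c])
  }))
  m <- ncol(splits)
  nn <- nrow(splits)
  chain_means <- colMeans(splits)
  chain_vars <- apply(splits, 2, var)
  w <- mean(chain_vars)
  b <- nn * var(chain_means)
  if (w <= 0) return(1)
  var_plus <- (nn - 1) / nn * w + b / nn
  sqrt(var_plus / w)
}

# diagnostics for a named list of iterations x chains matrices
mcmc_diagnostics <- function(draw_list, rhat_limit = 1.01) {
  rhat <- vapply(draw_list, split_rhat, numeric(1))
  ess <- vapply(draw_list, function(d) {
    ml <- coda::mcmc.list(lapply(seq_len(ncol(d)), function(c) coda::mcmc(d[, c])))
    sum(coda::effectiveSize(ml))
  }, numeric(1))
  converged <- all(is.na(rhat) | rhat <= rhat_limit)
  list(rhat = rhat, ess = ess, converged = converged, rhat_limit = rhat_limit)
}

warn_if_not_converged <- function(diag, what) {
  if (!isTRUE(diag$converged)) {
    bad <- names(diag$rhat)[which(diag$rhat > diag$rhat_limit)]
    warning(sprintf("%s: split-Rhat above %.3f for %s (max %.3f)",
                    what, diag$rhat_limit, paste(bad, collapse = ", "),
                    max(diag$rhat, na.rm = TRUE)), call. = FALSE)
  }
  invisible(diag)
}
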