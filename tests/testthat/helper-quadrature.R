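# Independent dense-grid quadrature oracle for the two-parameter BLRM
# posterior. Written without reference to the package's sampler or prior
# encodings: densities are spelled out from the model definition, so MCMC
# results can be checked against an implementation that shares no code path.

# log binomial likelihood at matrices A (log alpha) and B (log beta)
quad_loglik <- function(A, B, outcome, grid) {
  ll <- matrix(0, nrow(A), ncol(A))
  for (k in seq_len(grid$K)) {
    if (outcome$n_per_dose[k] == 0) next
    eta <- A + exp(B) * grid$log_std[k]
    ll <- ll + outcome$dlt_per_dose[k] * eta -
      outcome$n_per_dose[k] * log(1 + exp(eta))
  }
  ll
}

# log prior densities, written out per prior kind
quad_logprior <- function(A, B, prior) {
  if (prior$kind == "mixture") {
    s <- prior$source_part
    w <- prior$weak_part
    da <- prior$delta_alpha
    db <- prior$delta_beta
    log(da * dnorm(A, s$mu_alpha, sqrt(s$var_alpha)) +
          (1 - da) * dnorm(A, w$mu_alpha, sqrt(w$var_alpha))) +
      log(db * dnorm(B, s$mu_beta, sqrt(s$var_beta)) +
            (1 - db) * dnorm(B, w$mu_beta, sqrt(w$var_beta)))
  } else {
    p <- if (prior$kind == "weak") prior$weak_part else prior$source_part
    det <- p$var_alpha * p$var_beta - p$cov_ab^2
    da <- A - p$mu_alpha
    db <- B - p$mu_beta
    -0.5 * (da^2 * p$var_beta - 2 * da * db * p$cov_ab + db^2 * p$var_alpha) /
      det - 0.5 * log(det)
  }
}

# posterior moments by dense 2-D grid quadrature
quad_posterior <- function(outcome, grid, prior,
                           la_range = c(-9, 6), lb_range = c(-7, 5),
                           n_grid = 401) {
  la <- seq(la_range[1], la_range[2], length.out = n_grid)
  lb <- seq(lb_range[1], lb_range[2], length.out = n_grid)
  A <- matrix(la, n_grid, n_grid)
  B <- matrix(lb, n_grid, n_grid, byrow = TRUE)
  lp <- quad_loglik(A, B, outcome, grid) + quad_logprior(A, B, prior)
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  mu_a <- sum(w * A)
  mu_b <- sum(w * B)
  list(mean_log_alpha = mu_a, mean_log_beta = mu_b,
       var_log_alpha = sum(w * (A - mu_a)^2),
       var_log_beta = sum(w * (B - mu_b)^2),
       cov = sum(w * (A - mu_a) * (B - mu_b)))
}

# Monte-Carlo standard error of a posterior mean from a blrm_fit
fit_mcse <- function(fit, par) {
  sd(fit$draws[[par]]) / sqrt(fit$diagnostics$ess[[par]])
}
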