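#' Dose grid for a dose-finding trial
#'
#' A strictly increasing set of doses together with the reference dose
#' \eqn{d_R} at which the BLRM intercept is interpreted: at \eqn{d = d_R} the
#' log-odds of toxicity equal \eqn{\log\alpha}.
#'
#' @param doses strictly increasing vector of positive doses (length >= 2).
#' @param reference_dose positive scalar \eqn{d_R}.
#' @return an object of class `dose_grid` with elements `doses`,
#'   `reference_dose`, `K` and `log_std` (the standardized log doses
#'   \eqn{\log(d_k / d_R)}).
#' @export
#' @examples
#' dose_grid(c(0.25, 0.5, 1, 2, 4), reference_dose = 1)
dose_grid <- function(doses, reference_dose) {
  doses <- as.numeric(doses)
  stopifnot(length(doses) >= 2L, all(is.finite(doses)))
  if (any(doses <= 0)) stop("all doses must be positive")
  if (any(diff(doses) <= 0)) stop("doses must be strictly increasing")
  if (!is.numeric(reference_dose) || length(reference_dose) != 1L ||
      reference_dose <= 0) {
    stop("reference_dose must be a single positive number")
  }
  structure(list(doses = doses, reference_dose = reference_dose,
                 K = length(doses), log_std = log(doses / reference_dose)),
            class = "dose_grid")
}

#' Default five-level geometric dose grid
#'
#' Doses `(0.25, 0.5, 1, 2, 4) * reference_dose`, so the reference dose is
#' the middle level and the standardized log doses are symmetric about 0.
#'
#' @param reference_dose positive scalar; defaults to 1 (doses in units of
#'   the reference dose).
#' @return a [dose_grid()].
#' @export
default_dose_grid <- function(reference_dose = 1) {
  dose_grid(c(0.25, 0.5, 1, 2, 4) * reference_dose, reference_dose)
}

#' Per-dose binomial trial outcome
#'
#' @param n_per_dose non-negative integer vector: patients treated per dose
#'   level.
#' @param dlt_per_dose non-negative integer vector: dose-limiting toxicities
#'   per dose level; must satisfy `dlt_per_dose <= n_per_dose` elementwise.
#' @return an object of class `trial_outcome`.
#' @export
trial_outcome <- function(n_per_dose, dlt_per_dose) {
  n_per_dose <- as.integer(n_per_dose)
  dlt_per_dose <- as.integer(dlt_per_dose)
  if (length(n_per_dose) != length(dlt_per_dose)) {
    stop("n_per_dose and dlt_per_dose must have equal length")
  }
  if (any(n_per_dose < 0L) || any(dlt_per_dose < 0L)) {
    stop("counts must be non-negative")
  }
  if (any(dlt_per_dose > n_per_dose)) {
    stop("dlt_per_dose cannot exceed n_per_dose")
  }
  structure(list(n_per_dose = n_per_dose, dlt_per_dose = dlt_per_dose),
            class = "trial_outcome")
}

#' True dose-toxicity curve
#'
#' The data-generating logistic curve, parameterized by `log_alpha`
#' (log-odds of toxicity at the reference dose) and `log_beta` (log slope).
#'
#' @param log_alpha,log_beta real scalars.
#' @return an object of class `dose_tox_curve`.
#' @export
dose_tox_curve <- function(log_alpha, log_beta) {
  stopifnot(is.finite(log_alpha), is.finite(log_beta))
  structure(list(log_alpha = log_alpha, log_beta = log_beta),
            class = "dose_tox_curve")
}

#' Toxicity probability under the two-parameter logistic model
#'
#' \deqn{\mathrm{logit}\, p(d) = \log\alpha + \beta \log(d / d_R), \quad
#'   \beta = e^{\log\beta} > 0.}
#'
#' @param log_alpha,log_beta model parameters on the log scale.
#' @param dose positive dose (vectorized).
#' @param reference_dose positive reference dose \eqn{d_R}.
#' @return DLT probabilities in (0, 1), strictly increasing in `dose`.
#' @export
#' @examples
#' dose_toxicity(-0.84, 0, dose = 1, reference_dose = 1)  # plogis(-0.84)
dose_toxicity <- function(log_alpha, log_beta, dose, reference_dose) {
  if (any(dose <= 0) || any(reference_dose <= 0)) {
    stop("dose and reference_dose must be positive")
  }
  plogis(log_alpha + exp(log_beta) * log(dose / reference_dose))
}

# curve probabilities on a grid
curve_probs <- function(curve, grid) {
  dose_toxicity(curve$log_alpha, curve$log_beta, grid$doses,
                grid$reference_dose)
}

#' Target and escalation configuration for dose selection
#'
#' @param theta target DLT probability in (0, 1); default 0.30.
#' @param no_skip logical: if `TRUE`, escalation may not jump over untried
#'   dose levels (recommendation capped at one level above the highest tried).
#' @param mtd_rule currently only `"closest_to_theta"`.
#' @return object of class `target_config`.
#' @export
target_config <- function(theta = 0.30, no_skip = TRUE,
                          mtd_rule = "closest_to_theta") {
  stopifnot(is.numeric(theta), length(theta) == 1L, theta > 0, theta < 1)
  mtd_rule <- match.arg(mtd_rule)
  structure(list(theta = theta, no_skip = isTRUE(no_skip), mtd_rule = mtd_rule),
            class = "target_config")
}

#' Fit the two-parameter BLRM by MCMC
#'
#' Samples the posterior of `(log_alpha, log_beta)` under the binomial
#' likelihood \eqn{Y_k \sim \mathrm{Bin}(n_k, p_k)} and one of the prior
#' specifications from [weak_prior()], [full_borrowing_prior()],
#' [mixture_prior()] or [inflated_prior()], using an adaptive random-walk
#' Metropolis sampler. The robust mixture prior enters as a marginalized
#' two-component log density per parameter (no component indicators).
#'
#' Convergence is summarized by split-\eqn{\hat{R}} and effective sample
#' size per parameter; any split-\eqn{\hat{R}} above 1.01 raises a warning
#' and is flagged in `$diagnostics$converged`.
#'
#' @param outcome a [trial_outcome()]; all-zero counts give a prior-only fit.
#' @param grid a [dose_grid()] with `K` equal to the outcome length.
#' @param prior a `blrm_prior` object.
#' @param chains,iter,warmup,thin MCMC settings; defaults 4 chains x 1000
#'   retained post-warmup draws (500 warmup, thinning 3).
#' @param seed optional integer; if supplied, `set.seed(seed)` is called so
#'   the fit is reproducible. The fit consumes R's RNG stream either way.
#' @return object of class `blrm_fit` with elements `draws` (data.frame of
#'   `log_alpha`, `log_beta`), `draws_array` (iterations x chains x 2),
#'   `diagnostics`, `accept_rate`, `prior`, `grid`, `outcome`.
#' @export
fit_blrm <- function(outcome, grid, prior, chains = 4L, iter = 1000L,
                     warmup = 500L, thin = 3L, seed = NULL) {
  stopifnot(inherits(outcome, "trial_outcome"), inherits(grid, "dose_grid"),
            inherits(prior, "blrm_prior"))
  if (length(outcome$n_per_dose) != grid$K) {
    stop("outcome length does not match dose grid")
  }
  if (chains < 1L || iter < 1L) stop("chains and iter must be positive")
  if (!is.null(seed)) set.seed(seed)

  enc <- encode_prior(prior)
  ctr <- prior_center(prior)
  sds <- prior_marginal_sds(prior)
  init <- cbind(rnorm(chains, ctr[1], min(1, sds[1])),
                rnorm(chains, ctr[2], min(0.5, sds[2])))
  res <- .blrm_mh_cpp(outcome$dlt_per_dose, outcome$n_per_dose, grid$log_std,
                      enc$type, enc$pars, init, sds, as.integer(warmup),
                      as.integer(iter), as.integer(thin))
  arr <- array(c(res$log_alpha, res$log_beta), dim = c(iter, chains, 2),
               dimnames = list(NULL, NULL, c("log_alpha", "log_beta")))
  diag <- mcmc_diagnostics(list(log_alpha = res$log_alpha,
                                log_beta = res$log_beta))
  fit <- structure(list(
    draws = data.frame(log_alpha = as.vector(res$log_alpha),
                       log_beta = as.vector(res$log_beta)),
    draws_array = arr,
    diagnostics = diag,
    accept_rate = res$accept_rate,
    chains = chains, iter = iter, warmup = warmup, thin = thin,
    prior = prior, grid = grid, outcome = outcome), class = "blrm_fit")
  warn_if_not_converged(diag, "fit_blrm")
  fit
}

#' Posterior mean DLT probability per dose level
#'
#' @param fit a `blrm_fit`.
#' @param grid optionally a different [dose_grid()]; defaults to the fit's.
#' @return numeric vector of posterior mean toxicity probabilities.
#' @export
posterior_tox <- function(fit, grid = fit$grid) {
  stopifnot(inherits(fit, "blrm_fit"))
  la <- fit$draws$log_alpha
  beta <- exp(fit$draws$log_beta)
  vapply(grid$log_std, function(x) mean(plogis(la + beta * x)), numeric(1))
}

# argmin |p - theta| with ties broken toward the lower dose
closest_dose <- function(p_hat, theta) {
  d <- abs(p_hat - theta)
  which(d <= min(d) + 1e-12)[1L]
}

#' Model-recommended dose for the next cohort
#'
#' Returns the dose level whose posterior mean DLT probability is closest to
#' the target `theta`; exact ties are broken toward the lower (safer) dose.
#' With `no_skip` set in the target configuration, the recommendation is
#' capped at one level above the highest dose tried so far.
#'
#' @param fit a `blrm_fit`.
#' @param grid a [dose_grid()]; defaults to the fit's grid.
#' @param target a [target_config()].
#' @param current_highest_tried highest dose level tried so far (ordinal), or
#'   `NULL` if escalation capping does not apply (e.g., final MTD selection).
#' @return ordinal dose index in `1..K`.
#' @export
recommend_dose <- function(fit, grid = fit$grid, target = target_config(),
                           current_highest_tried = NULL) {
  if (grid$K < 1L) stop("empty dose grid")
  p_hat <- posterior_tox(fit, grid)
  k <- closest_dose(p_hat, target$theta)
  if (target$no_skip && !is.null(current_highest_tried)) {
    k <- min(k, current_highest_tried + 1L)
  }
  as.integer(k)
}

#' Moment-match a BLRM posterior to a bivariate normal
#'
#' Summarizes the MCMC draws of `(log_alpha, log_beta)` by their sample
#' means, variances and covariance — the bivariate normal approximation used
#' to carry a source-population posterior into a target-population prior.
#'
#' @param fit a `blrm_fit` with at least 1000 draws.
#' @return a [bvn_params()] object; `$rho` holds the posterior correlation
#'   \eqn{\rho_{source}}.
#' @export
moment_match <- function(fit) {
  stopifnot(inherits(fit, "blrm_fit"))
  d <- fit$draws
  if (nrow(d) < 1000L) stop("moment_match requires at least 1000 draws")
  va <- var(d$log_alpha)
  vb <- var(d$log_beta)
  if (va <= 0 || vb <= 0) stop("degenerate (zero-variance) posterior draws")
  bvn_params(mu_alpha = mean(d$log_alpha), mu_beta = mean(d$log_beta),
             var_alpha = va, var_beta = vb,
             cov_ab = cov(d$log_alpha, d$log_beta))
}

#' True MTD of a known dose-toxicity curve
#'
#' The dose level whose true DLT probability is closest to the target;
#' ties broken toward the lower dose.
#'
#' @param curve a [dose_tox_curve()].
#' @param grid a [dose_grid()].
#' @param theta target DLT probability.
#' @return ordinal dose index.
#' @export
true_mtd <- function(curve, grid, theta = 0.30) {
  as.integer(closest_dose(curve_probs(curve, grid), theta))
}

#' @export
print.blrm_fit <- function(x, ...) {
  cat("BLRM fit (", x$chains, "chains x", x$iter, "draws,",
      x$prior$kind, "prior )\n")
  s <- rbind(mean = colMeans(x$draws), sd = apply(x$draws, 2, sd))
  print(round(s, 3))
  cat("split-Rhat:", paste(sprintf("%s %.3f", names(x$diagnostics$rhat),
                                   x$diagnostics$rhat), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("dose grid: ", paste(signif(x$doses, 4), collapse = ", "),
      " (reference dose ", signif(x$reference_dose, 4), ")\n", sep = "")
  invisible(x)
}
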