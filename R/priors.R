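#' Bivariate normal parameters for (log alpha, log beta)
#'
#' The common currency of the borrowing workflow: weakly informative priors,
#' moment-matched source posteriors, and inflated priors are all carried as
#' means, variances and a covariance on the `(log alpha, log beta)` scale.
#'
#' @param mu_alpha,mu_beta means.
#' @param var_alpha,var_beta positive variances.
#' @param cov_ab covariance; must satisfy `cov_ab^2 <= var_alpha * var_beta`.
#' @return object of class `bvn_params` with derived element `rho`.
#' @export
bvn_params <- function(mu_alpha, mu_beta, var_alpha, var_beta, cov_ab = 0) {
  stopifnot(is.finite(mu_alpha), is.finite(mu_beta))
  if (var_alpha <= 0 || var_beta <= 0) stop("variances must be positive")
  if (cov_ab^2 > var_alpha * var_beta * (1 + 1e-12)) {
    stop("cov_ab^2 exceeds var_alpha * var_beta")
  }
  structure(list(mu_alpha = mu_alpha, mu_beta = mu_beta,
                 var_alpha = var_alpha, var_beta = var_beta, cov_ab = cov_ab,
                 rho = cov_ab / sqrt(var_alpha * var_beta)),
            class = "bvn_params")
}

#' @export
print.bvn_params <- function(x, ...) {
  cat(sprintf(
    "bivariate normal: mu = (%.3f, %.3f), var = (%.3f, %.3f), cov = %.3f (rho = %.3f)\n",
    x$mu_alpha, x$mu_beta, x$var_alpha, x$var_beta, x$cov_ab, x$rho))
  invisible(x)
}

new_prior <- function(kind, weak_part = NULL, source_part = NULL,
                      delta_alpha = NULL, delta_beta = NULL,
                      omega_alpha = NULL, omega_beta = NULL) {
  structure(list(kind = kind, weak_part = weak_part, source_part = source_part,
                 delta_alpha = delta_alpha, delta_beta = delta_beta,
                 omega_alpha = omega_alpha, omega_beta = omega_beta),
            class = "blrm_prior")
}

#' Weakly informative BLRM prior
#'
#' Independent normals `N(means[1], sd_alpha^2) x N(means[2], sd_beta^2)`
#' with the default scales `sd_alpha = 2`, `sd_beta = 1.5` and zero
#' covariance — wide enough to cover a broad range of reference-dose
#' toxicities and dose-response slopes. When borrowing "means only" from a
#' source population, pass the source posterior means as `means`.
#'
#' @param means length-2 numeric, means of `(log alpha, log beta)`; default
#'   `c(-0.84, 0)` (prior reference-dose toxicity `plogis(-0.84)`, about 0.3,
#'   and unit slope).
#' @param sd_alpha,sd_beta prior standard deviations.
#' @return a `blrm_prior` of kind `"weak"`.
#' @export
weak_prior <- function(means = c(-0.84, 0), sd_alpha = 2, sd_beta = 1.5) {
  stopifnot(length(means) == 2L, sd_alpha > 0, sd_beta > 0)
  new_prior("weak", weak_part = bvn_params(means[1], means[2],
                                           sd_alpha^2, sd_beta^2, 0))
}

#' Full-borrowing BLRM prior
#'
#' Uses the (moment-matched) source-population posterior, unchanged, as the
#' target-population prior.
#'
#' @param source a [bvn_params()] source posterior approximation.
#' @return a `blrm_prior` of kind `"full"`.
#' @export
full_borrowing_prior <- function(source) {
  stopifnot(inherits(source, "bvn_params"))
  new_prior("full", source_part = source)
}

#' Robust per-parameter mixture prior
#'
#' For each parameter independently, a two-component normal mixture of the
#' source posterior marginal (weight `delta`) and a weakly informative
#' component (weight `1 - delta`):
#' \deqn{\log\alpha \sim \delta_\alpha P_{src}(\log\alpha) +
#'   (1-\delta_\alpha) P_{weak}(\log\alpha)}
#' and likewise for \eqn{\log\beta}. The per-parameter formulation treats
#' the two parameters as independent, so the source covariance is dropped.
#'
#' @param source a [bvn_params()] source posterior approximation.
#' @param weak a [bvn_params()] weak component (e.g. from
#'   `weak_prior(...)$weak_part`).
#' @param delta_alpha,delta_beta mixture weights in `[0, 1]`; 1 is full
#'   borrowing, 0 discards the source.
#' @return a `blrm_prior` of kind `"mixture"`.
#' @export
mixture_prior <- function(source, weak, delta_alpha, delta_beta) {
  stopifnot(inherits(source, "bvn_params"), inherits(weak, "bvn_params"))
  for (d in c(delta_alpha, delta_beta)) {
    if (!is.numeric(d) || length(d) != 1L || d < 0 || d > 1) {
      stop("mixture weights must be in [0, 1]")
    }
  }
  new_prior("mixture", weak_part = weak, source_part = source,
            delta_alpha = delta_alpha, delta_beta = delta_beta)
}

#' Variance-inflated BLRM prior
#'
#' Bivariate normal with the source means, variances divided by the
#' inflation factors (\eqn{\sigma^2 / \omega}), and covariance adjusted so
#' that the source correlation is preserved:
#' \deqn{\sigma_{\alpha\beta,adj} = \rho_{src}
#'   \sqrt{(\sigma^2_{\alpha,src}/\omega_\alpha)
#'         (\sigma^2_{\beta,src}/\omega_\beta)}.}
#' \eqn{\omega = 1} is full borrowing; smaller \eqn{\omega} weakens the prior.
#'
#' @param source a [bvn_params()] source posterior approximation.
#' @param omega_alpha,omega_beta inflation factors in `(0, 1]`.
#' @return a `blrm_prior` of kind `"inflated"`.
#' @export
inflated_prior <- function(source, omega_alpha, omega_beta) {
  stopifnot(inherits(source, "bvn_params"))
  for (w in c(omega_alpha, omega_beta)) {
    if (!is.numeric(w) || length(w) != 1L || w <= 0 || w > 1) {
      stop("inflation factors must be in (0, 1]")
    }
  }
  va <- source$var_alpha / omega_alpha
  vb <- source$var_beta / omega_beta
  infl <- bvn_params(source$mu_alpha, source$mu_beta, va, vb,
                     cov_ab = source$rho * sqrt(va * vb))
  new_prior("inflated", source_part = infl,
            omega_alpha = omega_alpha, omega_beta = omega_beta)
}

# the bivariate-normal (or per-parameter mixture) parameters consumed by the
# sampler; type 0 = bivariate normal, type 1 = independent mixtures
encode_prior <- function(prior) {
  switch(prior$kind,
    weak = {
      p <- prior$weak_part
      list(type = 0L, pars = c(p$mu_alpha, p$mu_beta, p$var_alpha,
                               p$var_beta, p$cov_ab))
    },
    full = ,
    inflated = {
      p <- prior$source_part
      list(type = 0L, pars = c(p$mu_alpha, p$mu_beta, p$var_alpha,
                               p$var_beta, p$cov_ab))
    },
    mixture = {
      s <- prior$source_part; w <- prior$weak_part
      list(type = 1L,
           pars = c(prior$delta_alpha, s$mu_alpha, sqrt(s$var_alpha),
                    w$mu_alpha, sqrt(w$var_alpha),
                    prior$delta_beta, s$mu_beta, sqrt(s$var_beta),
                    w$mu_beta, sqrt(w$var_beta)))
    },
    stop("unknown prior kind: ", prior$kind))
}

# marginal prior standard deviations, for proposal scaling and inits
prior_marginal_sds <- function(prior) {
  if (prior$kind == "mixture") {
    s <- prior$source_part; w <- prior$weak_part
    msd <- function(d, ms, vs, mw, vw) {
      m <- d * ms + (1 - d) * mw
      sqrt(d * (vs + ms^2) + (1 - d) * (vw + mw^2) - m^2)
    }
    c(msd(prior$delta_alpha, s$mu_alpha, s$var_alpha, w$mu_alpha, w$var_alpha),
      msd(prior$delta_beta, s$mu_beta, s$var_beta, w$mu_beta, w$var_beta))
  } else {
    p <- if (prior$kind == "weak") prior$weak_part else prior$source_part
    c(sqrt(p$var_alpha), sqrt(p$var_beta))
  }
}

# prior center used for MCMC initialization
prior_center <- function(prior) {
  if (prior$kind == "mixture") {
    s <- prior$source_part; w <- prior$weak_part
    c(prior$delta_alpha * s$mu_alpha + (1 - prior$delta_alpha) * w$mu_alpha,
      prior$delta_beta * s$mu_beta + (1 - prior$delta_beta) * w$mu_beta)
  } else {
    p <- if (prior$kind == "weak") prior$weak_part else prior$source_part
    c(p$mu_alpha, p$mu_beta)
  }
}

#' Marginal prior density of one BLRM parameter
#'
#' Evaluates the marginal prior density of `log alpha` or `log beta` under
#' any prior specification (normal marginal, or two-component mixture for
#' the robust mixture prior). Used for audit plots and quadrature checks.
#'
#' @param prior a `blrm_prior`.
#' @param x numeric vector of evaluation points.
#' @param parameter `"alpha"` or `"beta"`.
#' @return density values.
#' @export
prior_marginal_density <- function(prior, x, parameter = c("alpha", "beta")) {
  parameter <- match.arg(parameter)
  pick <- function(p) if (parameter == "alpha") {
    c(p$mu_alpha, sqrt(p$var_alpha))
  } else c(p$mu_beta, sqrt(p$var_beta))
  if (prior$kind == "mixture") {
    s <- pick(prior$source_part); w <- pick(prior$weak_part)
    d <- if (parameter == "alpha") prior$delta_alpha else prior$delta_beta
    d * dnorm(x, s[1], s[2]) + (1 - d) * dnorm(x, w[1], w[2])
  } else {
    p <- pick(if (prior$kind == "weak") prior$weak_part else prior$source_part)
    dnorm(x, p[1], p[2])
  }
}

#' @export
print.blrm_prior <- function(x, ...) {
  cat("BLRM prior, kind =", x$kind, "\n")
  if (!is.null(x$source_part)) { cat("  source: "); print(x$source_part) }
  if (!is.null(x$weak_part)) { cat("  weak:   "); print(x$weak_part) }
  if (x$kind == "mixture") {
    cat(sprintf("  mixture weights delta = (%.3f, %.3f)\n",
                x$delta_alpha, x$delta_beta))
  }
  if (x$kind == "inflated") {
    cat(sprintf("  inflation omega = (%.3g, %.3g)\n",
                x$omega_alpha, x$omega_beta))
  }
  invisible(x)
}
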