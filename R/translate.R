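#' Map estimated similarity to a robust mixture weight
#'
#' The posterior mean similarity \eqn{\hat\zeta} is used directly as the
#' weight \eqn{\delta} of the informative mixture component.
#'
#' @param zeta_hat posterior mean similarity in `[0, 1]` (vectorized).
#' @return mixture weight(s) \eqn{\delta = \hat\zeta}.
#' @export
similarity_to_delta <- function(zeta_hat) {
  check_unit_interval(zeta_hat, "zeta_hat")
  zeta_hat
}

#' Map estimated similarity to a variance inflation factor
#'
#' \deqn{\omega = base^{\,1-\hat\zeta} \equiv base \cdot (1/base)^{\hat\zeta}}
#' with the default `base = 0.01`: a strictly increasing map with
#' \eqn{\omega(0) = 0.01}, \eqn{\omega(0.5) = 0.10} and \eqn{\omega(1) = 1}
#' (full borrowing). The untransformed choice \eqn{\omega = \hat\zeta} is
#' often not a strong enough discount; the exponential form widens the prior
#' much more aggressively at low similarity. The appropriate base depends on
#' how informative the source posterior is, so it is exposed as an argument.
#'
#' @param zeta_hat posterior mean similarity in `[0, 1]` (vectorized).
#' @param base transformation base in (0, 1); the inflation factor at
#'   `zeta_hat = 0`.
#' @return inflation factor(s) in `[base, 1]`.
#' @export
#' @examples
#' similarity_to_omega(c(0.1, 0.5, 0.9))  # 0.016, 0.10, 0.63
similarity_to_omega <- function(zeta_hat, base = 0.01) {
  check_unit_interval(zeta_hat, "zeta_hat")
  if (!is.numeric(base) || length(base) != 1L || base <= 0 || base >= 1) {
    stop("base must be a single number in (0, 1)")
  }
  base^(1 - zeta_hat)
}

#' Inflate a source posterior variance
#'
#' Divides the source-population posterior variance by the inflation factor:
#' the target-population prior variance is \eqn{\sigma^2_{src} / \omega}.
#'
#' @param source_var positive source posterior variance (vectorized).
#' @param omega inflation factor(s) in (0, 1].
#' @return inflated prior variance(s), `>= source_var`.
#' @export
inflated_variance <- function(source_var, omega) {
  if (any(!is.finite(source_var)) || any(source_var <= 0)) {
    stop("source_var must be positive")
  }
  if (any(!is.finite(omega)) || any(omega <= 0) || any(omega > 1)) {
    stop("omega must be in (0, 1]")
  }
  source_var / omega
}

#' Borrowing controls from estimated similarity
#'
#' Bundles the two translations: mixture weights \eqn{\delta = \hat\zeta}
#' and inflation factors \eqn{\omega = base^{1-\hat\zeta}}.
#'
#' @param zeta_alpha,zeta_beta posterior mean similarities in `[0, 1]`.
#' @param base transformation base for [similarity_to_omega()].
#' @return object of class `borrowing_weights` with fields `delta_alpha`,
#'   `delta_beta`, `omega_alpha`, `omega_beta`.
#' @export
borrowing_weights <- function(zeta_alpha, zeta_beta, base = 0.01) {
  structure(list(delta_alpha = similarity_to_delta(zeta_alpha),
                 delta_beta = similarity_to_delta(zeta_beta),
                 omega_alpha = similarity_to_omega(zeta_alpha, base),
                 omega_beta = similarity_to_omega(zeta_beta, base),
                 base = base),
            class = "borrowing_weights")
}

#' @export
print.borrowing_weights <- function(x, ...) {
  cat(sprintf("borrowing controls (base %.3g):\n", x$base))
  cat(sprintf("  mixture weights  delta = (%.3f, %.3f)\n",
              x$delta_alpha, x$delta_beta))
  cat(sprintf("  inflation factors omega = (%.3f, %.3f)\n",
              x$omega_alpha, x$omega_beta))
  invisible(x)
}

check_unit_interval <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(name, " must lie in [0, 1]")
  }
  invisible(x)
}
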