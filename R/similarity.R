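#' Paired source/target dose-toxicity data for one compound
#'
#' One historical compound with dose-toxicity tables from both populations.
#' Each population carries its own dose grid (grids may differ, as in real
#' cross-ethnic data where some doses were tested in only one population);
#' all modeling is done on the standardized `log(dose / reference_dose)`
#' scale so compounds with different dosing are commensurable.
#'
#' @param compound_id character label.
#' @param source_grid,target_grid [dose_grid()] per population.
#' @param source_outcome,target_outcome [trial_outcome()] per population.
#' @return object of class `compound_dataset`.
#' @export
compound_dataset <- function(compound_id, source_grid, source_outcome,
                             target_grid, target_outcome) {
  stopifnot(inherits(source_grid, "dose_grid"),
            inherits(target_grid, "dose_grid"),
            inherits(source_outcome, "trial_outcome"),
            inherits(target_outcome, "trial_outcome"))
  if (length(source_outcome$n_per_dose) != source_grid$K ||
      length(target_outcome$n_per_dose) != target_grid$K) {
    stop("outcome length does not match dose grid for compound ", compound_id)
  }
  structure(list(compound_id = as.character(compound_id),
                 source = list(grid = source_grid, outcome = source_outcome),
                 target = list(grid = target_grid, outcome = target_outcome)),
            class = "compound_dataset")
}

#' ExNex hyperparameters
#'
#' @param weight_prior length-2 Beta shape parameters for the
#'   exchangeability weights \eqn{\zeta_\alpha, \zeta_\beta}; default
#'   `c(0.5, 0.5)` (Jeffreys-type, prior mean 0.5).
#' @param variance_prior length-2 Gamma (shape, rate) prior on the
#'   component standard deviations; default `c(1, 1/10)` (vague, mean 10).
#' @param mean_alpha,mean_beta length-2 `(mean, sd)` normal hyperpriors for
#'   the compound-level location parameters (shared by the Ex and Nex
#'   component means); defaults `N(-0.84, 2^2)` and `N(0, 1.5^2)`.
#' @return object of class `exnex_hyperparams`.
#' @export
exnex_hyperparams <- function(weight_prior = c(0.5, 0.5),
                              variance_prior = c(1, 1 / 10),
                              mean_alpha = c(-0.84, 2),
                              mean_beta = c(0, 1.5)) {
  stopifnot(all(weight_prior > 0), all(variance_prior > 0),
            mean_alpha[2] > 0, mean_beta[2] > 0)
  structure(list(weight_prior = weight_prior, variance_prior = variance_prior,
                 mean_alpha = mean_alpha, mean_beta = mean_beta),
            class = "exnex_hyperparams")
}

#' Hierarchical-model hyperparameters
#'
#' @param mean_alpha,mean_beta `(mean, sd)` normal hyperpriors for the
#'   global means; defaults `N(-0.84, 2^2)`, `N(0, 1.5^2)`.
#' @param sd_prior Gamma (shape, rate) prior on all four standard deviations
#'   (within-compound `tau` and between-compound `sigma`); default
#'   `c(1, 1/10)`.
#' @param rho_bounds support of the uniform priors on the two correlations;
#'   default `c(-1, 1)`.
#' @return object of class `hierarchical_hyperparams`.
#' @export
hierarchical_hyperparams <- function(mean_alpha = c(-0.84, 2),
                                     mean_beta = c(0, 1.5),
                                     sd_prior = c(1, 1 / 10),
                                     rho_bounds = c(-1, 1)) {
  stopifnot(mean_alpha[2] > 0, mean_beta[2] > 0, all(sd_prior > 0),
            rho_bounds[1] < rho_bounds[2], rho_bounds[1] >= -1,
            rho_bounds[2] <= 1)
  structure(list(mean_alpha = mean_alpha, mean_beta = mean_beta,
                 sd_prior = sd_prior, rho_bounds = rho_bounds),
            class = "hierarchical_hyperparams")
}

#' MCMC settings for the similarity models
#'
#' @param chains number of parallel chains (default 4).
#' @param warmup adaptation plus burn-in iterations per chain (default 500).
#' @param iter retained iterations per chain (default 1000).
#' @return list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 4L, warmup = 500L, iter = 1000L) {
  stopifnot(chains >= 1L, warmup >= 100L, iter >= 100L)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter)), class = "mcmc_control")
}

# long-format data for the JAGS models
stack_compounds <- function(datasets) {
  rows <- do.call(rbind, lapply(seq_along(datasets), function(j) {
    d <- datasets[[j]]
    do.call(rbind, lapply(c(source = 1L, target = 2L), function(s) {
      pop <- if (s == 1L) d$source else d$target
      data.frame(comp = j, pop = s, x = pop$grid$log_std,
                 y = pop$outcome$dlt_per_dose, m = pop$outcome$n_per_dose)
    }))
  }))
  rownames(rows) <- NULL
  rows
}

exnex_model_string <- "
model {
  for (i in 1:N) {
    y[i] ~ dbin(p[i], m[i])
    logit(p[i]) <- la[comp[i], pop[i]] + exp(lb[comp[i], pop[i]]) * x[i]
  }
  for (j in 1:J) {
    z_a[j] ~ dbern(zeta_a)
    z_b[j] ~ dbern(zeta_b)
    mu_ex_a[j] ~ dnorm(m0a, prec0a)
    mu_ex_b[j] ~ dnorm(m0b, prec0b)
    for (s in 1:2) {
      mu_nex_a[j, s] ~ dnorm(m0a, prec0a)
      mu_nex_b[j, s] ~ dnorm(m0b, prec0b)
      mean_a[j, s] <- z_a[j] * mu_ex_a[j] + (1 - z_a[j]) * mu_nex_a[j, s]
      mean_b[j, s] <- z_b[j] * mu_ex_b[j] + (1 - z_b[j]) * mu_nex_b[j, s]
      la[j, s] ~ dnorm(mean_a[j, s], prec_sa)
      lb[j, s] ~ dnorm(mean_b[j, s], prec_sb)
    }
  }
  zeta_a ~ dbeta(w1, w2)
  zeta_b ~ dbeta(w1, w2)
  sig_a ~ dgamma(g_shape, g_rate)
  sig_b ~ dgamma(g_shape, g_rate)
  prec_sa <- 1 / (sig_a * sig_a)
  prec_sb <- 1 / (sig_b * sig_b)
}"

hierarchical_model_string <- "
model {
  for (i in 1:N) {
    y[i] ~ dbin(p[i], m[i])
    logit(p[i]) <- th[comp[i], pop[i], 1] + exp(th[comp[i], pop[i], 2]) * x[i]
  }
  for (j in 1:J) {
    muc[j, 1:2] ~ dmnorm(mug[1:2], prec_sig[1:2, 1:2])
    for (s in 1:2) {
      th[j, s, 1:2] ~ dmnorm(muc[j, 1:2], prec_tau[1:2, 1:2])
    }
  }
  mug[1] ~ dnorm(m0a, prec0a)
  mug[2] ~ dnorm(m0b, prec0b)
  tau_a ~ dgamma(g_shape, g_rate)
  tau_b ~ dgamma(g_shape, g_rate)
  rho_tau ~ dunif(rho_lo, rho_hi)
  sig_a ~ dgamma(g_shape, g_rate)
  sig_b ~ dgamma(g_shape, g_rate)
  rho_sig ~ dunif(rho_lo, rho_hi)
  cov_tau[1, 1] <- tau_a * tau_a
  cov_tau[2, 2] <- tau_b * tau_b
  cov_tau[1, 2] <- rho_tau * tau_a * tau_b
  cov_tau[2, 1] <- cov_tau[1, 2]
  cov_sig[1, 1] <- sig_a * sig_a
  cov_sig[2, 2] <- sig_b * sig_b
  cov_sig[1, 2] <- rho_sig * sig_a * sig_b
  cov_sig[2, 1] <- cov_sig[1, 2]
  prec_tau[1:2, 1:2] <- inverse(cov_tau[1:2, 1:2])
  prec_sig[1:2, 1:2] <- inverse(cov_sig[1:2, 1:2])
  zeta_a <- sig_a * sig_a / (sig_a * sig_a + tau_a * tau_a)
  zeta_b <- sig_b * sig_b / (sig_b * sig_b + tau_b * tau_b)
}"

run_jags <- function(model_string, data, inits_fun, monitor, control, seed) {
  if (!is.null(seed)) set.seed(seed)
  inits <- lapply(seq_len(control$chains), function(c) {
    c(inits_fun(),
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = sample.int(.Machine$integer.max - 1L, 1L)))
  })
  n_adapt <- max(100L, floor(control$warmup / 2))
  n_burn <- control$warmup - n_adapt
  model <- rjags::jags.model(textConnection(model_string), data = data,
                             inits = inits, n.chains = control$chains,
                             n.adapt = n_adapt, quiet = TRUE)
  if (n_burn > 0) update(model, n_burn, progress.bar = "none")
  rjags::coda.samples(model, monitor, n.iter = control$iter,
                      progress.bar = "none")
}

# posterior summaries shared by both similarity models
summarize_similarity <- function(samples, model_name, control, extra_monitor) {
  chains_mat <- function(par) {
    sapply(samples, function(ch) as.numeric(ch[, par]))
  }
  za <- chains_mat("zeta_a")
  zb <- chains_mat("zeta_b")
  diag_pars <- c("zeta_a", "zeta_b", extra_monitor)
  diag <- mcmc_diagnostics(setNames(lapply(diag_pars, chains_mat), diag_pars))
  est <- structure(list(
    zeta_alpha_mean = mean(za), zeta_beta_mean = mean(zb),
    zeta_alpha_ci = unname(quantile(za, c(0.025, 0.975))),
    zeta_beta_ci = unname(quantile(zb, c(0.025, 0.975))),
    zeta_alpha_draws = as.numeric(za), zeta_beta_draws = as.numeric(zb),
    model = model_name, diagnostics = diag, control = control),
    class = "similarity_estimate")
  warn_if_not_converged(diag, paste0("fit_", model_name))
  est
}

#' Estimate curve similarity with the ExNex model
#'
#' Joint MCMC fit across compounds in which, per compound and per BLRM
#' parameter, the source and target values are exchangeable (drawn around a
#' shared compound-specific mean) with probability \eqn{\zeta}, or
#' non-exchangeable (separate compound- and population-specific means) with
#' probability \eqn{1 - \zeta}. The exchangeability weights
#' \eqn{\zeta_\alpha, \zeta_\beta} carry Beta(0.5, 0.5) priors and are the
#' similarity estimates; component standard deviations carry vague Gamma
#' priors. No curve-location information is shared across compounds.
#'
#' @param datasets list of at least two [compound_dataset()] objects.
#' @param hyper an [exnex_hyperparams()].
#' @param control an [mcmc_control()].
#' @param seed optional integer seed (chain RNGs are derived from it).
#' @return object of class `similarity_estimate`: posterior means, 95%
#'   credible intervals and draws of \eqn{\zeta_\alpha, \zeta_\beta}, plus
#'   convergence diagnostics.
#' @export
fit_exnex <- function(datasets, hyper = exnex_hyperparams(),
                      control = mcmc_control(), seed = NULL) {
  check_datasets(datasets)
  long <- stack_compounds(datasets)
  J <- length(datasets)
  data <- list(N = nrow(long), J = J, y = long$y, m = long$m, x = long$x,
               comp = long$comp, pop = long$pop,
               m0a = hyper$mean_alpha[1], prec0a = 1 / hyper$mean_alpha[2]^2,
               m0b = hyper$mean_beta[1], prec0b = 1 / hyper$mean_beta[2]^2,
               w1 = hyper$weight_prior[1], w2 = hyper$weight_prior[2],
               g_shape = hyper$variance_prior[1],
               g_rate = hyper$variance_prior[2])
  inits_fun <- function() {
    list(la = matrix(hyper$mean_alpha[1], J, 2),
         lb = matrix(hyper$mean_beta[1], J, 2),
         mu_ex_a = rep(hyper$mean_alpha[1], J),
         mu_ex_b = rep(hyper$mean_beta[1], J),
         mu_nex_a = matrix(hyper$mean_alpha[1], J, 2),
         mu_nex_b = matrix(hyper$mean_beta[1], J, 2),
         z_a = rbinom(J, 1L, 0.5), z_b = rbinom(J, 1L, 0.5),
         zeta_a = runif(1, 0.2, 0.8), zeta_b = runif(1, 0.2, 0.8),
         sig_a = rinit_sd(hyper$variance_prior),
         sig_b = rinit_sd(hyper$variance_prior))
  }
  samples <- run_jags(exnex_model_string, data, inits_fun,
                      c("zeta_a", "zeta_b", "sig_a", "sig_b"), control, seed)
  summarize_similarity(samples, "exnex", control, c("sig_a", "sig_b"))
}

#' Estimate curve similarity with the hierarchical ICC model
#'
#' Two-level bivariate normal model: population-and-compound-specific
#' `(log alpha, log beta)` pairs are drawn around compound means with
#' within-compound (between-population) covariance built from
#' `(tau_alpha, tau_beta, rho_tau)`; compound means are drawn around global
#' means with between-compound covariance from
#' `(sigma_alpha, sigma_beta, rho_sigma)`. Similarity is the intraclass
#' correlation of two population curves from the same compound,
#' \deqn{\zeta = \sigma^2 / (\tau^2 + \sigma^2),}
#' computed per MCMC draw and averaged: it approaches 1 as the
#' between-population variability \eqn{\tau^2} vanishes (identical curves)
#' and 0 as it dominates.
#'
#' @param datasets list of at least two [compound_dataset()] objects.
#' @param hyper a [hierarchical_hyperparams()].
#' @param control an [mcmc_control()].
#' @param seed optional integer seed.
#' @return a `similarity_estimate` (see [fit_exnex()]).
#' @export
fit_hierarchical <- function(datasets, hyper = hierarchical_hyperparams(),
                             control = mcmc_control(), seed = NULL) {
  check_datasets(datasets)
  long <- stack_compounds(datasets)
  J <- length(datasets)
  data <- list(N = nrow(long), J = J, y = long$y, m = long$m, x = long$x,
               comp = long$comp, pop = long$pop,
               m0a = hyper$mean_alpha[1], prec0a = 1 / hyper$mean_alpha[2]^2,
               m0b = hyper$mean_beta[1], prec0b = 1 / hyper$mean_beta[2]^2,
               g_shape = hyper$sd_prior[1], g_rate = hyper$sd_prior[2],
               rho_lo = hyper$rho_bounds[1], rho_hi = hyper$rho_bounds[2])
  inits_fun <- function() {
    th <- array(0, dim = c(J, 2, 2))
    th[, , 1] <- hyper$mean_alpha[1]
    th[, , 2] <- hyper$mean_beta[1]
    list(th = th,
         muc = cbind(rep(hyper$mean_alpha[1], J), rep(hyper$mean_beta[1], J)),
         mug = c(hyper$mean_alpha[1], hyper$mean_beta[1]),
         tau_a = rinit_sd(hyper$sd_prior), tau_b = rinit_sd(hyper$sd_prior),
         sig_a = rinit_sd(hyper$sd_prior), sig_b = rinit_sd(hyper$sd_prior),
         rho_tau = 0, rho_sig = 0)
  }
  samples <- run_jags(hierarchical_model_string, data, inits_fun,
                      c("zeta_a", "zeta_b", "tau_a", "tau_b", "sig_a",
                        "sig_b"), control, seed)
  summarize_similarity(samples, "hierarchical", control,
                       c("tau_a", "tau_b", "sig_a", "sig_b"))
}

# overdispersed chain-specific initial SD, drawn from its prior but kept
# away from degenerate extremes
rinit_sd <- function(prior) {
  min(max(rgamma(1, prior[1], prior[2]), 0.2), 15)
}

check_datasets <- function(datasets) {
  if (!is.list(datasets) || length(datasets) < 2L) {
    stop("at least two compound datasets are required (no pooling possible ",
         "from a single compound)")
  }
  ok <- vapply(datasets, inherits, logical(1), "compound_dataset")
  if (!all(ok)) stop("all elements must be compound_dataset objects")
  invisible(datasets)
}

#' @export
print.similarity_estimate <- function(x, ...) {
  cat(sprintf("similarity estimate (%s model):\n", x$model))
  cat(sprintf("  zeta_alpha = %.3f  [%.3f, %.3f]\n", x$zeta_alpha_mean,
              x$zeta_alpha_ci[1], x$zeta_alpha_ci[2]))
  cat(sprintf("  zeta_beta  = %.3f  [%.3f, %.3f]\n", x$zeta_beta_mean,
              x$zeta_beta_ci[1], x$zeta_beta_ci[2]))
  cat(sprintf("  max split-Rhat %.3f (%s)\n", max(x$diagnostics$rhat),
              if (x$diagnostics$converged) "converged" else "NOT converged"))
  invisible(x)
}
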