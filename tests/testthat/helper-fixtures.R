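# shared fixtures, built in code

fix_grid <- function() default_dose_grid()

# a moderate 40-patient source outcome on the default grid
fix_source_outcome <- function() {
  trial_outcome(rep(8L, 5), c(0L, 1L, 2L, 4L, 5L))
}

# draws from a known bivariate normal, packaged as a minimal blrm_fit-shaped
# object for moment_match
fake_fit_bvn <- function(n, mu, var_a, var_b, rho, seed = 1) {
  set.seed(seed)
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  la <- mu[1] + sqrt(var_a) * z1
  lb <- mu[2] + sqrt(var_b) * (rho * z1 + sqrt(1 - rho^2) * z2)
  structure(list(draws = data.frame(log_alpha = la, log_beta = lb)),
            class = "blrm_fit")
}

# reduced MCMC settings used in simulation-scale tests
study_fit_args <- function() list(chains = 2L, warmup = 300L, iter = 400L,
                                  thin = 1L)
study_jags_control <- function() mcmc_control(chains = 2L, warmup = 400L,
                                              iter = 600L)
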