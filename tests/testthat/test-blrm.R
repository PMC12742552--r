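test_that("dose_toxicity matches the logistic model and its anchor points", {
  # at the reference dose the log-dose term vanishes for any slope
  for (lb in c(-1, 0, 2)) {
    expect_equal(dose_toxicity(-0.84, lb, dose = 10, reference_dose = 10),
                 plogis(-0.84), tolerance = 1e-12)
    expect_equal(dose_toxicity(-2.5, lb, dose = 3, reference_dose = 3),
                 plogis(-2.5), tolerance = 1e-12)
  }
  expect_equal(plogis(-0.84), 0.3015, tolerance = 1e-3)
  expect_equal(plogis(-2.5), 0.0759, tolerance = 1e-3)
  # unit slope, dose = e * reference dose: logit moves by exactly 1
  expect_equal(dose_toxicity(0, 0, dose = exp(1), reference_dose = 1),
               plogis(1), tolerance = 1e-12)
  expect_error(dose_toxicity(0, 0, dose = -1, reference_dose = 1), "positive")
  expect_error(dose_toxicity(0, 0, dose = 1, reference_dose = 0), "positive")
})

test_that("dose_toxicity is strictly increasing in dose and stays in (0,1)", {
  set.seed(11)
  doses <- sort(runif(30, 0.01, 50))
  for (i in 1:20) {
    la <- rnorm(1, -1, 2)
    lb <- rnorm(1, 0, 1)
    p <- dose_toxicity(la, lb, doses, reference_dose = 5)
    expect_true(all(diff(p) > 0))
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("grid and outcome constructors enforce their invariants", {
  expect_error(dose_grid(c(1, 1, 2), 1), "strictly increasing")
  expect_error(dose_grid(c(-1, 2), 1), "positive")
  expect_error(dose_grid(c(1, 2), -3), "positive")
  expect_error(trial_outcome(c(3, 3), c(4, 0)), "cannot exceed")
  expect_error(trial_outcome(c(3, 3), c(1, -1)), "non-negative")
  g <- default_dose_grid(10)
  expect_equal(g$doses, c(2.5, 5, 10, 20, 40))
  expect_equal(g$log_std[3], 0)
  expect_equal(g$log_std, -rev(g$log_std))
})

test_that("prior-only fit reproduces prior moments within Monte-Carlo error", {
  g <- fix_grid()
  empty <- trial_outcome(rep(0L, 5), rep(0L, 5))
  fit <- suppressWarnings(fit_blrm(empty, g, weak_prior(), seed = 301))
  for (par in c("log_alpha", "log_beta")) {
    truth <- if (par == "log_alpha") c(-0.84, 2) else c(0, 1.5)
    expect_lt(abs(mean(fit$draws[[par]]) - truth[1]), 3 * fit_mcse(fit, par))
    expect_equal(sd(fit$draws[[par]]), truth[2], tolerance = 0.1)
  }
  # mixture prior-only fit: moments of the two-component mixture
  src <- bvn_params(1, 0.5, 0.09, 0.04, 0)
  mix <- mixture_prior(src, weak_prior()$weak_part, 0.3, 0.7)
  fitm <- suppressWarnings(fit_blrm(empty, g, mix, seed = 302))
  mix_mean <- function(d, ms, mw) d * ms + (1 - d) * mw
  mix_var <- function(d, ms, vs, mw, vw) {
    m <- mix_mean(d, ms, mw)
    d * (vs + ms^2) + (1 - d) * (vw + mw^2) - m^2
  }
  expect_lt(abs(mean(fitm$draws$log_alpha) - mix_mean(0.3, 1, -0.84)),
            3 * fit_mcse(fitm, "log_alpha"))
  expect_equal(var(fitm$draws$log_alpha), mix_var(0.3, 1, 0.09, -0.84, 4),
               tolerance = 0.15)
  expect_lt(abs(mean(fitm$draws$log_beta) - mix_mean(0.7, 0.5, 0)),
            3 * fit_mcse(fitm, "log_beta"))
})

test_that("posterior concentrates on the binomial MLE when data dominate", {
  # 1000 patients at the reference dose, 300 DLTs: the posterior of the
  # reference-dose toxicity plogis(log_alpha) must sit at 0.30
  g <- fix_grid()
  out <- trial_outcome(c(0L, 0L, 1000L, 0L, 0L), c(0L, 0L, 300L, 0L, 0L))
  fit <- suppressWarnings(fit_blrm(out, g, weak_prior(), seed = 303))
  expect_equal(mean(plogis(fit$draws$log_alpha)), 0.30, tolerance = 0.02)
  # cross-check against the quadrature oracle
  q <- quad_posterior(out, g, weak_prior())
  expect_equal(mean(fit$draws$log_alpha), q$mean_log_alpha, tolerance = 0.02)
})

test_that("single-dose data at the reference dose leave the slope at its prior", {
  g <- fix_grid()
  out <- trial_outcome(c(0L, 0L, 30L, 0L, 0L), c(0L, 0L, 9L, 0L, 0L))
  fit <- suppressWarnings(fit_blrm(out, g, weak_prior(), seed = 304))
  # log(d/dR) = 0 makes the likelihood flat in log_beta
  expect_lt(abs(mean(fit$draws$log_beta) - 0), 3 * fit_mcse(fit, "log_beta"))
  expect_equal(sd(fit$draws$log_beta), 1.5, tolerance = 0.12)
  q <- quad_posterior(out, g, weak_prior())
  expect_equal(mean(fit$draws$log_beta), q$mean_log_beta, tolerance = 0.02)
})

test_that("fits are deterministic given a seed and attach diagnostics", {
  g <- fix_grid()
  out <- fix_source_outcome()
  f1 <- suppressWarnings(fit_blrm(out, g, weak_prior(), seed = 77))
  f2 <- suppressWarnings(fit_blrm(out, g, weak_prior(), seed = 77))
  expect_identical(f1$draws, f2$draws)
  expect_named(f1$diagnostics$rhat, c("log_alpha", "log_beta"))
  expect_true(all(f1$diagnostics$ess > 100))
  expect_equal(nrow(f1$draws), 4000L)
})

test_that("dose recommendation picks the dose closest to theta, ties low", {
  # single-point posterior: recommendation reduces to the true curve
  curve_fit <- function(la, lb) {
    structure(list(draws = data.frame(log_alpha = la, log_beta = lb),
                   grid = fix_grid()), class = "blrm_fit")
  }
  # p = (0.089, 0.162, 0.280, 0.437, 0.608) on the default grid
  fit <- curve_fit(qlogis(0.28), 0)
  expect_equal(recommend_dose(fit, target = target_config(theta = 0.30)), 3L)
  # exact tie broken toward the lower dose
  expect_equal(doseborrow:::closest_dose(c(0.25, 0.35, 0.9), 0.30), 1L)
  expect_equal(doseborrow:::closest_dose(c(0.05, 0.12, 0.28, 0.45, 0.60), 0.3),
               3L)
  # escalation cap: steep curve wants dose 5, but only dose 2 was tried
  fit_hot <- curve_fit(qlogis(0.29) - 4 * log(4), log(4))
  expect_equal(recommend_dose(fit_hot, target = target_config()), 5L)
  expect_equal(recommend_dose(fit_hot, target = target_config(),
                              current_highest_tried = 2L), 3L)
  # cap is inactive when no_skip is off
  expect_equal(recommend_dose(fit_hot,
                              target = target_config(no_skip = FALSE),
                              current_highest_tried = 2L), 5L)
})

test_that("recommendation is invariant to dose relabeling that preserves ordering", {
  fit <- suppressWarnings(fit_blrm(fix_source_outcome(), fix_grid(),
                                   weak_prior(), seed = 55))
  k1 <- recommend_dose(fit, target = target_config())
  # same standardized log doses, different absolute units
  g2 <- dose_grid(c(0.25, 0.5, 1, 2, 4) * 100, reference_dose = 100)
  expect_equal(recommend_dose(fit, grid = g2, target = target_config()), k1)
})

test_that("true_mtd follows the closest-to-theta rule with edge cases", {
  g <- fix_grid()
  # curve with p ~ (0.05, 0.12, 0.28, 0.45, 0.60): dose 3 is closest to 0.3
  expect_equal(true_mtd(dose_tox_curve(qlogis(0.28), 0), g, 0.30), 3L)
  # curve entirely below theta: highest dose
  expect_equal(true_mtd(dose_tox_curve(-6, 0), g, 0.30), 5L)
  # curve entirely above theta: lowest dose
  expect_equal(true_mtd(dose_tox_curve(5, 0), g, 0.30), 1L)
})

test_that("moment_match recovers generating moments from draws", {
  mu <- c(-1, 0.5)
  f <- fake_fit_bvn(50000, mu, 0.3, 0.2, rho = 0.4, seed = 21)
  mm <- moment_match(f)
  n <- 50000
  # sampling-theory standard errors: se(mean) = sd/sqrt(n),
  # se(var) ~ var * sqrt(2/n), se(rho) ~ (1 - rho^2)/sqrt(n)
  expect_lt(abs(mm$mu_alpha - mu[1]), 3 * sqrt(0.3 / n))
  expect_lt(abs(mm$mu_beta - mu[2]), 3 * sqrt(0.2 / n))
  expect_lt(abs(mm$var_alpha - 0.3), 3 * 0.3 * sqrt(2 / n))
  expect_lt(abs(mm$var_beta - 0.2), 3 * 0.2 * sqrt(2 / n))
  expect_lt(abs(mm$rho - 0.4), 3 * (1 - 0.4^2) / sqrt(n))

  # translation equivariance
  f2 <- f
  f2$draws$log_alpha <- f$draws$log_alpha + 10
  mm2 <- moment_match(f2)
  expect_equal(mm2$mu_alpha, mm$mu_alpha + 10)
  expect_equal(mm2$var_alpha, mm$var_alpha)
  expect_equal(mm2$cov_ab, mm$cov_ab)

  # independent draws: recovered correlation is near zero
  f0 <- fake_fit_bvn(50000, mu, 0.3, 0.2, rho = 0, seed = 22)
  expect_lt(abs(moment_match(f0)$rho), 0.03)

  # guards
  expect_error(moment_match(fake_fit_bvn(500, mu, 1, 1, 0)), "1000")
  fc <- fake_fit_bvn(2000, mu, 1, 1, 0)
  fc$draws$log_alpha <- rep(1, 2000)
  expect_error(moment_match(fc), "degenerate")
})

test_that("split_rhat detects disagreeing chains and passes mixed ones", {
  set.seed(9)
  good <- matrix(rnorm(4000), 1000, 4)
  expect_lt(split_rhat(good), 1.01)
  bad <- cbind(matrix(rnorm(2000), 1000, 2), matrix(rnorm(2000, 3), 1000, 2))
  expect_gt(split_rhat(bad), 1.5)
})
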