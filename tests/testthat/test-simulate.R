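test_that("source trial allocates equally, is seeded, and moment-matches", {
  g <- default_dose_grid()
  src <- suppressWarnings(simulate_source_trial(dose_tox_curve(-0.84, 0), g,
                                                seed = 501))
  expect_equal(src$outcome$n_per_dose, rep(8L, 5))
  expect_s3_class(src$posterior, "bvn_params")
  src2 <- suppressWarnings(simulate_source_trial(dose_tox_curve(-0.84, 0), g,
                                                 seed = 501))
  expect_identical(src$outcome, src2$outcome)
  expect_identical(src$posterior, src2$posterior)
  # degenerate curve with (near-)zero toxicity: no DLTs, low estimates
  src0 <- suppressWarnings(simulate_source_trial(dose_tox_curve(-20, 0), g,
                                                 seed = 502))
  expect_equal(src0$outcome$dlt_per_dose, rep(0L, 5))
  expect_lt(mean(plogis(src0$fit$draws$log_alpha)), 0.2)
})

test_that("source posterior means approach the truth as n grows", {
  g <- default_dose_grid()
  src <- suppressWarnings(simulate_source_trial(dose_tox_curve(-0.84, 0.5), g,
                                                n = 4000, seed = 503))
  expect_equal(src$posterior$mu_alpha, -0.84, tolerance = 0.15)
  expect_equal(src$posterior$mu_beta, 0.5, tolerance = 0.15)
  # and agrees with the quadrature oracle on the same data
  q <- quad_posterior(src$outcome, g, weak_prior())
  expect_equal(src$posterior$mu_alpha, q$mean_log_alpha, tolerance = 0.02)
  expect_equal(src$posterior$mu_beta, q$mean_log_beta, tolerance = 0.02)
})

test_that("trial records obey the cohort structure and escalation rules", {
  g <- default_dose_grid()
  set.seed(601)
  for (i in 1:6) {
    curve <- dose_tox_curve(sample(c(-2.5, -0.84), 1), sample(c(0, 1.5), 1))
    rec <- suppressWarnings(do.call(simulate_target_trial, c(
      list(curve, g, weak_prior()), study_fit_args())))
    expect_equal(rec$n_total, 12L)
    expect_equal(rec$cohort_log$n, rep(2L, 6))
    expect_equal(rec$cohort_log$dose[1], 1L)
    expect_true(rec$selected_mtd >= 1 && rec$selected_mtd <= g$K)
    expect_equal(rec$dlt_total, sum(rec$cohort_log$dlt))
    # no_skip: never more than one level above the highest dose tried so far
    high <- cummax(rec$cohort_log$dose)
    if (nrow(rec$cohort_log) > 1) {
      expect_true(all(rec$cohort_log$dose[-1] <= high[-length(high)] + 1L))
    }
  }
})

test_that("a harmless curve escalates one level per cohort to the top dose", {
  g <- default_dose_grid()
  rec <- suppressWarnings(do.call(simulate_target_trial, c(
    list(dose_tox_curve(-20, 0), g, weak_prior(), target_config()),
    study_fit_args(), list(seed = 602))))
  expect_equal(rec$cohort_log$dose, c(1L, 2L, 3L, 4L, 5L, 5L))
  expect_equal(rec$dlt_total, 0L)
  expect_equal(rec$selected_mtd, 5L)
})

test_that("a zero-weight mixture reproduces the weak-prior trial run for run", {
  g <- default_dose_grid()
  curve <- dose_tox_curve(-0.84, 0)
  src <- bvn_params(-0.3, 0.9, 0.09, 0.05, 0.02)
  weak <- weak_prior(means = c(-0.84, 0))
  mix0 <- mixture_prior(src, weak$weak_part, 0, 0)
  r_weak <- suppressWarnings(do.call(simulate_target_trial, c(
    list(curve, g, weak), study_fit_args(), list(seed = 603))))
  r_mix <- suppressWarnings(do.call(simulate_target_trial, c(
    list(curve, g, mix0), study_fit_args(), list(seed = 603))))
  expect_identical(r_weak$cohort_log, r_mix$cohort_log)
  expect_identical(r_weak$selected_mtd, r_mix$selected_mtd)
})

test_that("run_similarity_study collects one zeta pair per replicate", {
  res <- suppressWarnings(run_similarity_study(
    "both_equal", "exnex", n_compounds = 3, n_per_trial = 30, n_sims = 2,
    control = mcmc_control(chains = 2L, warmup = 200L, iter = 200L),
    seed = 604))
  expect_equal(nrow(res), 2L)
  expect_true(all(res$zeta_alpha >= 0 & res$zeta_alpha <= 1))
  expect_true(all(res$zeta_beta >= 0 & res$zeta_beta <= 1))
  expect_true(is.numeric(attr(res, "failure_rate")))
})

test_that("an empty dose-finding study returns an empty result without error", {
  res <- run_dose_finding_study(dose_tox_curve(-0.84, 0),
                                dose_tox_curve(-0.84, 0),
                                strategies = c("weak", "full"), n_sims = 0L)
  expect_s3_class(res, "study_result")
  expect_equal(nrow(res), 0L)
})

test_that("informed strategies require a zeta bank and use it", {
  expect_error(run_dose_finding_study(dose_tox_curve(-0.84, 0),
                                      dose_tox_curve(-0.84, 0),
                                      strategies = "mixture_informed",
                                      n_sims = 1L),
               "zeta_bank")
  bank <- data.frame(zeta_alpha = c(0.9, 0.95), zeta_beta = c(0.85, 0.9))
  res <- suppressWarnings(do.call(run_dose_finding_study, c(list(
    dose_tox_curve(-0.84, 0), dose_tox_curve(-0.84, 0),
    strategies = c("mixture_informed", "inflation_informed"),
    n_sims = 2L, zeta_bank = bank, seed = 605), study_fit_args())))
  expect_equal(nrow(res), 2L)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
  freq <- attr(res, "selection_freq")
  expect_equal(unname(rowSums(freq)), rep(1, 2))
})

test_that("strategy priors are assembled as specified", {
  src <- bvn_params(-0.5, 0.4, 0.3, 0.2, cov_ab = 0.1)
  p_weak <- doseborrow:::build_strategy_prior("weak", src)
  expect_equal(p_weak$kind, "weak")
  # weak strategy borrows the source means but fixed weak variances
  expect_equal(p_weak$weak_part$mu_alpha, -0.5)
  expect_equal(p_weak$weak_part$var_alpha, 4)
  p_full <- doseborrow:::build_strategy_prior("full", src)
  expect_equal(p_full$source_part$var_alpha, 0.3)
  p_mix <- doseborrow:::build_strategy_prior("mixture_fixed", src)
  expect_equal(c(p_mix$delta_alpha, p_mix$delta_beta), c(0.5, 0.5))
  p_inf <- doseborrow:::build_strategy_prior("inflation_fixed", src)
  expect_equal(p_inf$source_part$var_alpha, 0.6)
  p_mi <- doseborrow:::build_strategy_prior("mixture_informed", src,
                                            zeta = c(0.8, 0.2))
  expect_equal(c(p_mi$delta_alpha, p_mi$delta_beta), c(0.8, 0.2))
  p_ii <- doseborrow:::build_strategy_prior("inflation_informed", src,
                                            zeta = c(0.5, 0.5))
  expect_equal(p_ii$omega_alpha, 0.1, tolerance = 1e-12)
})
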