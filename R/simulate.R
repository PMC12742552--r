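#' Simulate the source-population (e.g., adult) dose-finding trial
#'
#' Allocates `n` patients equally across the dose grid, draws binomial DLT
#' counts from the true curve, fits the BLRM under a weakly informative
#' prior and moment-matches the posterior to a bivariate normal — the
#' information package that a target-population trial may borrow.
#'
#' @param curve true [dose_tox_curve()] of the source population.
#' @param grid [dose_grid()].
#' @param n total source-trial sample size (default 40).
#' @param prior prior for the source fit; default [weak_prior()].
#' @param seed optional integer seed.
#' @param ... further arguments to [fit_blrm()] (chains, iter, warmup).
#' @return list with `outcome` ([trial_outcome()]), `fit` (`blrm_fit`) and
#'   `posterior` ([bvn_params()]).
#' @export
simulate_source_trial <- function(curve, grid, n = 40L, prior = weak_prior(),
                                  seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  outcome <- draw_outcome(curve, grid, equal_allocation(n, grid$K))
  fit <- fit_blrm(outcome, grid, prior, ...)
  list(outcome = outcome, fit = fit, posterior = moment_match(fit))
}

#' Simulate one CRM trial in the target population
#'
#' Sequential continual-reassessment trial: the first cohort is treated at
#' the lowest dose; after each cohort the BLRM is refit and the next cohort
#' receives the model-recommended dose (capped at one level above the
#' highest tried when `no_skip` is set). After `n_total` patients the MTD is
#' selected by the recommendation rule on the final posterior over the full
#' grid (set `restrict_to_tried = TRUE` to restrict selection to doses
#' tried or one level above).
#'
#' @param curve true [dose_tox_curve()] of the target population.
#' @param grid [dose_grid()].
#' @param prior a `blrm_prior` built by the priors module.
#' @param target a [target_config()].
#' @param n_total total sample size (default 12).
#' @param cohort_size patients per cohort (default 2).
#' @param start_dose first cohort's dose level (default 1).
#' @param restrict_to_tried restrict final MTD selection to doses tried or
#'   one above (default `FALSE`).
#' @param seed optional integer seed.
#' @param ... further arguments to [fit_blrm()].
#' @return object of class `trial_record` with `cohort_log` (data.frame:
#'   cohort, dose, n, dlt), `selected_mtd`, `n_total`, `dlt_total`.
#' @export
simulate_target_trial <- function(curve, grid, prior,
                                  target = target_config(), n_total = 12L,
                                  cohort_size = 2L, start_dose = 1L,
                                  restrict_to_tried = FALSE, seed = NULL,
                                  ...) {
  stopifnot(n_total >= cohort_size, cohort_size >= 1L)
  if (!is.null(seed)) set.seed(seed)
  p_true <- curve_probs(curve, grid)
  n_cohorts <- n_total %/% cohort_size
  n_k <- integer(grid$K)
  y_k <- integer(grid$K)
  dose <- as.integer(start_dose)
  log_rows <- vector("list", n_cohorts)
  fit <- NULL
  for (co in seq_len(n_cohorts)) {
    dlt <- rbinom(1L, cohort_size, p_true[dose])
    n_k[dose] <- n_k[dose] + cohort_size
    y_k[dose] <- y_k[dose] + dlt
    log_rows[[co]] <- data.frame(cohort = co, dose = dose, n = cohort_size,
                                 dlt = dlt)
    fit <- fit_blrm(trial_outcome(n_k, y_k), grid, prior, ...)
    dose <- recommend_dose(fit, grid, target,
                           current_highest_tried = max(which(n_k > 0L)))
  }
  selected <- if (restrict_to_tried) {
    cap <- min(grid$K, max(which(n_k > 0L)) + 1L)
    sub <- seq_len(cap)
    p_hat <- posterior_tox(fit)[sub]
    as.integer(closest_dose(p_hat, target$theta))
  } else {
    recommend_dose(fit, grid, target, current_highest_tried = NULL)
  }
  structure(list(cohort_log = do.call(rbind, log_rows),
                 selected_mtd = selected, n_total = sum(n_k),
                 dlt_total = sum(y_k), final_fit = fit),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat("CRM trial record:", x$n_total, "patients,", x$dlt_total, "DLTs\n")
  print(x$cohort_log, row.names = FALSE)
  cat("selected MTD: dose", x$selected_mtd, "\n")
  invisible(x)
}

#' Repeated similarity estimation under a data-generating scenario
#'
#' Repeatedly generates historical compounds with [generate_compounds()] and
#' fits the chosen similarity model, collecting the posterior mean
#' similarity parameters — the sampling distribution of
#' \eqn{\hat\zeta_\alpha, \hat\zeta_\beta} under that scenario.
#'
#' @param scenario one of [similarity_scenarios()].
#' @param model `"exnex"` or `"hierarchical"`.
#' @param n_compounds,n_per_trial generator settings.
#' @param n_sims number of replicates.
#' @param control [mcmc_control()] for the similarity fits; study-scale runs
#'   typically reduce chains/iterations.
#' @param grid dose grid for the generated trials.
#' @param seed optional integer seed for the whole study.
#' @return data.frame with one row per replicate: `zeta_alpha`, `zeta_beta`,
#'   `converged`; convergence failure rate in `attr(, "failure_rate")`.
#' @export
run_similarity_study <- function(scenario, model = c("exnex", "hierarchical"),
                                 n_compounds, n_per_trial, n_sims,
                                 control = mcmc_control(chains = 2L,
                                                        warmup = 400L,
                                                        iter = 600L),
                                 grid = default_dose_grid(), seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  fitter <- if (model == "exnex") fit_exnex else fit_hierarchical
  rows <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    datasets <- generate_compounds(scenario, n_compounds, n_per_trial,
                                   grid = grid)
    est <- suppressWarnings(fitter(datasets, control = control))
    rows[[i]] <- data.frame(sim = i, zeta_alpha = est$zeta_alpha_mean,
                            zeta_beta = est$zeta_beta_mean,
                            converged = est$diagnostics$converged)
  }
  out <- do.call(rbind, rows)
  attr(out, "failure_rate") <- mean(!out$converged)
  attr(out, "scenario") <- scenario
  attr(out, "model") <- model
  out
}

#' Borrowing strategies for the dose-finding study
#'
#' @return character vector of the built-in strategy names: weakly
#'   informative (`"weak"`, borrows source posterior means only), full
#'   borrowing (`"full"`), fixed defaults (`"mixture_fixed"` with
#'   `delta = 0.5`, `"inflation_fixed"` with `omega = 0.5`), and informed
#'   variants (`"mixture_informed"`, `"inflation_informed"`) whose weights
#'   come from estimated similarity.
#' @export
borrowing_strategies <- function() {
  c("weak", "full", "mixture_fixed", "inflation_fixed",
    "mixture_informed", "inflation_informed")
}

# build the target-trial prior for one strategy from the source posterior;
# zeta: c(zeta_alpha, zeta_beta) for the informed strategies
build_strategy_prior <- function(strategy, source_post, zeta = NULL,
                                 base = 0.01, weak_sds = c(2, 1.5)) {
  weak_at_source <- bvn_params(source_post$mu_alpha, source_post$mu_beta,
                               weak_sds[1]^2, weak_sds[2]^2, 0)
  switch(strategy,
    weak = new_prior("weak", weak_part = weak_at_source),
    full = full_borrowing_prior(source_post),
    mixture_fixed = mixture_prior(source_post, weak_at_source, 0.5, 0.5),
    inflation_fixed = inflated_prior(source_post, 0.5, 0.5),
    mixture_informed = {
      d <- similarity_to_delta(zeta)
      mixture_prior(source_post, weak_at_source, d[1], d[2])
    },
    inflation_informed = {
      w <- similarity_to_omega(zeta, base)
      inflated_prior(source_post, w[1], w[2])
    },
    stop("unknown strategy: ", strategy))
}

#' Operating characteristics of borrowing strategies in the CRM design
#'
#' For each replicate: simulate a fresh source trial from the source curve
#' (so estimation noise in the borrowed posterior propagates), build the
#' prior for every strategy from the same source posterior, run the target
#' CRM trial, and score the selected MTD against the true target MTD. The
#' informed strategies draw their similarity estimates per replicate from
#' `zeta_bank`, a matrix of `(zeta_alpha, zeta_beta)` posterior means
#' pre-computed with [run_similarity_study()] under the matching scenario.
#'
#' @param source_curve,target_curve true [dose_tox_curve()]s.
#' @param strategies subset of [borrowing_strategies()].
#' @param n_sims replicates per strategy; `0` returns an empty result.
#' @param grid [dose_grid()].
#' @param target [target_config()].
#' @param zeta_bank matrix/data.frame with columns `zeta_alpha`,
#'   `zeta_beta`; required if an informed strategy is requested.
#' @param source_n source-trial sample size (default 40).
#' @param n_total,cohort_size target-trial size (defaults 12, 2).
#' @param base transformation base for informed variance inflation.
#' @param seed optional integer seed.
#' @param ... further arguments to [fit_blrm()].
#' @return data.frame of class `study_result`: one row per strategy with
#'   `accuracy`, `mcse` (binomial Monte-Carlo standard error), `mean_dlt`,
#'   `n_sims`; per-dose selection frequencies in
#'   `attr(, "selection_freq")`.
#' @export
run_dose_finding_study <- function(source_curve, target_curve,
                                   strategies = borrowing_strategies(),
                                   n_sims = 200L,
                                   grid = default_dose_grid(),
                                   target = target_config(),
                                   zeta_bank = NULL, source_n = 40L,
                                   n_total = 12L, cohort_size = 2L,
                                   base = 0.01, seed = NULL, ...) {
  strategies <- match.arg(strategies, borrowing_strategies(),
                          several.ok = TRUE)
  informed <- grepl("informed", strategies)
  if (any(informed) && is.null(zeta_bank)) {
    stop("zeta_bank is required for informed strategies")
  }
  if (!is.null(seed)) set.seed(seed)
  mtd_true <- true_mtd(target_curve, grid, target$theta)
  if (n_sims == 0L) {
    out <- data.frame(strategy = character(0), accuracy = numeric(0),
                      mcse = numeric(0), mean_dlt = numeric(0),
                      n_sims = integer(0))
    attr(out, "true_mtd") <- mtd_true
    class(out) <- c("study_result", class(out))
    return(out)
  }
  sel <- matrix(0L, length(strategies), grid$K,
                dimnames = list(strategies, NULL))
  hit <- matrix(NA, n_sims, length(strategies),
                dimnames = list(NULL, strategies))
  dlt <- matrix(NA_real_, n_sims, length(strategies))
  for (i in seq_len(n_sims)) {
    # source fit at full default MCMC settings: its moment-matched posterior
    # seeds every strategy's prior, so it is not run at reduced settings
    src <- simulate_source_trial(source_curve, grid, n = source_n)
    zeta <- if (!is.null(zeta_bank)) {
      zb <- zeta_bank[sample(nrow(zeta_bank), 1L), , drop = TRUE]
      c(as.numeric(zb[["zeta_alpha"]]), as.numeric(zb[["zeta_beta"]]))
    }
    for (s in seq_along(strategies)) {
      prior <- build_strategy_prior(strategies[s], src$posterior, zeta, base)
      rec <- simulate_target_trial(target_curve, grid, prior, target,
                                   n_total = n_total,
                                   cohort_size = cohort_size, ...)
      hit[i, s] <- rec$selected_mtd == mtd_true
      dlt[i, s] <- rec$dlt_total
      sel[s, rec$selected_mtd] <- sel[s, rec$selected_mtd] + 1L
    }
  }
  acc <- colMeans(hit)
  out <- data.frame(strategy = strategies,
                    accuracy = as.numeric(acc),
                    mcse = sqrt(pmax(acc * (1 - acc), 0) / n_sims),
                    mean_dlt = colMeans(dlt),
                    n_sims = n_sims, row.names = NULL)
  attr(out, "selection_freq") <- sel / n_sims
  attr(out, "true_mtd") <- mtd_true
  class(out) <- c("study_result", class(out))
  out
}
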