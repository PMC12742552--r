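#' Similarity scenarios for historical-compound generation
#'
#' @return character vector of the four scenario names.
#' @export
similarity_scenarios <- function() {
  c("both_equal", "alpha_equal_beta_diff", "alpha_diff_beta_equal",
    "both_diff")
}

#' Generate historical compounds with paired source/target trials
#'
#' Emulates the data-generating process of the similarity simulation study:
#' every compound's source-population curve takes `(log alpha, log beta)`
#' uniformly from the four combinations of `alpha_values x beta_values`
#' (defaults `{-2.5, -0.84} x {0, 1.5}`); the target-population curve keeps
#' a parameter equal or switches it to the *other* value of its two-point
#' set, according to the similarity scenario. Both populations are then
#' tested on the same dose grid with the trial sample size spread equally
#' over the dose levels (any remainder allocated to the lowest doses) and
#' binomial DLT counts drawn from the true curves.
#'
#' @param scenario one of [similarity_scenarios()].
#' @param n_compounds number of compounds (the study used 3, 7 or 20).
#' @param n_per_trial patients per trial per population (30 or 100 in the
#'   study).
#' @param grid [dose_grid()] shared by all trials; default
#'   [default_dose_grid()].
#' @param alpha_values,beta_values the two-point parameter sets.
#' @param seed optional integer seed; generation is deterministic given it.
#' @param param_sampler optional function `(scenario)` returning a list
#'   `(source = c(log_alpha, log_beta), target = c(log_alpha, log_beta))` to
#'   replace the fixed two-point mechanism entirely.
#' @return list of [compound_dataset()] objects, with the generating
#'   parameters attached as `attr(, "true_params")` (data.frame).
#' @export
generate_compounds <- function(scenario, n_compounds, n_per_trial,
                               grid = default_dose_grid(),
                               alpha_values = c(-2.5, -0.84),
                               beta_values = c(0, 1.5),
                               seed = NULL, param_sampler = NULL) {
  scenario <- match.arg(scenario, similarity_scenarios())
  stopifnot(n_compounds >= 1L, n_per_trial >= grid$K)
  if (!is.null(seed)) set.seed(seed)
  n_k <- equal_allocation(n_per_trial, grid$K)

  params <- vector("list", n_compounds)
  datasets <- vector("list", n_compounds)
  for (j in seq_len(n_compounds)) {
    if (is.null(param_sampler)) {
      src <- c(sample(alpha_values, 1L), sample(beta_values, 1L))
      tgt <- src
      if (scenario %in% c("alpha_diff_beta_equal", "both_diff")) {
        tgt[1] <- other_value(src[1], alpha_values)
      }
      if (scenario %in% c("alpha_equal_beta_diff", "both_diff")) {
        tgt[2] <- other_value(src[2], beta_values)
      }
    } else {
      pair <- param_sampler(scenario)
      src <- pair$source; tgt <- pair$target
    }
    datasets[[j]] <- compound_dataset(
      compound_id = sprintf("compound_%02d", j),
      source_grid = grid,
      source_outcome = draw_outcome(dose_tox_curve(src[1], src[2]), grid, n_k),
      target_grid = grid,
      target_outcome = draw_outcome(dose_tox_curve(tgt[1], tgt[2]), grid, n_k))
    params[[j]] <- data.frame(compound_id = datasets[[j]]$compound_id,
                              population = c("source", "target"),
                              log_alpha = c(src[1], tgt[1]),
                              log_beta = c(src[2], tgt[2]))
  }
  attr(datasets, "true_params") <- do.call(rbind, params)
  attr(datasets, "scenario") <- scenario
  datasets
}

other_value <- function(x, values) values[values != x][1L]

# n patients over K doses, remainder to the lowest dose levels
equal_allocation <- function(n, K) {
  base <- n %/% K
  extra <- n %% K
  as.integer(base + (seq_len(K) <= extra))
}

draw_outcome <- function(curve, grid, n_k) {
  p <- curve_probs(curve, grid)
  trial_outcome(n_k, rbinom(grid$K, n_k, p))
}

#' Generate irregular, case-study-shaped compound data (synthetic)
#'
#' Synthetic stand-in for real cross-population dose-escalation tables:
#' per compound, 4 to 9 dose levels, population-specific sample sizes
#' (source 21 to 67 patients, target 14 to 27, the ranges seen in published
#' cross-ethnic dose-escalation data), and some doses tested in only one of
#' the two populations (the first generated compound always has at least one
#' population-exclusive dose on each side). Intended to exercise readers and
#' similarity models under missing-dose patterns; it carries no information
#' about any real compound.
#'
#' @param n_compounds number of compounds (default 6).
#' @param seed optional integer seed.
#' @return list of [compound_dataset()] objects with generating parameters
#'   in `attr(, "true_params")`.
#' @export
generate_case_study_like <- function(n_compounds = 6L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  datasets <- vector("list", n_compounds)
  params <- vector("list", n_compounds)
  for (j in seq_len(n_compounds)) {
    K <- sample(4:9, 1L)
    doses <- round(cumprod(c(runif(1, 10, 50), runif(K - 1L, 1.3, 2))), 1)
    ref <- doses[max(2L, K - 2L)]
    la <- rnorm(1, -0.84, 1)
    lb <- rnorm(1, 0, 0.5)
    # target curve: moderately perturbed source curve
    la_t <- la + rnorm(1, 0, 0.5)
    lb_t <- lb + rnorm(1, 0, 0.3)
    # population-specific dose subsets; force exclusivity in compound 1
    keep_s <- sort(sample(K, max(3L, K - sample(0:2, 1L))))
    keep_t <- sort(sample(K, max(3L, K - sample(0:2, 1L))))
    if (j == 1L) {
      keep_s <- seq_len(K - 1L)
      keep_t <- c(1L, 3:K)
    }
    n_s <- spread_patients(sample(21:67, 1L), length(keep_s))
    n_t <- spread_patients(sample(14:27, 1L), length(keep_t))
    g_s <- dose_grid(doses[keep_s], ref)
    g_t <- dose_grid(doses[keep_t], ref)
    datasets[[j]] <- compound_dataset(
      compound_id = sprintf("synthetic_%02d", j),
      source_grid = g_s,
      source_outcome = draw_outcome(dose_tox_curve(la, lb), g_s, n_s),
      target_grid = g_t,
      target_outcome = draw_outcome(dose_tox_curve(la_t, lb_t), g_t, n_t))
    params[[j]] <- data.frame(compound_id = datasets[[j]]$compound_id,
                              population = c("source", "target"),
                              log_alpha = c(la, la_t), log_beta = c(lb, lb_t))
  }
  attr(datasets, "true_params") <- do.call(rbind, params)
  datasets
}

# sample sizes per dose with a rough escalation shape (more patients at
# intermediate/high doses), at least 1 per dose
spread_patients <- function(n, K) {
  w <- seq_len(K) + 1
  alloc <- pmax(1L, floor(n * w / sum(w)))
  while (sum(alloc) > n) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
  while (sum(alloc) < n) alloc[which.max(w)] <- alloc[which.max(w)] + 1L
  as.integer(alloc)
}
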