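# Parameter-recovery experiments: the package's verification studies.
# The study's raw data are not public, so correctness is demonstrated by
# simulating cohorts from the printed generating truth and measuring how
# the pipeline recovers it.

# Match fitted classes to generating classes by least-squares distance
# between trajectories (resolves label switching; the fitted class nearest
# each generating curve is that class's estimate).
match_classes <- function(fit, truth_beta) {
  X <- wave_basis()
  mu_true <- truth_beta %*% t(X)
  mu_fit <- fitted_trajectories(fit)
  apply(mu_true, 1L, function(m)
    which.min(rowSums((mu_fit - matrix(m, nrow(mu_fit), 3L,
                                       byrow = TRUE))^2)))
}

#' Trajectory-recovery experiment at study scale
#'
#' Simulates cohorts from the default generating truth (printed class
#' proportions, growth coefficients, and within-class wave SDs at n = 473
#' with the study's wave retention), refits the 4-class model, and
#' summarizes recovery: modal shares of the largest (low) and smallest
#' (high) trajectory classes, the decreasing class's linear slope, the high
#' class's quadratic term, entropy, and the mean average posterior
#' probability. Fitted classes are matched to generating classes by nearest
#' trajectory.
#'
#' @param n_reps Number of Monte-Carlo replicates.
#' @param seed Master seed; replicate seeds are derived from it.
#' @param n_starts EM starts per fit.
#' @param n_subjects Cohort size per replicate.
#' @return List with `summary` (means over replicates), `replicates` (the
#'   per-replicate statistics), and `fits` (the fitted models).
#' @export
recovery_experiment <- function(n_reps = 25L, seed = 1L, n_starts = 50L,
                                n_subjects = 473L) {
  truth <- default_growth_coefficients()
  fits <- vector("list", n_reps)
  reps <- matrix(NA_real_, n_reps, 6L,
                 dimnames = list(NULL,
                                 c("largest_share", "smallest_share",
                                   "linear_decreasing", "quadratic_high",
                                   "entropy", "avepp")))
  for (r in seq_len(n_reps)) {
    sim_seed <- derive_seed(seed, paste0("recovery_sim_", r))
    fit_seed <- derive_seed(seed, paste0("recovery_fit_", r))
    d <- simulate_cohort(simulation_spec(n_subjects = n_subjects,
                                         seed = sim_seed))
    fit <- fit_lcga(d, K = 4L, n_starts = n_starts, seed = fit_seed)
    near <- match_classes(fit, truth)
    sh <- tabulate(fit$modal_class, 4L) / fit$n
    app <- average_posterior_probabilities(fit$posteriors, fit$modal_class)
    reps[r, ] <- c(sh[near[1L]] * 100, sh[near[4L]] * 100,
                   fit$params$beta[near[2L], 2L],
                   fit$params$beta[near[4L], 3L],
                   entropy_stat(fit$posteriors), app$mean)
    fits[[r]] <- fit
  }
  list(summary = colMeans(reps), replicates = reps, fits = fits)
}

#' Odds-ratio recovery experiment for the three-step regression
#'
#' Simulates cohorts with a known per-copy genotype log-odds (and
#' optionally a genotype-by-abuse interaction log-odds) on the high-vs-low
#' contrast, runs LCGA, the classification-error matrix, and the corrected
#' multinomial model, and reports the recovered high-vs-low coefficient.
#' The recovered log odds ratio is averaged over replicates to reduce
#' Monte-Carlo error.
#'
#' @param effect `"main"` (per-copy dosage effect, generating OR 3.64) or
#'   `"interaction"` (per-abuse-unit per-copy interaction, generating OR
#'   1.32 alongside the main effect).
#' @param n_reps Number of replicates.
#' @param seed Master seed.
#' @param n_subjects Cohort size per replicate.
#' @param n_starts EM starts per fit.
#' @return List with `or` (exp of the mean recovered log OR),
#'   `generating_or`, and the per-replicate log ORs.
#' @export
or_recovery_experiment <- function(effect = c("main", "interaction"),
                                   n_reps = 10L, seed = 1L,
                                   n_subjects = 5000L, n_starts = 30L) {
  effect <- match.arg(effect)
  gen_or <- if (effect == "main") 3.64 else 1.32
  ef <- list(genotype = c(0, 0, 0, log(3.64)), snp = 2L)
  if (effect == "interaction")
    ef$interaction <- c(0, 0, 0, log(1.32))
  logors <- vapply(seq_len(n_reps), function(r) {
    sim_seed <- derive_seed(seed, paste0("or_", effect, "_sim_", r))
    fit_seed <- derive_seed(seed, paste0("or_", effect, "_fit_", r))
    d <- simulate_cohort(simulation_spec(n_subjects = n_subjects,
                                         effect_spec = ef,
                                         seed = sim_seed))
    fit <- fit_lcga(d, K = 4L, n_starts = n_starts, seed = fit_seed)
    res <- if (effect == "main") run_main_effects_model(d, fit, "snp2")
    else run_interaction_model(d, fit, "snp2")
    pred <- if (effect == "main") "dosage" else "dosage_x_abuse"
    ct <- res$contrasts
    row <- ct[ct$contrast == "high_vs_low" & ct$predictor == pred, ]
    if (nrow(row) != 1L)
      stop("high/low classes not identified in replicate ", r,
           call. = FALSE)
    row$logodds
  }, numeric(1L))
  list(or = exp(mean(logors)), generating_or = gen_or,
       logors = logors, n_reps = n_reps)
}
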