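# Shared fixtures, built in code.

# A small well-separated two-class spec for fast fitting tests.
two_class_spec <- function(n = 200, seed = 1, sds = 4) {
  simulation_spec(
    n_subjects = n,
    class_proportions = c(low = 0.6, high = 0.4),
    growth_coefficients = rbind(low = c(25, 0, 0), high = c(60, -5, 1)),
    wave_residual_sds = matrix(sds, 2, 3),
    snp_mafs = c(snp1 = 0.2),
    dropout = list(w2 = 1, w3 = 1, monotone = FALSE),
    seed = seed)
}

# Study-scale generating truth (printed-table calibration).
study_spec <- function(n = 473, seed = 1, ...) {
  simulation_spec(n_subjects = n, seed = seed, ...)
}

# Closed-form single-class oracle: with a saturated quadratic over three
# waves the MLE mean is each wave's observed mean and the MLE variance each
# wave's observed mean squared deviation, so the maximized log-likelihood
# has the closed form sum_t -n_t/2 * (log(2 pi s2_t) + 1).
one_class_oracle_loglik <- function(dataset) {
  Y <- as.matrix(as.data.frame(dataset)[, c("pts_w1", "pts_w2", "pts_w3")])
  sum(vapply(1:3, function(t) {
    y <- Y[!is.na(Y[, t]), t]
    s2 <- mean((y - mean(y))^2)
    -length(y) / 2 * (log(2 * pi * s2) + 1)
  }, numeric(1L)))
}

# Independent brute-force HWE enumeration used as oracle: enumerate every
# genotype table with the same allele counts directly.
hwe_brute_force <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  nb <- n_ab + 2 * n_bb
  configs <- list()
  for (h in 0:min(nb, 2 * n - nb)) {
    if ((nb - h) %% 2 != 0) next
    bb <- (nb - h) / 2
    aa <- n - h - bb
    if (aa < 0 || bb < 0) next
    configs[[length(configs) + 1L]] <- c(aa = aa, ab = h, bb = bb)
  }
  probs <- vapply(configs, function(cfg) {
    exp(lfactorial(n) - lfactorial(cfg[1]) - lfactorial(cfg[2]) -
          lfactorial(cfg[3]) + cfg[2] * log(2) +
          lfactorial(nb) + lfactorial(2 * n - nb) - lfactorial(2 * n))
  }, numeric(1L))
  probs <- probs / sum(probs)
  obs <- which(vapply(configs, function(cfg) cfg[2] == n_ab, logical(1L)))
  sum(probs[probs <= probs[obs] + 1e-12])
}
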