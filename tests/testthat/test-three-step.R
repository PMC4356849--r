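# Direct simulation of latent class + misclassified modal assignment through
# a KNOWN error matrix D: isolates the corrected estimator from the LCGA
# step. Binary covariate model: true class from a logistic on dosage, modal
# drawn from D rows.
simulate_misclassified <- function(n, beta0, beta1, D, maf = 0.3) {
  dosage <- rbinom(n, 2, maf)
  eta <- beta0 + beta1 * dosage
  pr2 <- 1 / (1 + exp(-eta))
  true <- 1L + rbinom(n, 1, pr2)
  modal <- vapply(true, function(k)
    sample.int(ncol(D), 1L, prob = D[k, ]), integer(1))
  list(dosage = dosage, true = true, modal = modal)
}

test_that("the classification-error matrix tabulates posteriors exactly", {
  tau_sharp <- diag(3)[rep(1:3, 4), ]
  cem <- classification_error_matrix(tau_sharp)
  expect_equal(unname(cem$D), diag(3))
  # uniform posteriors: ties go to class 1, so every row concentrates there
  tau_u <- matrix(0.25, 8, 4)
  cem_u <- classification_error_matrix(tau_u)
  expect_equal(unname(cem_u$D), cbind(1, 0, 0, 0)[rep(1, 4), , drop = FALSE])
  # 4-subject hand example against brute-force weighted tabulation
  tau <- rbind(c(0.7, 0.3), c(0.6, 0.4), c(0.2, 0.8), c(0.5, 0.5))
  modal <- c(1, 1, 2, 1) # row 4 tie -> class 1
  cem_h <- classification_error_matrix(tau, modal)
  expect_equal(unname(cem_h$D),
               rbind(c(0.7 + 0.6 + 0.5, 0.2) / 2.0,
                     c(0.3 + 0.4 + 0.5, 0.8) / 2.0))
  expect_equal(unname(cem_h$class_sizes), c(2, 2))
  expect_equal(rowSums(cem_h$D), c(true1 = 1, true2 = 1), tolerance = 1e-10)
})

test_that("with D = identity the corrected fit equals standard multinomial
          regression", {
  skip_if_not_installed("nnet")
  set.seed(7)
  n <- 600
  x <- rnorm(n)
  g <- rbinom(n, 2, 0.3)
  eta2 <- -0.5 + 0.8 * g - 0.3 * x
  eta3 <- 0.3 - 0.4 * g + 0.5 * x
  pr <- cbind(1, exp(eta2), exp(eta3))
  pr <- pr / rowSums(pr)
  y <- apply(pr, 1, function(p) sample.int(3, 1, prob = p))
  X <- cbind(`(Intercept)` = 1, g = g, x = x)
  fit <- fit_corrected_multinomial(y, diag(3), X, referent = 1)
  oracle <- nnet::multinom(factor(y) ~ g + x, trace = FALSE,
                           reltol = 1e-14)
  expect_equal(unname(fit$coefficients), unname(coef(oracle)),
               tolerance = 1e-4)
  # Wald SEs agree with the oracle's information matrix too
  se_pkg <- sqrt(diag(fit$vcov))
  se_orc <- as.vector(t(summary(oracle)$standard.errors))
  expect_equal(unname(se_pkg), se_orc, tolerance = 1e-3)
})

test_that("odds-ratio transitivity holds across referent rotations", {
  set.seed(11)
  sim <- simulate_misclassified(800, 0.2, 0.7,
                                D = rbind(c(0.85, 0.15), c(0.2, 0.8)))
  X <- cbind(`(Intercept)` = 1, dosage = sim$dosage,
             noise = rnorm(800))
  D3 <- rbind(c(0.8, 0.1, 0.1), c(0.1, 0.8, 0.1), c(0.15, 0.1, 0.75))
  cls <- 1L + (sim$modal - 1L) + rbinom(800, 1, 0.2)
  cls[cls > 3] <- 3L
  fit <- fit_corrected_multinomial(cls, D3, X, referent = 1)
  ct <- fit$contrasts
  for (pred in c("dosage", "noise")) {
    g <- function(a, b) ct$logodds[ct$class_a == a & ct$class_b == b &
                                     ct$predictor == pred]
    expect_lt(abs(g("class1", "class2") + g("class2", "class3") -
                    g("class1", "class3")), 1e-6)
    expect_lt(abs(g("class1", "class2") + g("class2", "class1")), 1e-12)
  }
  # refitting with a different referent reproduces the same contrasts
  fit2 <- fit_corrected_multinomial(cls, D3, X, referent = 3)
  m1 <- ct[order(ct$contrast, ct$predictor), ]
  m2 <- fit2$contrasts[order(fit2$contrasts$contrast,
                             fit2$contrasts$predictor), ]
  expect_equal(m1$logodds, m2$logodds, tolerance = 1e-5)
  expect_equal(m1$se, m2$se, tolerance = 1e-4)
})

test_that("the correction removes the attenuation of modal-class
          regression", {
  # entropy of this D is about 0.8; 200 replicates compare the corrected
  # estimator's bias for the generating log-odds with the naive estimator's
  D <- rbind(c(0.93, 0.07), c(0.18, 0.82))
  beta1 <- log(2.5)
  set.seed(42)
  est <- t(sapply(1:200, function(r) {
    sim <- simulate_misclassified(700, -0.4, beta1, D)
    X <- cbind(`(Intercept)` = 1, dosage = sim$dosage)
    corr <- fit_corrected_multinomial(sim$modal, D, X)$coefficients[1, 2]
    naive <- fit_corrected_multinomial(sim$modal, diag(2),
                                       X)$coefficients[1, 2]
    c(corr = corr, naive = naive)
  }))
  bias_corr <- abs(mean(est[, "corr"]) - beta1)
  bias_naive <- abs(mean(est[, "naive"]) - beta1)
  expect_lt(bias_corr, bias_naive)
  expect_lt(bias_corr, 0.05)
  expect_gt(bias_naive, 0.1)
})

test_that("Wald intervals cover a null effect at their nominal rate", {
  set.seed(13)
  cover <- vapply(1:150, function(r) {
    g <- rbinom(800, 2, 0.25)
    y <- 1L + rbinom(800, 1, 0.35) # class independent of g
    X <- cbind(`(Intercept)` = 1, dosage = g)
    ct <- fit_corrected_multinomial(y, diag(2), X)$contrasts
    row <- ct[ct$predictor == "dosage" & ct$contrast == "class2_vs_class1", ]
    row$ci_lo <= 1 && row$ci_hi >= 1
  }, logical(1))
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("degenerate designs raise rank errors naming the columns", {
  y <- rep(1:2, 50)
  X <- cbind(`(Intercept)` = 1, dosage = rep(0, 100))
  expect_error(fit_corrected_multinomial(y, diag(2), X), "dosage")
  d <- simulate_cohort(two_class_spec(n = 80, seed = 3))
  d$cts_total[] <- 0L
  d[paste0("cts_i", 1:6)] <- 0L
  fit <- fit_lcga(d, K = 2, n_starts = 4, seed = 1)
  expect_error(run_interaction_model(d, fit, "snp1"), "collinear")
})

test_that("main-effects and interaction models recover generating odds
          ratios through the full pipeline", {
  # moderate scale here (n = 2500); the full n = 5000 runs live in the
  # acceptance suite
  ef <- list(genotype = c(0, 0, 0, log(3.64)), snp = 2L)
  d <- simulate_cohort(study_spec(n = 2500, seed = 19, effect_spec = ef))
  fit <- fit_lcga(d, K = 4, n_starts = 10, seed = 4)
  res <- run_main_effects_model(d, fit, "snp2")
  ct <- res$contrasts
  row <- ct[ct$contrast == "high_vs_low" & ct$predictor == "dosage", ]
  expect_lt(abs(row$logodds - log(3.64)), 3 * row$se)
  expect_equal(res$model_tag, "main")
  expect_setequal(unique(ct$predictor),
                  c("(Intercept)", "dosage", "age", "female", "pc1", "pc2"))
  # interaction model carries the product term and all main effects
  res_i <- run_interaction_model(d, fit, "snp2")
  expect_true(all(c("abuse", "dosage_x_abuse") %in%
                    res_i$contrasts$predictor))
})

test_that("Bonferroni flags follow the alpha / n_snps rule", {
  ct <- data.frame(p_value = c(0.03, 0.024, 0.06))
  out2 <- apply_bonferroni(ct, n_snps = 2)
  expect_equal(out2$sig_nominal, c(TRUE, TRUE, FALSE))
  expect_equal(out2$sig_corrected, c(FALSE, TRUE, FALSE))
  expect_equal(attr(out2, "bonferroni_alpha"), 0.025)
  out1 <- apply_bonferroni(ct, n_snps = 1)
  expect_equal(attr(out1, "bonferroni_alpha"), 0.05)
  expect_equal(out1$sig_nominal, out1$sig_corrected)
})
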