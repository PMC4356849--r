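# Fit object with prescribed fitted wave means, for label/plot tests.
fake_fit <- function(means, pi = NULL, sigma2 = c(1, 1, 1)) {
  X <- cbind(1, 0:2, (0:2)^2)
  beta <- t(apply(means, 1, function(m) solve(X, m)))
  K <- nrow(beta)
  if (is.null(pi)) pi <- rep(1 / K, K)
  structure(list(params = lcga_parameters(pi, beta, sigma2), n = 10),
            class = "lcga_fit")
}

test_that("class density multiplies Normal densities over observed waves", {
  # subject exactly on the curve with unit SDs: phi(0)^3
  beta <- c(40, -5, 1)
  y <- beta[1] + beta[2] * (0:2) + beta[3] * (0:2)^2
  expect_equal(class_density(y, class_beta = beta,
                             class_sigma = c(1, 1, 1)),
               (2 * pi)^(-3 / 2))
  # one observed wave, 2 SD above the mean: phi(2) / sigma
  expect_equal(class_density(c(beta[1] + 6, NA, NA), class_beta = beta,
                             class_sigma = c(3, 1, 1)),
               dnorm(2) / 3)
  # steep-decline mean curve evaluated at t = 1
  dec <- c(53.53, -33.76, 11.73)
  expect_equal(dec[1] + dec[2] + dec[3], 31.50)
  expect_error(class_density(c(NA, NA, NA), class_beta = beta,
                             class_sigma = c(1, 1, 1)), "observed wave")
})

test_that("the E-step reproduces Bayes-rule arithmetic", {
  params <- lcga_parameters(
    pi = c(0.4, 0.6),
    beta = rbind(c(30, 0, 0), c(50, -2, 1)),
    sigma2 = c(4, 9, 16))
  Y <- rbind(c(31, 29, 33), c(49, 50, 47), c(40, NA, 40))
  df <- data.frame(pts_w1 = Y[, 1], pts_w2 = Y[, 2], pts_w3 = Y[, 3])
  tau <- e_step(df, params)
  # independent hand computation, subject by subject
  for (i in 1:3) {
    mu <- params$beta %*% rbind(1, 0:2, (0:2)^2)
    lik <- vapply(1:2, function(k) {
      obs <- !is.na(Y[i, ])
      prod(dnorm(Y[i, obs], mu[k, obs], sqrt(params$sigma2[obs])))
    }, numeric(1))
    post <- params$pi * lik / sum(params$pi * lik)
    expect_equal(unname(tau[i, ]), post, tolerance = 1e-12)
  }
  expect_equal(unname(rowSums(tau)), rep(1, 3), tolerance = 1e-12)
})

test_that("E-step limits: symmetry gives 1/2, separation gives certainty", {
  params <- lcga_parameters(pi = c(0.5, 0.5),
                            beta = rbind(c(30, 0, 0), c(40, 0, 0)),
                            sigma2 = c(1, 1, 1))
  df <- data.frame(pts_w1 = 35, pts_w2 = 35, pts_w3 = 35)
  expect_equal(unname(e_step(df, params)[1, ]), c(0.5, 0.5))
  params2 <- lcga_parameters(pi = c(0.5, 0.5),
                             beta = rbind(c(30, 0, 0), c(130, 0, 0)),
                             sigma2 = c(100, 100, 100))
  df2 <- data.frame(pts_w1 = 30, pts_w2 = 30, pts_w3 = 30)
  expect_gt(e_step(df2, params2)[1, 1], 0.999999)
})

test_that("M-step recovers generating curves from degenerate posteriors", {
  spec <- two_class_spec(n = 50, seed = 2)
  spec$wave_residual_sds <- matrix(0, 2, 3)
  d <- simulate_cohort(spec)
  tau <- cbind(d$true_class == 1, d$true_class == 2) * 1
  params <- m_step(d, tau)
  expect_equal(unname(params$beta),
               unname(spec$growth_coefficients), tolerance = 1e-9)
  # all-equal posteriors force all classes onto the pooled fit
  d2 <- simulate_cohort(two_class_spec(n = 80, seed = 5))
  tau2 <- matrix(0.5, 80, 2)
  p2 <- m_step(d2, tau2)
  expect_equal(p2$beta[1, ], p2$beta[2, ], tolerance = 1e-10)
  expect_equal(unname(p2$pi), c(0.5, 0.5))
})

test_that("K = 1 matches the closed-form single-class oracle", {
  d <- simulate_cohort(study_spec(n = 150, seed = 44))
  fit <- fit_lcga(d, K = 1, n_starts = 3, seed = 1)
  expect_lt(abs(fit$loglik - one_class_oracle_loglik(d)), 1e-6)
  # fitted means are the observed wave means (saturated quadratic)
  mu <- fitted_trajectories(fit)
  Y <- as.matrix(as.data.frame(d)[, c("pts_w1", "pts_w2", "pts_w3")])
  expect_equal(unname(mu[1, ]), unname(colMeans(Y, na.rm = TRUE)),
               tolerance = 1e-6)
})

test_that("noise-free two-class data is recovered exactly with entropy 1", {
  spec <- two_class_spec(n = 60, seed = 9)
  spec$wave_residual_sds <- matrix(0, 2, 3)
  d <- simulate_cohort(spec)
  fit <- fit_lcga(d, K = 2, n_starts = 6, seed = 2)
  # canonical order is descending mean trajectory: high first
  expect_equal(unname(fit$params$beta),
               unname(spec$growth_coefficients[2:1, ]), tolerance = 1e-8)
  expect_equal(entropy_stat(fit$posteriors), 1, tolerance = 1e-10)
  expect_equal(sort(fit$modal_class), sort(3L - d$true_class))
})

test_that("EM log-likelihood is monotone and matches its recomputation", {
  d <- simulate_cohort(study_spec(n = 200, seed = 7))
  fit <- fit_lcga(d, K = 3, n_starts = 8, seed = 11)
  expect_true(all(diff(fit$ll_trace) > -1e-8))
  expect_lt(abs(lcga_loglik(fit, d) - fit$loglik), 1e-6)
  expect_equal(unname(rowSums(fit$posteriors)), rep(1, 200),
               tolerance = 1e-8)
  expect_true(all(fit$posteriors >= 0 & fit$posteriors <= 1))
  expect_equal(sum(fit$params$pi), 1, tolerance = 1e-10)
})

test_that("subject order does not change the canonical solution", {
  d <- simulate_cohort(two_class_spec(n = 120, seed = 13))
  fit1 <- fit_lcga(d, K = 2, n_starts = 6, seed = 3)
  perm <- sample(nrow(d))
  d2 <- as_pts_cohort(as.data.frame(d)[perm, ])
  fit2 <- fit_lcga(d2, K = 2, n_starts = 6, seed = 3)
  expect_equal(fit1$params$beta, fit2$params$beta, tolerance = 1e-4)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-6)
  expect_equal(fit2$posteriors, fit1$posteriors[perm, ], tolerance = 1e-4)
})

test_that("growth parameters are recovered from study-scale simulations", {
  # one cohort at triple study scale; fitted classes are matched to
  # generating classes by nearest trajectory to resolve label switching.
  # Monte-Carlo bounds are generous; the 25-replicate study-scale
  # experiment lives in the acceptance suite.
  truth <- default_growth_coefficients()
  X <- cbind(1, 0:2, (0:2)^2)
  mu_true <- truth %*% t(X)
  d <- simulate_cohort(study_spec(n = 1500, seed = 101))
  fit <- fit_lcga(d, K = 4, n_starts = 30, seed = 1)
  mu <- fitted_trajectories(fit)
  near <- apply(mu_true, 1, function(m)
    which.min(rowSums((mu - matrix(m, 4, 3, byrow = TRUE))^2)))
  # every generating class has a distinct fitted counterpart
  expect_setequal(near, 1:4)
  # coefficients recovered within ~2 SE of the hardest (smallest) class
  expect_lt(max(abs(fit$params$beta[near, ] - truth)), 10)
  expect_equal(unname(fit$params$pi[near]),
               c(0.681, 0.173, 0.080, 0.066), tolerance = 0.25)
})

test_that("modal export carries labels plus all class probabilities", {
  d <- simulate_cohort(two_class_spec(n = 50, seed = 17))
  fit <- fit_lcga(d, K = 2, n_starts = 4, seed = 1)
  exp_tab <- assign_modal_class(fit, d$subject_id)
  expect_named(exp_tab, c("subject_id", "modal_class", "class1", "class2"))
  expect_equal(rowSums(exp_tab[, c("class1", "class2")]), rep(1, 50),
               tolerance = 1e-8)
  expect_equal(exp_tab$modal_class,
               apply(fit$posteriors, 1, which.max))
})

test_that("trajectory labels follow the cut-off rules", {
  means <- rbind(c(26.6, 25.7, 24.7),
                 c(53.5, 30.7, 32.5),
                 c(37.9, 53.1, 54.5),
                 c(70.1, 52.9, 60.9))
  f <- fake_fit(means)
  expect_equal(label_trajectories(f),
               c("low", "decreasing", "increasing", "high"))
  # boundary: the rule is >= cutoff
  expect_equal(label_trajectories(fake_fit(rbind(c(45, 45, 45)))), "high")
  expect_equal(label_trajectories(fake_fit(rbind(c(44, 44, 44)))), "high")
  # a pattern matching no rule keeps its index name
  expect_equal(label_trajectories(fake_fit(rbind(c(50, 30, 50)))),
               "class_1")
})
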