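# Latent class growth analysis: a K-component mixture of quadratic mean
# trajectories over waves t = 0, 1, 2 in which the within-class growth-factor
# variances are fixed at zero, so each class contributes a deterministic mean
# curve plus wave-specific Gaussian residual noise. Estimation is by
# multi-start (E)CM with an observed-data likelihood over the waves each
# subject completed (MAR).

wave_basis <- function(times = 0:2) cbind(1, times, times^2)

# Extract the n x 3 score matrix and observation mask from a cohort.
pts_matrix <- function(dataset) {
  cols <- c("pts_w1", "pts_w2", "pts_w3")
  if (!all(cols %in% names(dataset)))
    stop("dataset must have columns pts_w1, pts_w2, pts_w3", call. = FALSE)
  Y <- as.matrix(as.data.frame(dataset)[, cols])
  storage.mode(Y) <- "double"
  M <- 1 * !is.na(Y)
  if (any(rowSums(M) == 0))
    stop("subjects with no observed waves: rows ",
         paste(utils::head(which(rowSums(M) == 0), 5L), collapse = ", "),
         call. = FALSE)
  list(Y = Y, M = M, Y0 = ifelse(is.na(Y), 0, Y))
}

# sigma2 handling: either a length-3 vector (wave-specific, class-invariant,
# the default) or a K x 3 matrix (per class per wave).
sigma2_row <- function(sigma2, k) {
  if (is.matrix(sigma2)) sigma2[k, ] else sigma2
}

#' Construct an LCGA parameter set
#'
#' @param pi Class mixing proportions, summing to 1.
#' @param beta K x 3 matrix of per-class (intercept, linear, quadratic)
#'   growth coefficients.
#' @param sigma2 Residual variances: length-3 vector (wave-specific, shared
#'   across classes) or K x 3 matrix (per class per wave).
#' @param wave_times Wave time codes; fixed design `t = 0, 1, 2`.
#' @return An `lcga_parameters` object.
#' @export
lcga_parameters <- function(pi, beta, sigma2, wave_times = 0:2) {
  K <- length(pi)
  if (abs(sum(pi) - 1) > 1e-10 || any(pi <= 0))
    stop("pi must be positive and sum to 1 within 1e-10", call. = FALSE)
  if (!is.matrix(beta) || nrow(beta) != K || ncol(beta) != 3L)
    stop("beta must be a K x 3 matrix", call. = FALSE)
  if (any(unlist(sigma2) <= 0))
    stop("all residual variances must be > 0", call. = FALSE)
  structure(list(K = K, pi = as.numeric(pi), beta = beta, sigma2 = sigma2,
                 wave_times = wave_times),
            class = "lcga_parameters")
}

#' Number of free parameters of an LCGA model
#'
#' `(K - 1)` mixing proportions + `3K` growth coefficients + the free
#' residual variances (3 if wave-specific and class-invariant, `3K` if per
#' class). Always recomputed from the parameter object, never stored.
#'
#' @param params An `lcga_parameters` object.
#' @return Integer count of free parameters.
#' @export
n_params <- function(params) {
  nsig <- if (is.matrix(params$sigma2)) length(params$sigma2) else
    length(params$sigma2)
  (params$K - 1L) + 3L * params$K + nsig
}

# n x K matrix of per-class log density contributions.
loglik_matrix <- function(Y0, M, params) {
  K <- params$K
  X <- wave_basis(params$wave_times)
  mu <- params$beta %*% t(X) # K x 3
  n <- nrow(Y0)
  ll <- matrix(0, n, K)
  for (k in seq_len(K)) {
    s2 <- sigma2_row(params$sigma2, k)
    MU <- matrix(mu[k, ], n, 3L, byrow = TRUE)
    R2 <- (Y0 - MU)^2 * M
    ll[, k] <- -(M %*% (0.5 * log(2 * pi * s2))) - R2 %*% (1 / (2 * s2))
  }
  ll
}

#' Class-conditional density of one subject's score series
#'
#' The product over observed waves of the Normal density at the class mean
#' curve; missing waves contribute nothing (observed-data likelihood under
#' MAR).
#'
#' @param pts_scores Length-3 numeric vector of wave scores (NA allowed).
#' @param wave_mask Logical/0-1 vector marking observed waves; defaults to
#'   the non-missing entries of `pts_scores`.
#' @param class_beta Length-3 (intercept, linear, quadratic) coefficients.
#' @param class_sigma Length-3 residual SDs per wave.
#' @param log Return the log density?
#' @return The (log) likelihood contribution.
#' @export
class_density <- function(pts_scores, wave_mask = !is.na(pts_scores),
                          class_beta, class_sigma, log = FALSE) {
  obs <- which(as.logical(wave_mask))
  if (length(obs) == 0L)
    stop("all waves missing: at least one observed wave is required",
         call. = FALSE)
  tt <- (0:2)[obs]
  mu <- class_beta[1L] + class_beta[2L] * tt + class_beta[3L] * tt^2
  ll <- sum(stats::dnorm(pts_scores[obs], mu, class_sigma[obs], log = TRUE))
  if (log) ll else exp(ll)
}

#' E-step: posterior class membership probabilities
#'
#' Bayes' rule in log space: `tau_ik` proportional to
#' `pi_k * f_k(y_i)`, rows normalized.
#'
#' @param dataset A `pts_cohort` (or data frame with `pts_w1..pts_w3`).
#' @param params An `lcga_parameters` object.
#' @return An n x K posterior matrix whose rows sum to 1.
#' @export
e_step <- function(dataset, params) {
  d <- pts_matrix(dataset)
  e_step_mat(d$Y0, d$M, params)$tau
}

e_step_mat <- function(Y0, M, params) {
  lp <- loglik_matrix(Y0, M, params)
  lp <- sweep(lp, 2L, log(params$pi), `+`)
  lse <- log_row_sum_exp(lp)
  tau <- exp(lp - lse)
  list(tau = tau, loglik = sum(lse))
}

#' M-step: parameter update given posteriors
#'
#' Mixing proportions are posterior means; growth coefficients solve the
#' tau-weighted (inverse-variance weighted) least-squares fit of observed
#' scores on `(1, t, t^2)`; residual variances are tau-weighted mean squared
#' residuals per wave, pooled over classes by default. Weighted sums skip
#' missing waves.
#'
#' @param dataset A `pts_cohort`.
#' @param tau n x K posterior matrix with rows summing to 1.
#' @param residual `"wave"` (class-invariant, the default) or `"class_wave"`.
#' @param sigma2 Current residual variances used as weights for the
#'   coefficient update; defaults to equal weights.
#' @return An `lcga_parameters` object.
#' @export
m_step <- function(dataset, tau, residual = c("wave", "class_wave"),
                   sigma2 = NULL) {
  residual <- match.arg(residual)
  d <- pts_matrix(dataset)
  m_step_mat(d$Y0, d$M, tau, residual, sigma2)
}

m_step_mat <- function(Y0, M, tau, residual = "wave", sigma2 = NULL) {
  n <- nrow(Y0)
  K <- ncol(tau)
  X <- wave_basis()
  if (is.null(sigma2)) sigma2 <- rep(1, 3L)
  w_class <- colSums(tau)
  if (min(w_class) < 1e-6)
    stop("degenerate class: total posterior weight below 1e-6",
         call. = FALSE)
  pi_new <- w_class / n
  Wkt <- t(tau) %*% M          # K x 3 total weight per class per wave
  Skt <- t(tau) %*% (Y0 * M)   # K x 3 weighted score sums
  beta <- matrix(0, K, 3L,
                 dimnames = list(NULL, c("intercept", "linear", "quadratic")))
  for (k in seq_len(K)) {
    s2 <- sigma2_row(sigma2, k)
    A <- t(X) %*% (X * (Wkt[k, ] / s2))
    b <- t(X) %*% (Skt[k, ] / s2)
    bk <- tryCatch(solve(A, b), error = function(e)
      stop("degenerate class: singular weighted design for class ", k,
           call. = FALSE))
    beta[k, ] <- bk
  }
  mu <- beta %*% t(X)
  num <- matrix(0, K, 3L)
  for (k in seq_len(K)) {
    MU <- matrix(mu[k, ], n, 3L, byrow = TRUE)
    num[k, ] <- colSums(tau[, k] * (Y0 - MU)^2 * M)
  }
  if (residual == "wave") {
    s2_new <- colSums(num) / colSums(M)
  } else {
    s2_new <- num / Wkt
  }
  if (any(unlist(s2_new) < 1e-4)) {
    # A collapsing residual variance is spurious (a start chasing a
    # singularity) unless classification is already essentially perfect, the
    # noise-free separated limit, where the MLE sits at the boundary.
    separated <- all(apply(tau, 1L, max) > 1 - 1e-6)
    if (!separated)
      stop("degenerate fit: residual variance collapsed below 1e-4",
           call. = FALSE)
    if (is.matrix(s2_new)) s2_new <- pmax(s2_new, 1e-10)
    else s2_new <- pmax(s2_new, 1e-10)
  }
  lcga_parameters(pi_new, beta, s2_new)
}

em_run <- function(Y0, M, params, residual, tol, max_iter) {
  ll_old <- -Inf
  trace <- numeric(0L)
  for (iter in seq_len(max_iter)) {
    es <- e_step_mat(Y0, M, params)
    trace <- c(trace, es$loglik)
    if (is.finite(ll_old) &&
        abs(es$loglik - ll_old) < tol * abs(ll_old)) {
      return(list(params = params, loglik = es$loglik, tau = es$tau,
                  converged = TRUE, n_iter = iter, ll_trace = trace))
    }
    ll_old <- es$loglik
    params <- m_step_mat(Y0, M, es$tau, residual, params$sigma2)
  }
  es <- e_step_mat(Y0, M, params)
  list(params = params, loglik = es$loglik, tau = es$tau,
       converged = FALSE, n_iter = max_iter, ll_trace = c(trace, es$loglik))
}

# Starting values, three families: k-means on mean-imputed wave scores,
# randomly drawn subjects as class-curve seeds, and random perturbations of
# the pooled quadratic fit. Mixtures of curves are multimodal — in
# particular, when one class dominates, k-means keeps splitting the big
# cluster — so diverse start families are needed for coverage.
make_start <- function(Y0, M, K, kind) {
  n <- nrow(Y0)
  Yimp <- Y0
  for (t in 1:3) {
    m_t <- sum(Y0[, t] * M[, t]) / max(sum(M[, t]), 1)
    Yimp[M[, t] == 0, t] <- m_t
  }
  sdy <- stats::sd(Y0[M == 1])
  if (kind == "kmeans" && K > 1L) {
    km <- suppressWarnings(stats::kmeans(Yimp, centers = K, nstart = 3L))
    tau <- matrix(1e-3, n, K)
    tau[cbind(seq_len(n), km$cluster)] <- 1
    tau <- tau / rowSums(tau)
    return(m_step_mat(Y0, M, tau))
  }
  X <- wave_basis()
  if (kind == "subjects" && K > 1L) {
    seeds <- Yimp[sample.int(n, K), , drop = FALSE]
    beta <- t(apply(seeds, 1L, function(y) solve(X, y)))
    return(lcga_parameters(rep(1 / K, K), beta, rep(sdy^2, 3L)))
  }
  wt <- colSums(M)
  A <- t(X) %*% (X * wt)
  b <- t(X) %*% colSums(Y0 * M)
  beta0 <- as.numeric(solve(A, b))
  beta <- t(vapply(seq_len(K), function(k)
    beta0 + stats::rnorm(3L, 0, c(sdy, sdy / 2, sdy / 4)), numeric(3L)))
  pi0 <- stats::runif(K, 0.5, 1.5)
  pi0 <- pi0 / sum(pi0)
  lcga_parameters(pi0, beta, rep(sdy^2, 3L))
}

#' Fit a latent class growth analysis by multi-start EM
#'
#' Quadratic mean trajectories per class (saturated with three waves),
#' growth-factor variances fixed at zero, wave-specific residual variances
#' (class-invariant by default). Half the starts come from k-means on the
#' (mean-imputed) wave scores, half from random perturbations of the pooled
#' quadratic fit; the best converged log-likelihood wins. Classes are
#' reported in canonical order: descending mean of the fitted trajectory
#' averaged over waves, ties broken by descending intercept.
#'
#' @param dataset A `pts_cohort` or data frame with `pts_w1..pts_w3`.
#' @param K Number of latent classes.
#' @param n_starts Number of initializations.
#' @param seed Seed governing starts.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per start.
#' @param residual `"wave"` (default) or `"class_wave"` residual variances.
#' @return An `lcga_fit` with elements `params`, `loglik`, `posteriors`,
#'   `modal_class`, `converged`, `n_iter`, `ll_trace`, `n_starts_used`,
#'   `best_start`, `n`.
#' @examples
#' cohort <- simulate_cohort(simulation_spec(n_subjects = 120, seed = 2))
#' fit <- fit_lcga(cohort, K = 2, n_starts = 4, seed = 9)
#' fit$params$beta
#' @export
fit_lcga <- function(dataset, K, n_starts = 20L, seed = 1L, tol = 1e-6,
                     max_iter = 2000L, residual = c("wave", "class_wave")) {
  residual <- match.arg(residual)
  d <- pts_matrix(dataset)
  n <- nrow(d$Y0)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (n < K) stop("need at least K subjects with wave-1 scores",
                  call. = FALSE)
  set.seed(seed)
  best <- NULL
  diagnostics <- character(0L)
  n_kmeans <- if (K == 1L) 0L else ceiling(n_starts / 3)
  n_subj <- if (K == 1L) 0L else ceiling(n_starts / 3)
  for (s in seq_len(max(n_starts, 1L))) {
    kind <- if (s <= n_kmeans) "kmeans"
    else if (s <= n_kmeans + n_subj) "subjects"
    else "random"
    res <- tryCatch({
      init <- make_start(d$Y0, d$M, K, kind)
      em_run(d$Y0, d$M, init, residual, tol, max_iter)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      diagnostics <- c(diagnostics, conditionMessage(res))
      next
    }
    if (is.null(best) || res$loglik > best$loglik) {
      best <- res
      best$start <- s
    }
  }
  if (is.null(best))
    stop("no EM start converged; diagnostics: ",
         paste(unique(diagnostics), collapse = "; "), call. = FALSE)
  fit <- canonicalize_fit(best, n, residual)
  fit$n_starts_used <- n_starts
  fit$call <- match.call()
  fit
}

# Reorder classes by descending mean fitted trajectory (tie-break:
# descending intercept) so output is deterministic up to the seed.
canonicalize_fit <- function(res, n, residual) {
  params <- res$params
  X <- wave_basis(params$wave_times)
  mu <- params$beta %*% t(X)
  ord <- order(-rowMeans(mu), -params$beta[, 1L])
  params$pi <- params$pi[ord]
  params$beta <- params$beta[ord, , drop = FALSE]
  rownames(params$beta) <- paste0("class", seq_len(params$K))
  if (is.matrix(params$sigma2))
    params$sigma2 <- params$sigma2[ord, , drop = FALSE]
  tau <- res$tau[, ord, drop = FALSE]
  colnames(tau) <- paste0("class", seq_len(params$K))
  modal <- modal_assign(tau)
  structure(list(params = params, loglik = res$loglik, posteriors = tau,
                 modal_class = modal, converged = res$converged,
                 n_iter = res$n_iter, ll_trace = res$ll_trace,
                 best_start = res$start, n = n, residual = residual),
            class = "lcga_fit")
}

# argmax with ties broken toward the lower canonical class index.
modal_assign <- function(tau) {
  apply(tau, 1L, function(r) which(r >= max(r) - 0)[1L])
}

#' @export
print.lcga_fit <- function(x, ...) {
  cat("LCGA fit: K =", x$params$K, "classes, n =", x$n, "subjects\n")
  cat("log-likelihood:", format(x$loglik, digits = 10),
      if (x$converged) "(converged," else "(NOT converged,",
      x$n_iter, "EM iterations, best start", x$best_start, ")\n")
  cat("class proportions:",
      paste(sprintf("%.3f", x$params$pi), collapse = " "), "\n")
  cat("growth coefficients (intercept, linear, quadratic):\n")
  print(round(x$params$beta, 3))
  invisible(x)
}

#' @export
logLik.lcga_fit <- function(object, ...) {
  structure(object$loglik, df = n_params(object$params), class = "logLik")
}

#' Recompute an LCGA fit's log-likelihood from its parameters
#'
#' @param fit An `lcga_fit`.
#' @param dataset The dataset it was fit to.
#' @return The observed-data log-likelihood.
#' @export
lcga_loglik <- function(fit, dataset) {
  d <- pts_matrix(dataset)
  e_step_mat(d$Y0, d$M, fit$params)$loglik
}

#' Export modal class assignments and posterior probabilities
#'
#' @param fit An `lcga_fit`.
#' @param subject_id Optional subject identifiers.
#' @return Data frame with `subject_id`, `modal_class`, and one posterior
#'   probability column per class.
#' @export
assign_modal_class <- function(fit, subject_id = NULL) {
  tau <- fit$posteriors
  if (is.null(subject_id)) subject_id <- seq_len(nrow(tau))
  out <- data.frame(subject_id = subject_id,
                    modal_class = fit$modal_class,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(tau))
}

#' Label fitted trajectories relative to the probable-PTSD cut-off
#'
#' Rule-based names: *low* if every fitted wave mean is below the cut-off,
#' *high* if every mean is at or above it, *decreasing* if the wave-1 mean is
#' at/above and later means below, *increasing* for the reverse; anything
#' else keeps its `class_k` index name. Labels are cosmetic; the analysis
#' keys on class indices.
#'
#' @param fit An `lcga_fit`.
#' @param ptsd_cutoff Probable-PTSD cut-off on the PCL-C total (default 44).
#' @return Character vector of labels, one per class.
#' @export
label_trajectories <- function(fit, ptsd_cutoff = 44) {
  X <- wave_basis(fit$params$wave_times)
  mu <- fit$params$beta %*% t(X)
  vapply(seq_len(nrow(mu)), function(k) {
    above <- mu[k, ] >= ptsd_cutoff
    if (!any(above)) "low"
    else if (all(above)) "high"
    else if (above[1L] && !above[2L] && !above[3L]) "decreasing"
    else if (!above[1L] && above[2L] && above[3L]) "increasing"
    else paste0("class_", k)
  }, character(1L))
}

#' Fitted mean trajectory per class
#'
#' @param fit An `lcga_fit`.
#' @return K x 3 matrix of fitted wave means.
#' @export
fitted_trajectories <- function(fit) {
  X <- wave_basis(fit$params$wave_times)
  mu <- fit$params$beta %*% t(X)
  dimnames(mu) <- list(paste0("class", seq_len(nrow(mu))),
                       paste0("w", 1:3))
  mu
}
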