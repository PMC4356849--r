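# Class-enumeration statistics: BIC, sample-size-adjusted BIC, normalized
# entropy, per-class average posterior probabilities, and a parametric
# bootstrap likelihood-ratio test of k vs k-1 classes. The bootstrap LRT is
# the package's operational k-vs-(k-1) test: it is fully specified and
# distributionally valid, and plays the same role as the Lo-Mendell-Rubin
# adjusted test printed by the software this model family is usually fit in
# (comparable in role, not numerically identical).

#' BIC and sample-size-adjusted BIC of an LCGA fit
#'
#' `BIC = -2 LL + p log(n)` and `aBIC = -2 LL + p log((n + 2) / 24)`, with
#' `p` the free-parameter count recomputed from the parameter object. Lower
#' values indicate better fit.
#'
#' @param fit An `lcga_fit` (or list with `loglik` and `params`).
#' @param n Number of subjects; defaults to `fit$n`.
#' @return Named list with `bic`, `adj_bic`, and `p`.
#' @export
bic_stats <- function(fit, n = fit$n) {
  if (is.null(n) || n <= 1) stop("n must exceed 1", call. = FALSE)
  p <- n_params(fit$params)
  list(bic = -2 * fit$loglik + p * log(n),
       adj_bic = -2 * fit$loglik + p * log((n + 2) / 24),
       p = p)
}

#' Normalized classification entropy
#'
#' `1 - sum_i sum_k (-tau_ik log tau_ik) / (n log K)`, with `0 log 0 = 0`.
#' 1 means perfect classification, 0 maximal uncertainty. Undefined for a
#' single class.
#'
#' @param tau n x K posterior matrix with normalized rows.
#' @return Entropy in `[0, 1]`, or `NA` when `K = 1`.
#' @export
entropy_stat <- function(tau) {
  K <- ncol(tau)
  if (K < 2L) return(NA_real_)
  h <- -tau * log(tau)
  h[!is.finite(h)] <- 0
  1 - sum(h) / (nrow(tau) * log(K))
}

#' Per-class average posterior probabilities
#'
#' For each class, the mean posterior probability of that class among the
#' subjects modally assigned to it, plus mean/SD/range across classes.
#' Empty modal classes are reported as `NA` and excluded from the summary.
#'
#' @param tau n x K posterior matrix.
#' @param modal Modal class assignment per subject; defaults to row argmax
#'   with ties to the lower index.
#' @return List with `per_class`, `mean`, `sd`, `range`.
#' @export
average_posterior_probabilities <- function(tau, modal = NULL) {
  K <- ncol(tau)
  if (is.null(modal)) modal <- apply(tau, 1L, which.max)
  per_class <- vapply(seq_len(K), function(k) {
    idx <- modal == k
    if (!any(idx)) NA_real_ else mean(tau[idx, k])
  }, numeric(1L))
  ok <- per_class[!is.na(per_class)]
  list(per_class = per_class,
       mean = mean(ok),
       sd = if (length(ok) > 1L) stats::sd(ok) else NA_real_,
       range = range(ok))
}

# Simulate score matrices from fitted LCGA parameters, imposing a given
# observation mask (the observed missingness pattern).
simulate_from_params <- function(params, M) {
  n <- nrow(M)
  K <- params$K
  cls <- sample.int(K, n, replace = TRUE, prob = params$pi)
  X <- wave_basis(params$wave_times)
  mu <- params$beta %*% t(X)
  Y <- matrix(NA_real_, n, 3L)
  for (t in 1:3) {
    s2 <- if (is.matrix(params$sigma2)) params$sigma2[cls, t] else
      params$sigma2[t]
    Y[, t] <- stats::rnorm(n, mu[cls, t], sqrt(s2))
  }
  Y[M == 0] <- NA_real_
  data.frame(pts_w1 = Y[, 1L], pts_w2 = Y[, 2L], pts_w3 = Y[, 3L])
}

#' Parametric bootstrap likelihood-ratio test of K vs K-1 classes
#'
#' The observed statistic is `2 (LL_K - LL_{K-1})`. Null datasets are
#' simulated from the fitted `(K-1)`-class model with the observed
#' missingness pattern; both models are refit to each replicate with a
#' reduced number of starts, and
#' `p = (1 + #\{boot >= observed\}) / (n_boot + 1)`.
#'
#' @param dataset A `pts_cohort` or data frame with wave scores.
#' @param K Number of classes under the alternative (K >= 2).
#' @param n_boot Number of bootstrap replicates.
#' @param seed Seed for fitting and resampling.
#' @param n_starts Starts for the observed-data fits.
#' @param boot_starts Reduced starts used inside the bootstrap.
#' @param max_redraw Cap on redraws of non-converging replicates.
#' @return List with `statistic`, `p_value`, `loglik_k`, `loglik_km1`,
#'   `n_boot`, `boot_stats`.
#' @export
bootstrap_lrt <- function(dataset, K, n_boot = 199L, seed = 1L,
                          n_starts = 20L, boot_starts = 5L,
                          max_redraw = n_boot) {
  if (K < 2L) stop("K must be >= 2", call. = FALSE)
  d <- pts_matrix(dataset)
  fit0 <- fit_lcga(dataset, K - 1L, n_starts = n_starts, seed = seed)
  fit1 <- fit_lcga(dataset, K, n_starts = n_starts, seed = seed + 1L)
  obs <- 2 * (fit1$loglik - fit0$loglik)
  set.seed(derive_seed(seed, "bootstrap_lrt"))
  boot <- numeric(n_boot)
  redraws <- 0L
  b <- 1L
  while (b <= n_boot) {
    null_data <- simulate_from_params(fit0$params, d$M)
    stat <- tryCatch({
      f0 <- fit_lcga(null_data, K - 1L, n_starts = boot_starts,
                     seed = sample.int(2^30, 1L))
      f1 <- fit_lcga(null_data, K, n_starts = boot_starts,
                     seed = sample.int(2^30, 1L))
      2 * (f1$loglik - f0$loglik)
    }, error = function(e) NA_real_)
    if (is.na(stat)) {
      redraws <- redraws + 1L
      if (redraws > max_redraw)
        stop("bootstrap LRT: replicate non-convergence cap exceeded",
             call. = FALSE)
      next
    }
    boot[b] <- stat
    b <- b + 1L
  }
  list(statistic = obs,
       p_value = (1 + sum(boot >= obs)) / (n_boot + 1),
       loglik_k = fit1$loglik, loglik_km1 = fit0$loglik,
       n_boot = n_boot, boot_stats = boot, redraws = redraws)
}

#' Enumerate candidate class counts and assemble a fit-comparison table
#'
#' Fits the model for each K in `k_range` and reports log-likelihood, free
#' parameters, BIC, adjusted BIC, entropy, the average-posterior-probability
#' summary, and (optionally) the bootstrap LRT p-value of K vs K-1. The
#' `selected` flag marks the smallest K whose successor fails the LRT at
#' `alpha`; the full table is always emitted for human judgment.
#'
#' @param dataset A `pts_cohort`.
#' @param k_range Integer vector of class counts (default 2:6).
#' @param n_starts Starts per fit.
#' @param seed Master seed.
#' @param lrt Run the bootstrap LRT per K?
#' @param n_boot Bootstrap replicates for the LRT.
#' @param boot_starts Reduced starts inside the bootstrap.
#' @param alpha Significance level for the selection flag.
#' @return A data frame of class `lcga_enumeration`, one row per K, with a
#'   `fits` attribute holding the fitted models.
#' @export
enumerate_classes <- function(dataset, k_range = 2:6, n_starts = 20L,
                              seed = 1L, lrt = TRUE, n_boot = 199L,
                              boot_starts = 5L, alpha = 0.05) {
  k_range <- sort(unique(as.integer(k_range)))
  rows <- list()
  fits <- list()
  for (K in k_range) {
    row <- tryCatch({
      fit <- fit_lcga(dataset, K, n_starts = n_starts,
                      seed = derive_seed(seed, paste0("fit_k", K)))
      fits[[as.character(K)]] <- fit
      ic <- bic_stats(fit)
      app <- average_posterior_probabilities(fit$posteriors,
                                             fit$modal_class)
      lrt_p <- NA_real_
      if (lrt && K >= 2L) {
        lrt_p <- bootstrap_lrt(dataset, K, n_boot = n_boot,
                               seed = derive_seed(seed, paste0("lrt_k", K)),
                               n_starts = n_starts,
                               boot_starts = boot_starts)$p_value
      }
      data.frame(K = K, loglik = fit$loglik, p = ic$p, n = fit$n,
                 bic = ic$bic, adj_bic = ic$adj_bic,
                 entropy = entropy_stat(fit$posteriors),
                 avepp_mean = app$mean, avepp_sd = app$sd,
                 avepp_min = app$range[1L], avepp_max = app$range[2L],
                 lrt_p = lrt_p, error = NA_character_)
    }, error = function(e) {
      data.frame(K = K, loglik = NA_real_, p = NA_integer_, n = NA_integer_,
                 bic = NA_real_, adj_bic = NA_real_, entropy = NA_real_,
                 avepp_mean = NA_real_, avepp_sd = NA_real_,
                 avepp_min = NA_real_, avepp_max = NA_real_,
                 lrt_p = NA_real_, error = conditionMessage(e))
    })
    rows[[as.character(K)]] <- row
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$selected <- FALSE
  if (lrt && nrow(tab) > 1L) {
    for (i in seq_len(nrow(tab) - 1L)) {
      succ <- tab$lrt_p[i + 1L]
      if (!is.na(succ) && succ > alpha) {
        tab$selected[i] <- TRUE
        break
      }
    }
  }
  structure(tab, fits = fits, class = c("lcga_enumeration", "data.frame"))
}

#' @export
print.lcga_enumeration <- function(x, ...) {
  cat("LCGA class enumeration (n =", x$n[which(!is.na(x$n))[1L]],
      "subjects)\n")
  df <- as.data.frame(x)
  df$bic <- round(df$bic, 2)
  df$adj_bic <- round(df$adj_bic, 2)
  df$entropy <- round(df$entropy, 2)
  df$avepp_mean <- round(df$avepp_mean, 2)
  print(df[, c("K", "bic", "adj_bic", "entropy", "avepp_mean", "lrt_p",
               "selected")], row.names = FALSE)
  invisible(x)
}
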