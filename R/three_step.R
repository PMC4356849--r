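# Bias-adjusted three-step covariate analysis. Step 1 fits the LCGA; step 2
# summarizes its classification quality as the row-stochastic matrix
# D[k, s] = P(modal class s | true class k) derived from the posteriors;
# step 3 regresses the latent class on covariates by maximum likelihood,
# treating the modal assignment as an indicator of the latent class observed
# with the known misclassification rates in D. With perfect classification
# (D = identity) the estimator reduces to ordinary multinomial logistic
# regression on the modal class; with imperfect classification it undoes the
# attenuation that plain modal-class regression suffers. Standard errors
# come from the observed information and ignore step-1 uncertainty in D, as
# the standard three-step procedure does.

#' Classification-error matrix from LCGA posteriors
#'
#' `D[k, s] = sum_i tau_ik 1(modal_i = s) / sum_i tau_ik`: the probability
#' of being modally assigned to class s given true class k. Rows sum to 1;
#' D is the identity when classification is perfect.
#'
#' @param tau n x K posterior matrix.
#' @param modal Modal assignments; defaults to row argmax (ties to the
#'   lower index).
#' @return A `class_error_matrix`: list with `D` and `class_sizes` (the
#'   expected class counts `sum_i tau_ik`).
#' @export
classification_error_matrix <- function(tau, modal = NULL) {
  K <- ncol(tau)
  if (is.null(modal)) modal <- apply(tau, 1L, which.max)
  sizes <- colSums(tau)
  if (any(sizes < 1e-8))
    stop("empty expected class: class ", which(sizes < 1e-8)[1L],
         " has vanishing posterior mass", call. = FALSE)
  D <- matrix(0, K, K)
  for (s in seq_len(K)) {
    idx <- modal == s
    if (any(idx)) D[, s] <- colSums(tau[idx, , drop = FALSE]) / sizes
  }
  dimnames(D) <- list(paste0("true", seq_len(K)),
                      paste0("modal", seq_len(K)))
  structure(list(D = D, class_sizes = sizes), class = "class_error_matrix")
}

#' @export
print.class_error_matrix <- function(x, ...) {
  cat("Classification-error matrix P(modal | true):\n")
  print(round(x$D, 4))
  cat("expected class sizes:",
      paste(sprintf("%.1f", x$class_sizes), collapse = " "), "\n")
  invisible(x)
}

# negative log-likelihood and gradient of the error-corrected multinomial.
# par: (K-1) x P coefficients, referent class fixed at zero, flattened
# row-major by class. Dmod: n x K matrix with Dmod[i, k] = D[k, modal_i].
corrected_negloglik <- function(par, X, Dmod, K) {
  P <- ncol(X)
  G <- matrix(0, K, P)
  G[-1L, ] <- matrix(par, K - 1L, P, byrow = TRUE)
  eta <- X %*% t(G)
  eta <- eta - apply(eta, 1L, max)
  pe <- exp(eta)
  pr <- pe / rowSums(pe)
  L <- rowSums(pr * Dmod)
  -sum(log(pmax(L, 1e-300)))
}

corrected_gradient <- function(par, X, Dmod, K) {
  P <- ncol(X)
  G <- matrix(0, K, P)
  G[-1L, ] <- matrix(par, K - 1L, P, byrow = TRUE)
  eta <- X %*% t(G)
  eta <- eta - apply(eta, 1L, max)
  pe <- exp(eta)
  pr <- pe / rowSums(pe)
  L <- pmax(rowSums(pr * Dmod), 1e-300)
  # d ll / d eta_ik = p_ik (D[k, m_i] / L_i - 1)
  W <- pr * (Dmod / L - 1)
  -as.vector(t(t(W[, -1L, drop = FALSE]) %*% X))
}

#' Error-corrected multinomial logistic regression of latent class
#'
#' Maximizes `sum_i log sum_k P(C = k | x_i; gamma) D[k, modal_i]` over the
#' multinomial-logit coefficients `gamma` with the stated referent class
#' fixed at zero. Optimization is BFGS with an analytic gradient on
#' internally standardized predictors; estimates are mapped back to the raw
#' scale and the covariance matrix is the inverse observed information
#' (numerically differentiated gradient) at the raw-scale optimum.
#'
#' @param modal Integer vector of modal class assignments in `1..K`.
#' @param D K x K row-stochastic classification-error matrix (or a
#'   `class_error_matrix`).
#' @param X Design matrix including an intercept column.
#' @param referent Referent class index (coefficients are log-odds of each
#'   other class vs this one).
#' @param class_labels Optional class labels for reporting.
#' @return A `corrected_multinom`: coefficients ((K-1) x P), `vcov`,
#'   log-likelihood, convergence diagnostics, and a contrast table for
#'   every pairwise class contrast (see [rotate_referents()]).
#' @export
fit_corrected_multinomial <- function(modal, D, X, referent = 1L,
                                      class_labels = NULL) {
  if (inherits(D, "class_error_matrix")) D <- D$D
  K <- nrow(D)
  if (any(abs(rowSums(D) - 1) > 1e-10))
    stop("D must be row-stochastic", call. = FALSE)
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(modal) != n) stop("modal and X disagree in length",
                               call. = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(class_labels)) class_labels <- paste0("class", seq_len(K))
  # reorder classes so the referent is first in the internal parameterization
  ord <- c(referent, setdiff(seq_len(K), referent))
  Dmod <- t(D)[modal, , drop = FALSE][, ord, drop = FALSE] # n x K
  P <- ncol(X)
  # standardize non-intercept columns for optimization
  is_int <- apply(X, 2L, function(col) all(col == col[1L]))
  ctr <- ifelse(is_int, 0, colMeans(X))
  scl <- ifelse(is_int, 1, apply(X, 2L, stats::sd))
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, `/`)
  par0 <- rep(0, (K - 1L) * P)
  opt <- stats::optim(par0, corrected_negloglik, corrected_gradient,
                      X = Xs, Dmod = Dmod, K = K, method = "BFGS",
                      control = list(maxit = 1000L, reltol = 1e-14))
  for (restart in 1:2) { # BFGS occasionally stalls near the optimum
    if (opt$convergence == 0) break
    opt <- stats::optim(opt$par, corrected_negloglik, corrected_gradient,
                        X = Xs, Dmod = Dmod, K = K, method = "BFGS",
                        control = list(maxit = 1000L, reltol = 1e-14))
  }
  grad_norm <- sqrt(sum(corrected_gradient(opt$par, Xs, Dmod, K)^2))
  if (grad_norm > 0.05)
    stop("corrected multinomial did not converge (code ", opt$convergence,
         ", gradient norm ", format(grad_norm, digits = 3), ")",
         call. = FALSE)
  # map standardized-scale estimates back to the raw scale
  Gs <- matrix(opt$par, K - 1L, P, byrow = TRUE)
  Graw <- sweep(Gs, 2L, scl, `/`)
  int_col <- which(is_int)[1L]
  Graw[, int_col] <- Graw[, int_col] -
    as.vector(Gs[, !is_int, drop = FALSE] %*%
                (ctr[!is_int] / scl[!is_int]))
  par_raw <- as.vector(t(Graw))
  H <- stats::optimHess(par_raw, corrected_negloglik, corrected_gradient,
                        X = X, Dmod = Dmod, K = K)
  vc <- tryCatch(solve(H), error = function(e)
    stop("observed information is singular; model may be separated",
         call. = FALSE))
  coef <- Graw
  nonref <- class_labels[ord][-1L]
  dimnames(coef) <- list(nonref, colnames(X))
  rownames(vc) <- colnames(vc) <-
    paste(rep(nonref, each = P), rep(colnames(X), K - 1L), sep = ":")
  out <- structure(list(coefficients = coef, vcov = vc,
                        loglik = -opt$value,
                        referent = class_labels[referent],
                        class_labels = class_labels,
                        class_order = ord,
                        grad_norm = grad_norm,
                        converged = opt$convergence == 0,
                        n = n, K = K, predictors = colnames(X)),
                   class = "corrected_multinom")
  out$contrasts <- rotate_referents(out)
  out
}

#' @export
print.corrected_multinom <- function(x, ...) {
  cat("Error-corrected multinomial logit (referent:", x$referent, ", n =",
      x$n, ")\nlog-likelihood:", format(x$loglik, digits = 8), "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' All pairwise class contrasts of a corrected multinomial fit
#'
#' Log-odds of class A vs class B for every ordered class pair are linear
#' combinations of the fitted coefficients (`gamma_A - gamma_B` with the
#' referent's row at zero), so odds-ratio transitivity
#' `OR(A vs B) x OR(B vs C) = OR(A vs C)` holds exactly. Wald standard
#' errors come from the full coefficient covariance.
#'
#' @param fit A `corrected_multinom`.
#' @param conf_level Confidence level for the Wald interval.
#' @return Data frame with one row per contrast per predictor: `contrast`,
#'   `class_a`, `class_b`, `predictor`, `logodds`, `se`, `or`, `ci_lo`,
#'   `ci_hi`, `z`, `p_value`.
#' @export
rotate_referents <- function(fit, conf_level = 0.95) {
  K <- fit$K
  P <- length(fit$predictors)
  labels <- fit$class_labels[fit$class_order]
  # full coefficient matrix in internal order, referent row = 0
  G <- rbind(0, fit$coefficients)
  rownames(G) <- labels
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  # covariance lookup: row r (2..K) block of vcov
  block <- function(r) ((r - 2L) * P + 1L):((r - 1L) * P)
  rows <- list()
  pairs <- expand.grid(a = seq_len(K), b = seq_len(K))
  pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  for (j in seq_len(nrow(pairs))) {
    a <- pairs$a[j]; b <- pairs$b[j]
    est <- G[a, ] - G[b, ]
    va <- if (a == 1L) matrix(0, P, P) else fit$vcov[block(a), block(a)]
    vb <- if (b == 1L) matrix(0, P, P) else fit$vcov[block(b), block(b)]
    vab <- if (a == 1L || b == 1L) matrix(0, P, P) else
      fit$vcov[block(a), block(b)]
    se <- sqrt(pmax(diag(va) + diag(vb) - 2 * diag(vab), 0))
    z <- est / se
    rows[[length(rows) + 1L]] <- data.frame(
      contrast = paste0(labels[a], "_vs_", labels[b]),
      class_a = labels[a], class_b = labels[b],
      predictor = fit$predictors,
      logodds = est, se = se, or = exp(est),
      ci_lo = exp(est - zq * se), ci_hi = exp(est + zq * se),
      z = z, p_value = 2 * stats::pnorm(-abs(z)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Shared front end for the two covariate models.
build_step3 <- function(dataset, fit, snp, interaction) {
  df <- as.data.frame(dataset)
  dose_col <- paste0("dosage_", snp)
  if (!dose_col %in% names(df))
    stop("no dosage column for SNP ", snp, call. = FALSE)
  vars <- c(dose_col, "age", "female", "pc1", "pc2")
  if (interaction) vars <- c(vars, "cts_total")
  cc <- stats::complete.cases(df[, vars])
  n_drop <- sum(!cc)
  if (n_drop > 0)
    message(n_drop, " subject(s) dropped for missing covariates ",
            "(complete-case analysis)")
  df <- df[cc, , drop = FALSE]
  modal <- fit$modal_class[cc]
  tau <- fit$posteriors[cc, , drop = FALSE]
  cem <- classification_error_matrix(tau, modal)
  X <- cbind(`(Intercept)` = 1, dosage = df[[dose_col]],
             age = df$age, female = df$female,
             pc1 = df$pc1, pc2 = df$pc2)
  if (interaction) {
    X <- cbind(X, abuse = df$cts_total,
               dosage_x_abuse = df[[dose_col]] * df$cts_total)
  }
  labels <- if (fit$params$K == 4L) label_trajectories(fit) else
    paste0("class", seq_len(fit$params$K))
  # make labels unique if the rule left duplicates
  if (anyDuplicated(labels))
    labels <- make.unique(labels, sep = "_")
  list(modal = modal, cem = cem, X = X, labels = labels, n_dropped = n_drop)
}

#' Three-step main-effects model: SNP dosage predicting trajectory class
#'
#' Additively coded dosage (copies of the minor allele) plus age, gender,
#' and the two ancestry principal components, fit by the error-corrected
#' multinomial likelihood with the classification-error matrix derived from
#' the supplied LCGA fit. Subjects with missing covariates are dropped
#' (complete-case) with a logged count. Results cover every pairwise class
#' contrast.
#'
#' @param dataset A `pts_cohort`.
#' @param fit An `lcga_fit` on the same subjects (same row order).
#' @param snp SNP name (matching a `dosage_<snp>` column).
#' @param referent Referent class index for the internal parameterization;
#'   contrasts are emitted for all pairs regardless.
#' @return A `corrected_multinom` with a `model_tag` of `"main"` and a
#'   `snp` field.
#' @export
run_main_effects_model <- function(dataset, fit, snp, referent = NULL) {
  parts <- build_step3(dataset, fit, snp, interaction = FALSE)
  if (is.null(referent)) referent <- which(parts$labels == "low")[1L]
  if (is.na(referent)) referent <- fit$params$K
  res <- fit_corrected_multinomial(parts$modal, parts$cem, parts$X,
                                   referent = referent,
                                   class_labels = parts$labels)
  res$model_tag <- "main"
  res$snp <- snp
  res$n_dropped <- parts$n_dropped
  res
}

#' Three-step interaction model: dosage, abuse, and dosage-by-abuse
#'
#' Adds the childhood physical abuse score (raw 0-24 scale, uncentered) and
#' the dosage-by-abuse product to the main-effects design; the interaction
#' odds ratio is per abuse-unit per minor-allele copy. The full hierarchical
#' model (all main effects plus the interaction) is fit and every term is
#' reported.
#'
#' @inheritParams run_main_effects_model
#' @param center_abuse Center the abuse score before forming the product?
#'   Default `FALSE` (raw scale).
#' @return A `corrected_multinom` with `model_tag` `"interaction"`.
#' @export
run_interaction_model <- function(dataset, fit, snp, referent = NULL,
                                  center_abuse = FALSE) {
  parts <- build_step3(dataset, fit, snp, interaction = TRUE)
  if (center_abuse) {
    ab <- parts$X[, "abuse"] - mean(parts$X[, "abuse"])
    parts$X[, "abuse"] <- ab
    parts$X[, "dosage_x_abuse"] <- parts$X[, "dosage"] * ab
  }
  if (is.null(referent)) referent <- which(parts$labels == "low")[1L]
  if (is.na(referent)) referent <- fit$params$K
  res <- fit_corrected_multinomial(parts$modal, parts$cem, parts$X,
                                   referent = referent,
                                   class_labels = parts$labels)
  res$model_tag <- "interaction"
  res$snp <- snp
  res$n_dropped <- parts$n_dropped
  res
}

#' Flag contrasts at nominal and Bonferroni-corrected levels
#'
#' Adds `sig_nominal` (p < 0.05) and `sig_corrected` (p < 0.05 / n_snps)
#' flags to a contrast table; both flags are retained so readers can see
#' which findings survive correction for the number of SNPs analyzed.
#'
#' @param results A contrast data frame (e.g. `fit$contrasts`) with a
#'   `p_value` column, or a `corrected_multinom`.
#' @param n_snps Number of SNPs tested.
#' @param alpha Base significance level.
#' @return The contrast table with flag columns and a `bonferroni_alpha`
#'   attribute.
#' @export
apply_bonferroni <- function(results, n_snps, alpha = 0.05) {
  if (n_snps < 1L) stop("n_snps must be >= 1", call. = FALSE)
  if (inherits(results, "corrected_multinom")) results <- results$contrasts
  thr <- alpha / n_snps
  results$sig_nominal <- results$p_value < alpha
  results$sig_corrected <- results$p_value < thr
  attr(results, "bonferroni_alpha") <- thr
  results
}
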