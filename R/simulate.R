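#' Specify a synthetic posttraumatic-stress cohort
#'
#' Builds the generating truth for [simulate_cohort()]. The defaults encode
#' the statistical structure of the study cohort the package emulates: four
#' latent trajectory classes with quadratic mean curves on the PCL-C scale
#' (low / decreasing / increasing / high), class-and-wave-specific residual
#' SDs, class shares 68.1 / 17.3 / 8.0 / 6.6 percent, biallelic SNPs in
#' Hardy-Weinberg equilibrium at minor allele frequencies 0.12 and 0.11, a
#' right-skewed childhood physical abuse score on 0-24 with mean 3.59 and SD
#' 3.81, survey covariates (57.5% female; age mean 53.35, SD 15.58; two
#' ancestry principal components), and independent per-wave retention of
#' 276/473 at wave 2 and 217/473 at wave 3.
#'
#' Class membership follows a multinomial logit on genotype dosage, abuse,
#' and their product. Intercepts are calibrated so that class probabilities
#' equal `class_proportions` at the covariate means, giving exact marginal
#' control when all effects are zero.
#'
#' @param n_subjects Number of subjects.
#' @param class_proportions Probability vector over the K latent classes;
#'   must sum to 1. The first class is the referent of the membership logit.
#' @param growth_coefficients K x 3 matrix of per-class (intercept, linear,
#'   quadratic) coefficients on the PCL-C total scale; wave times are fixed
#'   at t = 0, 1, 2.
#' @param wave_residual_sds K x 3 matrix of within-class residual SDs per
#'   wave, PCL-C units.
#' @param snp_mafs Named vector of minor allele frequencies in (0.01, 0.5].
#' @param abuse_distribution List with `mean`, `sd`, `max`: a negative
#'   binomial with these moments, truncated to `[0, max]`.
#' @param covariate_params List with `female_prop`, `age_mean`, `age_sd`,
#'   `age_floor`, `pc_sds` (length-2 SDs of the ancestry PCs).
#' @param effect_spec List with per-class log-odds vectors `genotype`,
#'   `abuse`, `interaction` (entry 1, the referent, must be 0) and `snp`,
#'   the index of the SNP carrying the effect.
#' @param dropout List with wave-2 and wave-3 retention probabilities `w2`,
#'   `w3` and a `monotone` flag; when `TRUE`, wave 3 can only be observed if
#'   wave 2 is (retention `w3/w2` conditional on wave 2).
#' @param clip_scores Clip generated scores to the observable 17-85 range?
#'   Off by default: the LCGA likelihood is Gaussian and clipping would bias
#'   parameter-recovery checks.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the spec including this seed.
#' @return An object of class `simulation_spec`.
#' @seealso [simulate_cohort()]
#' @export
simulation_spec <- function(n_subjects = 473,
                            class_proportions = c(low = 0.681,
                                                  decreasing = 0.173,
                                                  increasing = 0.080,
                                                  high = 0.066),
                            growth_coefficients = default_growth_coefficients(),
                            wave_residual_sds = default_wave_residual_sds(),
                            snp_mafs = c(snp1 = 0.12, snp2 = 0.11),
                            abuse_distribution = list(mean = 3.59, sd = 3.81,
                                                      max = 24),
                            covariate_params = list(female_prop = 0.575,
                                                    age_mean = 53.35,
                                                    age_sd = 15.58,
                                                    age_floor = 18,
                                                    pc_sds = c(0.05, 0.01)),
                            effect_spec = list(genotype = NULL, abuse = NULL,
                                               interaction = NULL, snp = 1L),
                            dropout = list(w2 = 276 / 473, w3 = 217 / 473,
                                           monotone = FALSE),
                            clip_scores = FALSE,
                            seed = 1L) {
  K <- length(class_proportions)
  zeros <- rep(0, K)
  for (nm in c("genotype", "abuse", "interaction")) {
    if (is.null(effect_spec[[nm]])) effect_spec[[nm]] <- zeros
  }
  if (is.null(effect_spec$snp)) effect_spec$snp <- 1L
  spec <- structure(list(n_subjects = n_subjects,
                         class_proportions = class_proportions,
                         growth_coefficients = growth_coefficients,
                         wave_residual_sds = wave_residual_sds,
                         snp_mafs = snp_mafs,
                         abuse_distribution = abuse_distribution,
                         covariate_params = covariate_params,
                         effect_spec = effect_spec,
                         dropout = dropout,
                         clip_scores = clip_scores,
                         seed = as.integer(seed)),
                    class = "simulation_spec")
  validate_simulation_spec(spec)
  spec
}

#' Default generating growth coefficients (intercept, linear, quadratic)
#' @return 4 x 3 matrix, classes low / decreasing / increasing / high.
#' @export
default_growth_coefficients <- function() {
  m <- rbind(low        = c(26.60,  -0.87,  -0.04),
             decreasing = c(53.53, -33.76,  11.73),
             increasing = c(37.85,  19.24,  -5.56),
             high       = c(70.06, -30.69,  12.77))
  colnames(m) <- c("intercept", "linear", "quadratic")
  m
}

#' Default within-class residual SDs per wave
#' @return 4 x 3 matrix, one row per class, one column per wave.
#' @export
default_wave_residual_sds <- function() {
  m <- rbind(low        = c(7.01,   8.54,  7.49),
             decreasing = c(7.81,   8.14,  9.06),
             increasing = c(8.68,  13.29, 12.28),
             high       = c(10.36, 13.79,  8.60))
  colnames(m) <- paste0("w", 1:3)
  m
}

#' Validate a simulation spec
#'
#' Checks all spec invariants and raises an error naming the offending field.
#'
#' @param spec A `simulation_spec`.
#' @return The spec, invisibly, if valid.
#' @export
validate_simulation_spec <- function(spec) {
  p <- spec$class_proportions
  K <- length(p)
  if (!is.numeric(spec$n_subjects) || length(spec$n_subjects) != 1L ||
      !is.finite(spec$n_subjects) || spec$n_subjects < 1)
    stop_field("n_subjects", "must be a positive count")
  if (any(!is.finite(p)) || any(p <= 0))
    stop_field("class_proportions", "entries must be finite and > 0")
  if (abs(sum(p) - 1) > 1e-12)
    stop_field("class_proportions", "must sum to 1 within 1e-12")
  g <- spec$growth_coefficients
  if (!is.matrix(g) || nrow(g) != K || ncol(g) != 3L || any(!is.finite(g)))
    stop_field("growth_coefficients", "must be a finite K x 3 matrix")
  s <- spec$wave_residual_sds
  if (!is.matrix(s) || nrow(s) != K || ncol(s) != 3L || any(!is.finite(s)) ||
      any(s < 0))
    stop_field("wave_residual_sds", "must be a K x 3 matrix of SDs >= 0")
  maf <- spec$snp_mafs
  if (length(maf) < 1L || any(!is.finite(maf)) || any(maf <= 0.01) ||
      any(maf > 0.5))
    stop_field("snp_mafs", "every MAF must lie in (0.01, 0.5]")
  ab <- spec$abuse_distribution
  if (!is.finite(ab$mean) || ab$mean <= 0 || !is.finite(ab$sd) || ab$sd <= 0)
    stop_field("abuse_distribution", "mean and sd must be positive")
  if (ab$sd^2 <= ab$mean)
    stop_field("abuse_distribution",
               "sd^2 must exceed mean for a right-skewed negative binomial")
  cv <- spec$covariate_params
  if (!is.finite(cv$female_prop) || cv$female_prop < 0 || cv$female_prop > 1)
    stop_field("covariate_params$female_prop", "must lie in [0, 1]")
  if (!is.finite(cv$age_sd) || cv$age_sd <= 0)
    stop_field("covariate_params$age_sd", "must be > 0")
  if (length(cv$pc_sds) != 2L || any(cv$pc_sds <= 0))
    stop_field("covariate_params$pc_sds", "needs two positive SDs")
  ef <- spec$effect_spec
  for (nm in c("genotype", "abuse", "interaction")) {
    v <- ef[[nm]]
    if (length(v) != K || any(!is.finite(v)))
      stop_field(paste0("effect_spec$", nm),
                 sprintf("must be a finite length-%d vector", K))
    if (v[1L] != 0)
      stop_field(paste0("effect_spec$", nm),
                 "referent-class entry (first) must be 0")
  }
  if (ef$snp < 1L || ef$snp > length(maf))
    stop_field("effect_spec$snp", "must index an entry of snp_mafs")
  dr <- spec$dropout
  for (nm in c("w2", "w3")) {
    if (!is.finite(dr[[nm]]) || dr[[nm]] < 0 || dr[[nm]] > 1)
      stop_field(paste0("dropout$", nm), "retention must lie in [0, 1]")
  }
  if (isTRUE(dr$monotone) && dr$w3 > dr$w2)
    stop_field("dropout", "monotone dropout requires w3 <= w2")
  invisible(spec)
}

# Truncated negative binomial calibrated so that the truncated law itself
# has the target (mean, sd); truncation to 0..max otherwise shaves the SD a
# few percent below target. The moment-matching parameters are found by a
# deterministic two-parameter search; values above `max` are resampled,
# which is equivalent to renormalizing on the truncated support.
nbinom_truncated_params <- function(ab) {
  moments <- function(par) {
    mu <- exp(par[1L]); size <- exp(par[2L])
    p <- stats::dnbinom(0:ab$max, size = size, mu = mu)
    p <- p / sum(p)
    m <- sum((0:ab$max) * p)
    s2 <- sum((0:ab$max)^2 * p) - m^2
    c(m, sqrt(s2))
  }
  obj <- function(par) {
    ms <- moments(par)
    (ms[1L] / ab$mean - 1)^2 + (ms[2L] / ab$sd - 1)^2
  }
  size0 <- ab$mean^2 / (ab$sd^2 - ab$mean)
  opt <- stats::optim(log(c(ab$mean, size0)), obj,
                      control = list(reltol = 1e-14, maxit = 2000L))
  list(mu = exp(opt$par[1L]), size = exp(opt$par[2L]))
}

draw_abuse <- function(n, ab) {
  pars <- nbinom_truncated_params(ab)
  x <- stats::rnbinom(n, size = pars$size, mu = pars$mu)
  while (any(x > ab$max)) {
    idx <- x > ab$max
    x[idx] <- stats::rnbinom(sum(idx), size = pars$size, mu = pars$mu)
  }
  x
}

# Decompose a 0-24 total into six 0-4 items (sequential allocation over
# items with remaining capacity; item-level structure is not moment-
# calibrated, only the total is).
decompose_cts <- function(total) {
  items <- integer(6L)
  remaining <- total
  while (remaining > 0L) {
    open <- which(items < 4L)
    pick <- if (length(open) == 1L) open else sample(open, 1L)
    items[pick] <- items[pick] + 1L
    remaining <- remaining - 1L
  }
  items
}

#' Simulate a synthetic longitudinal cohort
#'
#' Draws a complete cohort from the generating model described in
#' [simulation_spec()]: HWE-binomial genotypes, a truncated negative binomial
#' abuse score, survey covariates, latent class membership from a calibrated
#' multinomial logit, Gaussian PCL-C totals around each class's quadratic
#' mean curve at waves t = 0, 1, 2, and per-wave missingness at waves 2-3.
#' Wave 1 is always observed, mirroring the inclusion rule that trajectory
#' analysis requires a wave-1 score.
#'
#' @param spec A [simulation_spec()].
#' @return A `pts_cohort`: a data frame with one row per subject, columns
#'   `subject_id`, `pts_w1`..`pts_w3` (NA where a wave is missing),
#'   `cts_i1`..`cts_i6`, `cts_total`, one `dosage_*` column per SNP, `age`,
#'   `female`, `pc1`, `pc2`, and the latent `true_class`. Attributes carry
#'   the SNP names and wave times.
#' @examples
#' cohort <- simulate_cohort(simulation_spec(n_subjects = 50, seed = 7))
#' table(cohort$true_class)
#' @export
simulate_cohort <- function(spec) {
  validate_simulation_spec(spec)
  set.seed(spec$seed)
  n <- as.integer(spec$n_subjects)
  K <- length(spec$class_proportions)
  cv <- spec$covariate_params

  female <- stats::rbinom(n, 1L, cv$female_prop)
  age <- pmax(stats::rnorm(n, cv$age_mean, cv$age_sd), cv$age_floor)
  pc1 <- stats::rnorm(n, 0, cv$pc_sds[1L])
  pc2 <- stats::rnorm(n, 0, cv$pc_sds[2L])

  dosages <- vapply(spec$snp_mafs,
                    function(maf) stats::rbinom(n, 2L, maf),
                    integer(n))
  dosages <- matrix(dosages, nrow = n,
                    dimnames = list(NULL, names(spec$snp_mafs)))

  abuse <- draw_abuse(n, spec$abuse_distribution)
  cts_items <- t(vapply(abuse, decompose_cts, integer(6L)))

  ef <- spec$effect_spec
  d_eff <- dosages[, ef$snp]
  # Calibrate intercepts so class probabilities equal the target shares at
  # the covariate means (exact marginal control when all effects are zero).
  xbar_d <- 2 * spec$snp_mafs[[ef$snp]]
  xbar_a <- spec$abuse_distribution$mean
  alpha <- log(spec$class_proportions / spec$class_proportions[1L]) -
    ef$genotype * xbar_d - ef$abuse * xbar_a -
    ef$interaction * xbar_d * xbar_a
  eta <- outer(rep(1, n), alpha) +
    outer(d_eff, ef$genotype) + outer(abuse, ef$abuse) +
    outer(d_eff * abuse, ef$interaction)
  pr <- exp(eta - apply(eta, 1L, max))
  pr <- pr / rowSums(pr)
  u <- stats::runif(n)
  cum <- t(apply(pr, 1L, cumsum))
  true_class <- rowSums(u > cum) + 1L

  tt <- 0:2
  mu <- spec$growth_coefficients %*% rbind(1, tt, tt^2) # K x 3
  Y <- matrix(NA_real_, n, 3L)
  for (t in 1:3) {
    Y[, t] <- stats::rnorm(n, mu[true_class, t],
                           spec$wave_residual_sds[cbind(true_class, t)])
  }
  if (isTRUE(spec$clip_scores)) Y <- pmin(pmax(Y, 17), 85)

  keep2 <- stats::runif(n) < spec$dropout$w2
  if (isTRUE(spec$dropout$monotone)) {
    cond <- if (spec$dropout$w2 > 0) spec$dropout$w3 / spec$dropout$w2 else 0
    keep3 <- keep2 & (stats::runif(n) < cond)
  } else {
    keep3 <- stats::runif(n) < spec$dropout$w3
  }
  Y[!keep2, 2L] <- NA_real_
  Y[!keep3, 3L] <- NA_real_

  out <- data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                    pts_w1 = Y[, 1L], pts_w2 = Y[, 2L], pts_w3 = Y[, 3L],
                    stringsAsFactors = FALSE)
  colnames(cts_items) <- paste0("cts_i", 1:6)
  out <- cbind(out, cts_items)
  out$cts_total <- abuse
  dos <- dosages
  colnames(dos) <- paste0("dosage_", colnames(dosages))
  out <- cbind(out, dos)
  out$age <- age
  out$female <- female
  out$pc1 <- pc1
  out$pc2 <- pc2
  out$true_class <- as.integer(true_class)
  as_pts_cohort(out, snp_names = names(spec$snp_mafs))
}

#' Mark a data frame as a longitudinal PTS cohort
#'
#' Validates the header contract and field invariants (wave-1 scores always
#' observed, CTS totals in 0-24 and equal to the item sum when items are
#' present, dosages in 0/1/2 or missing) and attaches cohort metadata.
#'
#' @param df Data frame with the documented columns.
#' @param snp_names Names of the SNPs; defaults to the `dosage_*` columns.
#' @return The data frame with class `pts_cohort`.
#' @export
as_pts_cohort <- function(df, snp_names = NULL) {
  need <- c("subject_id", "pts_w1", "age", "female", "pc1", "pc2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort table is missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyNA(df$pts_w1))
    stop("pts_w1 must be observed for every subject (rows ",
         paste(utils::head(which(is.na(df$pts_w1)), 5L), collapse = ", "),
         ")", call. = FALSE)
  if (is.null(snp_names)) {
    snp_names <- sub("^dosage_", "", grep("^dosage_", names(df), value = TRUE))
  }
  for (snp in snp_names) {
    col <- df[[paste0("dosage_", snp)]]
    bad <- !is.na(col) & !(col %in% c(0, 1, 2))
    if (any(bad))
      stop("dosage_", snp, " has values outside {0,1,2} at rows ",
           paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
  }
  if ("cts_total" %in% names(df)) {
    tot <- df$cts_total
    bad <- !is.na(tot) & (tot < 0 | tot > 24)
    if (any(bad))
      stop("cts_total outside [0, 24] at rows ",
           paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
    items <- df[, grep("^cts_i", names(df)), drop = FALSE]
    if (ncol(items) == 6L) {
      ok <- stats::complete.cases(items)
      mismatch <- ok & !is.na(tot) & rowSums(items) != tot
      if (any(mismatch))
        stop("cts_total does not equal the item sum at rows ",
             paste(utils::head(which(mismatch), 5L), collapse = ", "),
             call. = FALSE)
    }
  }
  structure(df,
            snp_names = snp_names,
            wave_times = 0:2,
            class = unique(c("pts_cohort", class(df))))
}

#' @export
print.pts_cohort <- function(x, ...) {
  cat("PTS cohort:", nrow(x), "subjects,",
      sum(!is.na(x$pts_w2)), "observed at wave 2,",
      sum(!is.na(x$pts_w3)), "at wave 3\n")
  cat("SNPs:", paste(attr(x, "snp_names"), collapse = ", "), "\n")
  NextMethod()
}

#' Draw PCL-C item responses consistent with a target total
#'
#' Samples 17 item scores, each on 1-5, summing exactly to the (rounded)
#' target total, uniformly over all valid compositions. Counts of bounded
#' compositions are computed by dynamic programming and items drawn
#' sequentially in proportion to the number of completions.
#'
#' @param total_target Target total in `[17, 85]`.
#' @param n_items Number of items; the PCL-C has 17.
#' @return Integer vector of `n_items` responses in 1-5 summing to
#'   `round(total_target)`.
#' @examples
#' sum(simulate_pcl_items(44))
#' @export
simulate_pcl_items <- function(total_target, n_items = 17L) {
  total <- round(total_target)
  if (!is.finite(total) || total < n_items || total > 5L * n_items)
    stop("target total ", total_target, " is unreachable with ", n_items,
         " items on 1-5", call. = FALSE)
  s <- total - n_items               # excess over the all-ones floor
  # counts[j + 1, v + 1] = number of ways j items (each 0..4) sum to v
  counts <- matrix(0, n_items + 1L, s + 1L)
  counts[1L, 1L] <- 1
  if (s > 0 || n_items > 0) {
    for (j in seq_len(n_items)) {
      for (v in 0:s) {
        lo <- max(0L, v - 4L)
        counts[j + 1L, v + 1L] <- sum(counts[j, (lo:v) + 1L])
      }
    }
  }
  items <- integer(n_items)
  rem <- s
  for (j in seq_len(n_items)) {
    left <- n_items - j              # items remaining after this one
    vals <- max(0L, rem - 4L * left):min(4L, rem)
    w <- counts[left + 1L, rem - vals + 1L]
    pick <- if (length(vals) == 1L) vals else
      sample(vals, 1L, prob = w / sum(w))
    items[j] <- pick
    rem <- rem - pick
  }
  items + 1L
}
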