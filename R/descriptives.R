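# Scale scoring, psychometrics, genotype QC, gene-environment correlation,
# and the cross-tabulation / median-split decomposition of an interaction.

#' Score the 17-item PCL-C
#'
#' Sums 17 items each rated 1-5 to a total on 17-85 and flags probable PTSD
#' at the cut-off. The default rule counts a total at or above the cut-off
#' as probable (`rule = "gte"`, the common scoring convention); the
#' strict-exceed rule is available as `rule = "gt"`. The boundary choice
#' affects descriptives only, never the trajectory or regression models.
#'
#' @param items Numeric vector of 17 item scores, or an n x 17 matrix.
#' @param cutoff Probable-PTSD cut-off (default 44).
#' @param rule `"gte"` (total >= cutoff, default) or `"gt"` (total >
#'   cutoff).
#' @return List with `total`, `probable_ptsd`, and the `rule` applied.
#' @export
score_pcl <- function(items, cutoff = 44, rule = c("gte", "gt")) {
  rule <- match.arg(rule)
  m <- if (is.matrix(items)) items else matrix(items, nrow = 1L)
  if (ncol(m) != 17L)
    stop("PCL-C scoring needs 17 items, got ", ncol(m), call. = FALSE)
  bad <- which(!(m %in% 1:5) | is.na(m))
  if (length(bad))
    stop("PCL-C item out of range 1-5 at position ", bad[1L], call. = FALSE)
  total <- rowSums(m)
  probable <- if (rule == "gte") total >= cutoff else total > cutoff
  if (!is.matrix(items)) {
    total <- total[[1L]]
    probable <- probable[[1L]]
  }
  list(total = total, probable_ptsd = probable, rule = rule)
}

#' Score the CTS physical assault subscale
#'
#' Sums six items each rated 0-4 to a childhood physical abuse severity
#' score on 0-24.
#'
#' @param items Numeric vector of 6 items, or an n x 6 matrix.
#' @return Total score(s) in `[0, 24]`.
#' @export
score_cts <- function(items) {
  m <- if (is.matrix(items)) items else matrix(items, nrow = 1L)
  if (ncol(m) != 6L)
    stop("CTS scoring needs 6 items, got ", ncol(m), call. = FALSE)
  bad <- which(!(m %in% 0:4) | is.na(m))
  if (length(bad))
    stop("CTS item out of range 0-4 at position ", bad[1L], call. = FALSE)
  total <- rowSums(m)
  if (!is.matrix(items)) total <- total[[1L]]
  total
}

#' Cronbach's alpha
#'
#' `(k / (k - 1)) * (1 - sum(item variances) / variance(total score))`.
#'
#' @param items n x k matrix of item responses, complete rows.
#' @return Alpha.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) < 2L || nrow(items) < 3L)
    stop("need at least 2 items and 3 subjects", call. = FALSE)
  if (anyNA(items)) stop("complete rows required", call. = FALSE)
  vt <- stats::var(rowSums(items))
  if (vt == 0) stop("total-score variance is zero; alpha undefined",
                    call. = FALSE)
  k <- ncol(items)
  (k / (k - 1)) * (1 - sum(apply(items, 2L, stats::var)) / vt)
}

#' Spearman gene-environment correlation
#'
#' Rank correlation between SNP dosage and an environmental exposure, using
#' midranks for ties (dosages are heavily tied) and the t-approximation for
#' the p-value.
#'
#' @param dosage Genotype dosages (0/1/2).
#' @param abuse Exposure scores.
#' @return List with `rho`, `p_value`, and `n` (complete pairs used).
#' @export
spearman_rge <- function(dosage, abuse) {
  ok <- stats::complete.cases(dosage, abuse)
  x <- dosage[ok]; y <- abuse[ok]
  n <- length(x)
  if (n < 5L) stop("need at least 5 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("correlation undefined for a constant vector", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(rho = rho, p_value = p, n = n)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Full enumeration over heterozygote counts compatible with the observed
#' allele counts: the p-value is the total probability of all genotype
#' configurations as or less probable than the observed one under HWE.
#'
#' @param n_aa Count of major-allele homozygotes.
#' @param n_ab Count of heterozygotes.
#' @param n_bb Count of minor-allele homozygotes.
#' @return List with `p_value`, the observed heterozygote count, and the
#'   enumeration table (`het`, `prob`).
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  nb <- n_ab + 2L * n_bb           # minor allele count
  na <- n_ab + 2L * n_aa
  hs <- seq(nb %% 2L, min(na, nb), by = 2L)
  logp <- vapply(hs, function(h) {
    lgamma(n + 1) + h * log(2) -
      lgamma((na - h) / 2 + 1) - lgamma(h + 1) - lgamma((nb - h) / 2 + 1)
  }, numeric(1L))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[hs == n_ab]
  list(p_value = sum(pr[pr <= obs + 1e-12]),
       het_observed = n_ab,
       table = data.frame(het = hs, prob = pr))
}

# chi-square HWE test, offered for cross-checking the exact test.
hwe_chisq_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  p <- (2 * n_aa + n_ab) / (2 * n)
  q <- 1 - p
  expd <- n * c(p^2, 2 * p * q, q^2)
  stat <- sum((c(n_aa, n_ab, n_bb) - expd)^2 / expd)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Genotype quality control
#'
#' Per-SNP call rate, minor allele frequency, and exact HWE p-value, with
#' SNPs dropped when they fail any threshold (call rate > `call_rate`,
#' MAF > `maf_min`, HWE p > `hwe_min`).
#'
#' @param genotypes n x S matrix or data frame of dosages (0/1/2, NA =
#'   missing call), one column per SNP.
#' @param call_rate Minimum call rate (exclusive bound).
#' @param maf_min Minimum minor allele frequency (exclusive bound).
#' @param hwe_min Minimum exact HWE p-value (exclusive bound).
#' @return List with `genotypes` (passing columns) and `report` (per-SNP
#'   data frame with metrics, pass flags, and drop reasons).
#' @export
genotype_qc <- function(genotypes, call_rate = 0.95, maf_min = 0.01,
                        hwe_min = 1e-6) {
  g <- as.matrix(genotypes)
  snps <- colnames(g)
  if (is.null(snps)) snps <- paste0("snp", seq_len(ncol(g)))
  rows <- lapply(seq_len(ncol(g)), function(j) {
    x <- g[, j]
    called <- sum(!is.na(x))
    cr <- called / length(x)
    n2 <- sum(x == 2, na.rm = TRUE)
    n1 <- sum(x == 1, na.rm = TRUE)
    n0 <- sum(x == 0, na.rm = TRUE)
    maf <- if (called > 0) (n1 + 2 * n2) / (2 * called) else NA_real_
    maf <- min(maf, 1 - maf)
    hwe_p <- if (called > 0 && maf > 0)
      hwe_exact_test(n0, n1, n2)$p_value else NA_real_
    pass_cr <- cr > call_rate
    pass_maf <- !is.na(maf) && maf > maf_min
    pass_hwe <- !is.na(hwe_p) && hwe_p > hwe_min
    reason <- c(if (!pass_cr) sprintf("call rate %.3f <= %.2f", cr,
                                      call_rate),
                if (!pass_maf) sprintf("MAF %.4f <= %.2f",
                                       ifelse(is.na(maf), 0, maf), maf_min),
                if (!pass_hwe) sprintf("HWE p %s <= %.0e",
                                       format(hwe_p, digits = 3), hwe_min))
    data.frame(snp = snps[j], n_called = called, call_rate = cr, maf = maf,
               hwe_p = hwe_p, pass = pass_cr && pass_maf && pass_hwe,
               reason = if (length(reason)) paste(reason, collapse = "; ")
               else "", stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  keep <- report$snp[report$pass]
  list(genotypes = g[, report$pass, drop = FALSE], report = report)
}

#' Median split with ties assigned to the low stratum
#'
#' @param x Numeric vector.
#' @return Factor with levels `low` (x <= median) and `high`.
#' @export
median_split <- function(x) {
  med <- stats::median(x, na.rm = TRUE)
  factor(ifelse(x <= med, "low", "high"), levels = c("low", "high"))
}

#' Cross-tabulate genotype dosage within trajectory class
#'
#' Row percentages of dosage 0/1/2 within each class, with counts emitted
#' alongside percentages. When a stratifier is supplied, separate tables
#' are produced per stratum of its median split (ties at the median go to
#' the low stratum).
#'
#' @param modal Class labels or indices per subject.
#' @param dosage Genotype dosages (0/1/2) per subject.
#' @param stratifier Optional numeric vector to median-split on.
#' @return A `trajectory_crosstab`: list of per-stratum lists with `counts`
#'   and `percent` matrices (classes x dosage), plus the split value.
#' @export
crosstab_by_class <- function(modal, dosage, stratifier = NULL) {
  stopifnot(length(modal) == length(dosage))
  one_table <- function(cls, dos) {
    lev <- if (is.factor(cls)) levels(cls) else sort(unique(cls))
    counts <- t(vapply(lev, function(l)
      c(sum(dos[cls == l] == 0, na.rm = TRUE),
        sum(dos[cls == l] == 1, na.rm = TRUE),
        sum(dos[cls == l] == 2, na.rm = TRUE)), numeric(3L)))
    dimnames(counts) <- list(as.character(lev), c("0", "1", "2"))
    tot <- rowSums(counts)
    percent <- 100 * counts / ifelse(tot == 0, NA, tot)
    list(counts = counts, percent = percent)
  }
  if (is.null(stratifier)) {
    out <- list(overall = one_table(modal, dosage))
    split_value <- NULL
  } else {
    stopifnot(length(stratifier) == length(modal))
    strata <- median_split(stratifier)
    split_value <- stats::median(stratifier, na.rm = TRUE)
    out <- lapply(levels(strata), function(s)
      one_table(modal[strata == s], dosage[strata == s]))
    names(out) <- levels(strata)
  }
  structure(list(tables = out, split_value = split_value),
            class = "trajectory_crosstab")
}

#' @export
print.trajectory_crosstab <- function(x, ...) {
  for (nm in names(x$tables)) {
    cat(nm, if (!is.null(x$split_value))
      sprintf("(split at %.2f)", x$split_value), "\n")
    print(round(x$tables[[nm]]$percent, 1))
  }
  invisible(x)
}

#' Compare included vs dropped participants on study variables
#'
#' Welch t-tests for continuous variables and chi-square tests for
#' categorical ones, with a Bonferroni correction over the number of
#' variables tested. Degenerate variables (constant, or fewer than two
#' observations in a group) are skipped with a note.
#'
#' @param included Data frame for the analytic sample.
#' @param dropped Data frame for the excluded participants.
#' @param vars Named character vector mapping column names to
#'   `"continuous"` or `"categorical"`.
#' @return Data frame with statistic, df, p, Bonferroni-adjusted p, and
#'   significance flag per variable.
#' @export
compare_included_vs_dropped <- function(included, dropped, vars) {
  m <- length(vars)
  rows <- lapply(names(vars), function(v) {
    x <- included[[v]]; y <- dropped[[v]]
    res <- tryCatch({
      if (vars[[v]] == "continuous") {
        if (length(unique(stats::na.omit(c(x, y)))) < 2L)
          stop("constant variable")
        tt <- stats::t.test(x, y)
        data.frame(variable = v, type = "continuous",
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value,
                   note = "", stringsAsFactors = FALSE)
      } else {
        tab <- table(factor(c(rep("in", length(x)), rep("out", length(y)))),
                     c(x, y))
        if (any(dim(tab) < 2L)) stop("degenerate table")
        ct <- suppressWarnings(stats::chisq.test(tab))
        data.frame(variable = v, type = "categorical",
                   statistic = unname(ct$statistic),
                   df = unname(ct$parameter), p_value = ct$p.value,
                   note = "", stringsAsFactors = FALSE)
      }
    }, error = function(e)
      data.frame(variable = v, type = vars[[v]], statistic = NA_real_,
                 df = NA_real_, p_value = NA_real_,
                 note = paste("skipped:", conditionMessage(e)),
                 stringsAsFactors = FALSE))
    res
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p_value * m, 1)
  out$significant <- !is.na(out$p_bonferroni) & out$p_bonferroni < 0.05
  out
}
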