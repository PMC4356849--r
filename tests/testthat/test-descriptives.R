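test_that("PCL-C scoring spans 17-85 and applies the cut-off rule", {
  lo <- score_pcl(rep(1, 17))
  hi <- score_pcl(rep(5, 17))
  expect_equal(lo$total, 17)
  expect_false(lo$probable_ptsd)
  expect_equal(hi$total, 85)
  expect_true(hi$probable_ptsd)
  # boundary: default rule counts 44 as probable; strict-exceed does not
  items44 <- c(rep(3, 10), rep(2, 7)) # sums to 44
  expect_equal(sum(items44), 44)
  expect_true(score_pcl(items44)$probable_ptsd)
  expect_false(score_pcl(items44, rule = "gt")$probable_ptsd)
  expect_error(score_pcl(c(rep(1, 16), 6)), "out of range")
  expect_error(score_pcl(rep(1, 16)), "17 items")
})

test_that("CTS scoring sums six 0-4 items to a 0-24 severity score", {
  expect_equal(score_cts(rep(0, 6)), 0)
  expect_equal(score_cts(rep(4, 6)), 24)
  expect_equal(score_cts(c(1, 0, 2, 0, 0, 1)), 4)
  expect_error(score_cts(c(1, 0, 2, 0, 0, 5)), "out of range")
  m <- rbind(rep(1, 6), rep(2, 6))
  expect_equal(score_cts(m), c(6, 12))
})

test_that("Cronbach's alpha matches direct variance arithmetic", {
  # perfectly correlated items
  x <- rnorm(20)
  perfect <- cbind(x, x, x)
  expect_equal(cronbach_alpha(perfect), 1)
  # 4 x 3 hand matrix against the spreadsheet-style formula
  m <- rbind(c(1, 2, 1), c(2, 3, 3), c(3, 3, 2), c(4, 5, 4))
  item_vars <- apply(m, 2, var)
  tot_var <- var(rowSums(m))
  expect_equal(cronbach_alpha(m),
               (3 / 2) * (1 - sum(item_vars) / tot_var))
  expect_equal(cronbach_alpha(m), 0.95705521, tolerance = 1e-7)
  # independent items in large samples have alpha near 0
  set.seed(2)
  ind <- cbind(rnorm(4000), rnorm(4000))
  expect_lt(abs(cronbach_alpha(ind)), 0.1)
  expect_error(cronbach_alpha(cbind(rep(1, 5), rep(2, 5))), "variance")
})

test_that("Spearman rGE uses midranks and the t approximation", {
  expect_equal(spearman_rge(1:6, c(2, 4, 6, 7, 9, 12))$rho, 1)
  expect_equal(spearman_rge(c(1, 2, 3, 4, 5), c(3, 1, 2, 5, 4))$rho,
               1 - 6 * sum(c(2, -1, -1, 1, -1)^2 / (5 * 24)))
  # heavily tied dosages agree with the base midrank implementation
  set.seed(3)
  g <- rbinom(120, 2, 0.2)
  a <- rnbinom(120, mu = 3.6, size = 1.2)
  ours <- spearman_rge(g, a)
  base_rho <- suppressWarnings(
    cor.test(g, a, method = "spearman"))$estimate
  expect_equal(ours$rho, unname(base_rho), tolerance = 1e-10)
  expect_error(spearman_rge(rep(1, 10), rnorm(10)), "constant")
})

test_that("the exact HWE test enumerates heterozygote configurations", {
  res <- hwe_exact_test(0, 4, 0)
  expect_equal(res$table$prob, c(6, 48, 16) / 70, tolerance = 1e-12)
  expect_equal(res$p_value, (6 + 16) / 70, tolerance = 1e-12)
  # agreement with an independent brute-force enumeration on all small
  # tables
  for (n_aa in 0:4) for (n_ab in 0:4) for (n_bb in 0:3) {
    if (n_aa + n_ab + n_bb < 2) next
    expect_equal(hwe_exact_test(n_aa, n_ab, n_bb)$p_value,
                 hwe_brute_force(n_aa, n_ab, n_bb),
                 tolerance = 1e-9,
                 label = paste("table", n_aa, n_ab, n_bb))
  }
})

test_that("exact and chi-square HWE p-values agree in large balanced
          samples", {
  # agreement holds at exact HWE balance and on the heterozygote-deficit
  # side; with a heterozygote excess the exact test's two-sided tail is
  # asymmetric and the two p-values legitimately diverge, so that side is
  # checked only at the decision level
  for (maf in c(0.2, 0.4)) {
    n <- 600
    nb <- round(2 * n * maf)
    for (d in c(0, -2, -4, -8)) {
      n1 <- round(2 * maf * (1 - maf) * n) + d
      if ((nb - n1) %% 2 != 0) n1 <- n1 + 1
      n2 <- (nb - n1) / 2
      n0 <- n - n1 - n2
      p_exact <- hwe_exact_test(n0, n1, n2)$p_value
      p_chi <- ptstraj:::hwe_chisq_test(n0, n1, n2)
      expect_lt(abs(p_exact - p_chi), 0.02)
    }
    # excess side: both tests must still agree on passing lenient QC
    n1 <- round(2 * maf * (1 - maf) * n) + 4
    if ((nb - n1) %% 2 != 0) n1 <- n1 + 1
    n2 <- (nb - n1) / 2
    n0 <- n - n1 - n2
    expect_gt(hwe_exact_test(n0, n1, n2)$p_value, 1e-6)
    expect_gt(ptstraj:::hwe_chisq_test(n0, n1, n2), 1e-6)
  }
})

test_that("genotype QC applies the stated thresholds with reasons", {
  set.seed(5)
  n <- 400
  good <- rbinom(n, 2, 0.3)
  low_maf <- rbinom(n, 2, 0.005)
  sparse <- good
  sparse[sample(n, 40)] <- NA # 10% missing fails 95% call rate
  hwe_bad <- c(rep(0, 200), rep(2, 200)) # no heterozygotes
  g <- cbind(good = good, low_maf = low_maf, sparse = sparse,
             hwe_bad = hwe_bad)
  qc <- genotype_qc(g)
  expect_equal(qc$report$pass, c(TRUE, FALSE, FALSE, FALSE))
  expect_match(qc$report$reason[2], "MAF")
  expect_match(qc$report$reason[3], "call rate")
  expect_match(qc$report$reason[4], "HWE")
  expect_equal(colnames(qc$genotypes), "good")
  # MAF counting oracle on a hand table
  hand <- c(0, 0, 1, 1, 2, NA)
  rep1 <- genotype_qc(cbind(s = hand))$report
  expect_equal(rep1$maf, (2 + 2 * 1) / (2 * 5))
  expect_equal(rep1$call_rate, 5 / 6)
})

test_that("cross-tabs give row percentages with counts alongside", {
  modal <- c(rep("high", 31), rep("low", 40))
  dose <- c(rep(0, 18), rep(1, 13), rep(0, 40))
  ct <- crosstab_by_class(modal, dose)
  expect_equal(unname(ct$tables$overall$percent["high", ]),
               c(58.1, 41.9, 0.0), tolerance = 0.05)
  expect_equal(unname(ct$tables$overall$counts["high", ]), c(18, 13, 0))
  expect_equal(unname(rowSums(ct$tables$overall$percent)), c(100, 100))
  # all-zero dosage: 100 / 0 / 0 everywhere
  ct0 <- crosstab_by_class(modal, rep(0, 71))
  expect_true(all(ct0$tables$overall$percent[, 1] == 100))
  # invariance to subject order
  perm <- sample(71)
  ct_p <- crosstab_by_class(modal[perm], dose[perm])
  expect_equal(ct_p$tables$overall$counts, ct$tables$overall$counts)
})

test_that("the median split sends ties to the low stratum", {
  x <- c(1, 2, 3, 3, 4, 9)
  s <- median_split(x)
  expect_equal(as.character(s), c("low", "low", "low", "low", "high",
                                  "high"))
  modal <- rep(c("a", "b"), 3)
  ct <- crosstab_by_class(modal, c(0, 1, 2, 0, 1, 2), stratifier = x)
  expect_named(ct$tables, c("low", "high"))
  expect_equal(sum(ct$tables$low$counts), 4)
})

test_that("included-vs-dropped comparisons flag real shifts only", {
  set.seed(21)
  inc <- data.frame(age = rnorm(200, 50, 10), female = rbinom(200, 1, 0.5))
  same <- data.frame(age = rnorm(200, 50, 10), female = rbinom(200, 1, 0.5))
  shifted <- data.frame(age = rnorm(200, 60, 10),
                        female = rbinom(200, 1, 0.5))
  vars <- c(age = "continuous", female = "categorical")
  res_same <- compare_included_vs_dropped(inc, same, vars)
  expect_false(any(res_same$significant))
  res_shift <- compare_included_vs_dropped(inc, shifted, vars)
  expect_true(res_shift$significant[res_shift$variable == "age"])
  # degenerate variables are skipped with a note, not an error
  inc$flat <- 1; shifted$flat <- 1
  res_deg <- compare_included_vs_dropped(
    inc, shifted, c(vars, flat = "continuous"))
  expect_match(res_deg$note[res_deg$variable == "flat"], "skipped")
})

test_that("scale scores error on fuzzed out-of-range input, never clip", {
  set.seed(8)
  for (r in 1:20) {
    items <- sample(1:5, 17, replace = TRUE)
    bad_pos <- sample(17, 1)
    items[bad_pos] <- sample(c(0, 6, 2.5, NA), 1)
    expect_error(score_pcl(items))
    cts <- sample(0:4, 6, replace = TRUE)
    cts[sample(6, 1)] <- sample(c(-1, 5, 1.5, NA), 1)
    expect_error(score_cts(cts))
  }
})
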