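test_that("median-of-ratios size factors behave under scaling", {
  m <- matrix(rpois(300, 50) + 1L, 30, 10)
  expect_equal(size_factors(cbind(m[, 1], m[, 1], m[, 1])), rep(1, 3))
  s <- size_factors(cbind(a = m[, 1], b = 2L * m[, 1]))
  expect_equal(s[2] / s[1], 2, ignore_attr = TRUE)
  # hand-computed 3x3 case: row geometric means 4, 2, 8
  h <- matrix(c(2, 1, 4, 4, 2, 8, 8, 4, 16), 3, 3)
  expect_equal(size_factors(h) / size_factors(h)[1], c(1, 2, 4))
  # equivariance: scaling one sample scales its factor
  s0 <- size_factors(m)
  m2 <- m; m2[, 3] <- m2[, 3] * 3L
  s2 <- size_factors(m2)
  expect_equal((s2[3] / s2[1]) / (s0[3] / s0[1]), 3, tolerance = 1e-12)
})

test_that("size factors match the DESeq2 convention up to rescaling", {
  skip_if_not_installed("DESeq2")
  set.seed(21)
  # odd row count: the median ratio is a single element, so the plain-ratio
  # and log-ratio medians coincide exactly
  m <- matrix(rnbinom(2020, mu = 60, size = 3) + 1L, 101, 20)
  ours <- size_factors(m)
  theirs <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(ours / ours[1], theirs / theirs[1], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("detection summaries count thresholds and chromosomes", {
  ref <- toy_reference()
  m <- matrix(0L, 4, 6, dimnames = list(mature_names(ref), paste0("s", 1:6)))
  m["mirA-5p", 1:3] <- 5L
  m["mirB-3p", ] <- 1L
  d <- detection_summary(m, min_reads = 1, ref = ref)
  expect_equal(unname(d$prevalence["mirA-5p"]), 0.5)
  expect_equal(unname(d$prevalence["mirA-3p"]), 0)
  # chromosome with every mature name detected reports 100%
  chrY <- d$per_chromosome[d$per_chromosome$chromosome == "chrY", ]
  expect_equal(chrY$n_detected, 1)
  expect_equal(chrY$pct_detected, 100 * 1 / 2)
  # prevalence is monotone non-increasing in the threshold
  prev1 <- detection_summary(m, 1)$prevalence
  prev5 <- detection_summary(m, 5)$prevalence
  expect_true(all(prev5 <= prev1))
  expect_true(all(detection_summary(m * 0L, 1)$prevalence == 0))
})

test_that("robust CV is the unscaled MAD over the median", {
  r <- robust_cv(c(2, 4, 4, 4, 5, 5, 7, 9))
  expect_equal(r$median_expr, 4.5)
  expect_equal(r$mad, 0.5)
  expect_equal(r$cv, 0.5 / 4.5)
  expect_equal(robust_cv(c(5, 5, 5, 5))$cv, 0)
  # scale invariance
  x <- c(1.5, 3, 4, 8, 13)
  expect_equal(robust_cv(x * 7)$cv, robust_cv(x)$cv)
  # permutation invariance
  expect_equal(robust_cv(rev(x))$cv, robust_cv(x)$cv)
  expect_error(robust_cv(c(0.1, 0.2, 0.3)), "median")
  # mean-absolute-deviation variant differs but stays scale invariant
  expect_equal(robust_cv(x * 7, "mean")$cv, robust_cv(x, "mean")$cv)
})

test_that("CV ranking filters on the median and orders deterministically", {
  m <- rbind(hi = c(10, 12, 14, 16), lo = c(0, 0, 1, 0),
             flat = c(8, 8, 8, 8))
  cv <- cv_ranking(m, min_median = 1)
  expect_equal(cv$mirna, c("flat", "hi")) # lo excluded; flat cv 0 first
  expect_equal(cv$rank, 1:2)
})

test_that("Spearman handles ties, monotonicity and small-n exactness", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_scc(x, x^2)$scc, 1)
  expect_equal(spearman_scc(x, -x)$scc, -1)
  tied_x <- c(1, 2, 2, 3); tied_y <- c(1, 2, 3, 4)
  expect_equal(spearman_scc(tied_x, tied_y)$scc,
               brute_spearman(tied_x, tied_y))
  expect_equal(spearman_scc(tied_x, tied_y)$scc,
               unname(suppressWarnings(
                 cor.test(tied_x, tied_y, method = "spearman")$estimate)))
  expect_false(spearman_scc(c(2, 2, 2, 2), c(1, 2, 3, 4))$defined)
  # exact permutation p agrees with cor.test's exact p when there are no ties
  for (n in c(5, 6, 7)) {
    set.seed(n)
    a <- sample(n); b <- sample(n)
    expect_equal(spearman_scc(a, b)$p,
                 cor.test(a, b, method = "spearman", exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("Wilcoxon signed-rank matches brute-force enumeration", {
  # all-positive differences at n = 6: p = 2/64
  expect_equal(wilcoxon_signed_rank(7:12, 1:6)$p, 2 / 64)
  expect_equal(wilcoxon_signed_rank(1:5, 1:5)$p, 1)
  expect_true(wilcoxon_signed_rank(1:5, 1:5)$all_zero)
  set.seed(31)
  for (n in 3:8) {
    for (k in 1:10) {
      a <- sample(1:6, n, TRUE); b <- sample(1:6, n, TRUE)
      if (all(a == b)) next
      expect_equal(wilcoxon_signed_rank(a, b)$p, brute_wilcoxon_p(a, b),
                   tolerance = 1e-12)
    }
  }
  # exact and normal branches agree within 0.01 at n = 25
  set.seed(32)
  a <- rnorm(25); b <- rnorm(25)
  pe <- wilcoxon_signed_rank(a, b, exact_n_max = 25)$p
  pn <- wilcoxon_signed_rank(a, b, exact_n_max = 10)$p
  expect_lt(abs(pe - pn), 0.01)
})

test_that("stability reports identity, null and planted-shift behaviour", {
  ref <- simulate_reference(30, 0.5, seed = 41)
  coh <- simulate_cohort(20, seed = 42)
  cfg <- sim_config(library_size_mean = 1e5, mirna_fraction = 0.5,
                    dispersion = 0.1, baseline_sdlog = 1, libsize_sdlog = 0,
                    batch_sd = 0)
  sim <- simulate_counts(ref, coh, list(), cfg, seed = 43)
  m <- normalize_counts(sim$counts)
  nine <- rownames(m)[order(-rowMeans(m))][1:9]
  idem <- stability_report(m, m, nine)
  expect_true(all(abs(idem$per_subject$scc - 1) < 1e-12))
  expect_true(all(idem$per_mirna$wilcoxon_p == 1))
  # independent re-simulation: per-subject SCC centred near zero
  sim2 <- simulate_counts(ref, coh, list(), cfg, seed = 44)
  perm <- normalize_counts(sim2$counts)
  set.seed(45)
  perm <- perm[sample(nrow(perm)), ]
  rownames(perm) <- rownames(m)
  null_scc <- stability_report(m, perm, NULL)$per_subject$scc
  expect_lt(abs(median(null_scc)), 0.25)
  # planted shift: only the shifted miRNA flags at 20 repeat subjects
  t2 <- normalize_counts(sim$counts)
  t2[nine[1], ] <- t2[nine[1], ] * 3
  rep_ <- stability_report(m, t2, nine)
  expect_lt(rep_$per_mirna$wilcoxon_p[1], 0.01)
  expect_true(all(rep_$per_mirna$wilcoxon_p[-1] > 0.05))
  m1 <- m[, 1:2, drop = FALSE]
  colnames(m1) <- c("x", "y")
  expect_error(stability_report(m1, m, NULL), "shared")
})
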