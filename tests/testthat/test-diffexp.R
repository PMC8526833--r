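test_that("dispersion estimation recovers known NB dispersions", {
  set.seed(51)
  s <- rep(1, 1000)
  cells <- factor(rep(c("a", "b"), 500))
  # Poisson rows land at the floor
  y_pois <- matrix(rpois(3000, 100), 3, 1000)
  a_pois <- estimate_dispersion(y_pois, cells, s)
  expect_true(all(a_pois < 0.01))
  # alpha = 0.5 recovered within [0.3, 0.7] at n = 500 per cell
  y_nb <- matrix(rnbinom(2000, mu = 100, size = 2), 2, 1000)
  a_nb <- estimate_dispersion(y_nb, cells, s)
  expect_true(all(a_nb > 0.3 & a_nb < 0.7))
  # constant row: floor
  y_const <- matrix(7L, 1, 1000)
  expect_lt(estimate_dispersion(y_const, cells, s), 1e-7)
  # degenerate cells fall back to pooling with a warning
  expect_warning(
    estimate_dispersion(y_nb[, 1:3, drop = FALSE],
                        factor(c("a", "b", "c")), s[1:3]),
    "pooling")
})

test_that("the NB Wald fit agrees with glm oracles", {
  set.seed(52)
  n <- 200
  x <- rep(0:1, each = n / 2)
  X <- cbind(1, x)
  s <- runif(n, 0.8, 1.25)
  # Poisson limit: alpha ~ 0 vs a Poisson regression oracle
  mu <- s * exp(4 + 0.7 * x)
  y <- rpois(n, mu)
  ours <- nb_wald(y, X, s, alpha = 1e-10, coef_index = 2)
  oracle <- glm(y ~ x + offset(log(s)), family = poisson())
  b <- summary(oracle)$coefficients["x", ]
  expect_equal(ours$log2fc * log(2), unname(b["Estimate"]), tolerance = 1e-6)
  expect_equal(ours$wald, unname(b["Estimate"] / b["Std. Error"]),
               tolerance = 0.01)
  # fixed-dispersion NB vs MASS's negative.binomial family
  y2 <- rnbinom(n, mu = mu, size = 1 / 0.4)
  ours2 <- nb_wald(y2, X, s, alpha = 0.4, coef_index = 2)
  fam <- MASS::negative.binomial(theta = 1 / 0.4)
  oracle2 <- glm(y2 ~ x + offset(log(s)), family = fam)
  # dispersion = 1: the NB variance is fully specified by theta
  b2 <- summary(oracle2, dispersion = 1)$coefficients["x", ]
  expect_equal(ours2$log2fc * log(2), unname(b2["Estimate"]),
               tolerance = 1e-6)
  expect_equal(ours2$se * log(2), unname(b2["Std. Error"]),
               tolerance = 0.01)
})

test_that("separated and degenerate fits are flagged, not silently wrong", {
  n <- 40
  x <- rep(0:1, each = n / 2)
  X <- cbind(1, x)
  s <- rep(1, n)
  y <- c(rpois(n / 2, 50), rep(0L, n / 2)) # test group all zero
  r <- nb_wald(y, X, s, alpha = 0.1, coef_index = 2)
  expect_equal(r$flag, "separated")
  expect_lt(r$log2fc, -10)
})

test_that("BH adjustment matches the definitional step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(53)
  for (k in 1:20) {
    p <- runif(sample(3:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, brute_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_equal(order(q[order(p)]), seq_along(p)) # order-preserving
  }
  # missing values pass through; invalid values error
  q <- bh_adjust(c(0.01, NA, 0.04))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], brute_bh(c(0.01, 0.04)))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEmiRNA calling needs both significance and abundance", {
  res <- data.frame(q = c(0.04, 0.04, 0.06), median_ref = c(12, 8, 50),
                    median_test = c(3, 9, 50), log2fc = c(1, 1, -1))
  out <- call_demirnas(res)
  expect_equal(out$is_de, c(TRUE, FALSE, FALSE))
  expect_equal(out$direction, c("up", NA, NA))
})

test_that("the full DE path holds its nominal type-I error on null data", {
  ref <- simulate_reference(500, 0.5, seed = 61)
  coh <- categorize_cohort(simulate_cohort(100, seed = 62))
  sim <- simulate_counts(ref, coh, list(),
                         sim_config(library_size_mean = 1e5,
                                    mirna_fraction = 0.5, dispersion = 0.3,
                                    baseline_sdlog = 1.5), seed = 63)
  de <- de_analysis(sim$counts, coh, c("sex", "male", "female"),
                    adjust = "age", batch = "library_pool")
  frac <- mean(de$p < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
  expect_true(all(de$q >= de$p, na.rm = TRUE))
})

test_that("planted effects are recovered with direction and magnitude", {
  marg <- default_cohort_marginals()
  marg$sex <- c(female = 0.5, male = 0.5)
  ref <- simulate_reference(300, 0.5, seed = 64)
  coh <- categorize_cohort(simulate_cohort(200, marginals = marg, seed = 65))
  cfg <- sim_config(library_size_mean = 1e5, mirna_fraction = 0.5,
                    dispersion = 0.3, baseline_sdlog = 1.5)
  sim0 <- simulate_counts(ref, coh, list(), cfg, seed = 66)
  med <- apply(normalize_counts(sim0$counts), 1, median)
  set.seed(67)
  targets <- sample(names(med)[med >= 20], 20)
  eff <- effect_spec("sex", c("female", "male"), targets,
                     rep(c(1.5, -1.5), 10))
  sim <- simulate_counts(ref, coh, list(eff), cfg, seed = 66)
  de <- de_analysis(sim$counts, coh, c("sex", "male", "female"),
                    adjust = "age", batch = "library_pool")
  hit <- de[match(targets, de$mirna), ]
  expect_equal(mean(hit$log2fc), mean(eff$log2fc), tolerance = 0.2)
  expect_gte(mean(hit$is_de), 0.8)
  called <- de$mirna[de$is_de]
  expect_lte(mean(!(called %in% targets)), 0.1)
  # direction matches the planted sign
  expect_true(all(sign(hit$log2fc) == sign(eff$log2fc)))
})

test_that("sex-stratified analysis reuses the same code path", {
  marg <- default_cohort_marginals()
  ref <- simulate_reference(100, 0.5, seed = 71)
  coh <- categorize_cohort(simulate_cohort(150, marginals = marg, seed = 72))
  sim <- simulate_counts(ref, coh, list(),
                         sim_config(library_size_mean = 5e4,
                                    mirna_fraction = 0.5, dispersion = 0.3,
                                    baseline_sdlog = 1.5), seed = 73)
  females <- coh$subject_id[coh$sex == "female"]
  de_f <- de_analysis(sim$counts[, females], coh[coh$sex == "female", ],
                      c("smoking", "former", "never"), adjust = "age",
                      batch = "library_pool")
  expect_equal(nrow(de_f), nrow(sim$counts))
  expect_equal(attr(de_f, "n_used") <= length(females), TRUE)
})

test_that("continuous covariate SCC classifies at the 0.2 boundaries", {
  set.seed(81)
  n <- 300
  age <- runif(n, 18, 81)
  base <- matrix(rnbinom(20 * n, mu = 50, size = 5), 20, n,
                 dimnames = list(paste0("m", 1:20), paste0("s", 1:n)))
  # one planted monotone row
  base[1, ] <- rnbinom(n, mu = 20 + 2 * age, size = 10)
  r <- continuous_scc(base, age, min_median = 10)
  expect_equal(r$category[r$mirna == "m1"], "increasing")
  expect_gt(mean(r$category[-1] == "unaltered"), 0.9)
  # permuted covariate: essentially everything unaltered
  rp <- continuous_scc(base, sample(age), min_median = 10)
  expect_gt(mean(rp$category == "unaltered"), 0.85)
  # the boundary is strict: exactly +-0.2 is unaltered
  expect_equal(scc_category(c(0.2, 0.21, -0.2, -0.21, 0, NA)),
               c("unaltered", "increasing", "unaltered", "decreasing",
                 "unaltered", NA))
})

test_that("heatmap transform z-scores rows and clusters deterministically", {
  set.seed(91)
  m <- matrix(rlnorm(40, 3, 1), 4, 10,
              dimnames = list(paste0("m", 1:4), paste0("s", 1:10)))
  m[2, ] <- m[1, ] # identical pair merges first
  h <- heatmap_matrix(m, rownames(m))
  expect_equal(unname(rowMeans(h$z)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(h$z, 1, sd)), rep(1, 4), tolerance = 1e-12)
  expect_equal(sort(h$row_hclust$merge[1, ]), c(-2, -1))
  # 4-row toy: first merge joins the closest pair, as brute force says
  m2 <- matrix(runif(24, 0, 2), 4, 6, dimnames = list(paste0("r", 1:4), NULL))
  z <- t(scale(t(m2)))
  d <- as.matrix(dist(z))
  diag(d) <- Inf
  closest <- sort(arrayInd(which.min(d), dim(d))[1, ])
  h2 <- heatmap_matrix(10^m2 - 1, rownames(m2)) # log10(x+1) recovers m2
  expect_equal(sort(-h2$row_hclust$merge[1, ]), closest)
  # zero-variance row flagged and zeroed
  m3 <- rbind(flat = rep(5, 6), var = rlnorm(6, 2, 1))
  h3 <- heatmap_matrix(m3, rownames(m3))
  expect_equal(h3$zero_variance, "flat")
  expect_true(all(h3$z["flat", ] == 0))
})
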