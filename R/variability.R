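#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median across features of the
#' ratio of its count to the feature's geometric mean over samples, taken
#' over features positive in every sample; factors are then rescaled to
#' geometric mean 1. When no feature is positive in all samples the
#' geometric means are computed over the positive subset of each feature,
#' with a warning.
#'
#' @param counts integer matrix, features x samples (>= 2 samples)
#' @return numeric vector of per-sample size factors, geometric mean 1
#' @export
size_factors <- function(counts) {
  stopifnot(ncol(counts) >= 2)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (any(all_pos)) {
    sub <- counts[all_pos, , drop = FALSE]
    geo <- exp(rowMeans(log(sub)))
    s <- apply(sub / geo, 2, stats::median)
  } else {
    warning("no feature positive in all samples; ",
            "using positive-subset geometric means")
    any_pos <- rowSums(counts > 0) > 0
    if (!any(any_pos)) stop("all-zero count matrix")
    sub <- counts[any_pos, , drop = FALSE]
    geo <- exp(apply(sub, 1, function(x) mean(log(x[x > 0]))))
    rat <- sub / geo
    rat[sub == 0] <- NA
    s <- apply(rat, 2, stats::median, na.rm = TRUE)
  }
  s / exp(mean(log(s)))
}

#' Normalized counts
#' @param counts integer matrix
#' @param s size factors (default recomputed via [size_factors()])
#' @return matrix of counts divided columnwise by size factors
#' @export
normalize_counts <- function(counts, s = size_factors(counts)) {
  sweep(counts, 2, s, "/")
}

#' Detection summaries
#'
#' A feature is detected in a sample when its count reaches `min_reads`.
#' Reports per-miRNA detection prevalence, per-sample detected totals, and
#' (when the reference carries chromosome labels) the fraction of each
#' chromosome's mature name space detected in at least one sample.
#'
#' @param counts integer matrix, mature miRNAs x samples
#' @param min_reads detection threshold (default 1 read)
#' @param ref optional `mirna_reference` for the per-chromosome summary
#' @return list with `prevalence` (named numeric), `per_sample_detected`
#'   (named integer), and `per_chromosome` (data.frame: `chromosome`,
#'   `n_reference`, `n_detected`, `pct_detected`) or `NULL`
#' @export
detection_summary <- function(counts, min_reads = 1, ref = NULL) {
  det <- counts >= min_reads
  out <- list(
    prevalence = rowMeans(det),
    per_sample_detected = colSums(det),
    per_chromosome = NULL
  )
  if (!is.null(ref)) {
    chrom <- rep(ref$precursors$chromosome, each = 2L)
    names(chrom) <- mature_names(ref)
    chrom <- chrom[rownames(counts)]
    ever <- rowSums(det) > 0
    tab <- tapply(ever, chrom, function(x) c(length(x), sum(x)))
    chr <- names(tab)
    n_ref <- vapply(tab, `[`, numeric(1), 1L)
    n_det <- vapply(tab, `[`, numeric(1), 2L)
    out$per_chromosome <- data.frame(
      chromosome = chr, n_reference = n_ref, n_detected = n_det,
      pct_detected = 100 * n_det / n_ref, row.names = NULL)
  }
  out
}

#' Robust coefficient of variation of one expression row
#'
#' CV is the unscaled median absolute deviation divided by the median of
#' normalized expression (no 1.4826 consistency constant). Only rows whose
#' median is at least 1 normalized read are eligible; lower medians are a
#' contract violation here and must be filtered upstream. `mad_kind =
#' "mean"` computes the mean absolute deviation about the median instead.
#'
#' @param normalized_row numeric vector of normalized reads for one miRNA
#' @param mad_kind `"median"` (default) or `"mean"` absolute deviation
#' @return list with `median_expr`, `mad`, `cv`
#' @export
robust_cv <- function(normalized_row, mad_kind = c("median", "mean")) {
  mad_kind <- match.arg(mad_kind)
  med <- stats::median(normalized_row)
  if (med < 1) stop("robust_cv requires a median of at least 1 normalized read")
  dev <- abs(normalized_row - med)
  mad <- if (mad_kind == "median") stats::median(dev) else mean(dev)
  list(median_expr = med, mad = mad, cv = mad / med)
}

#' Rank miRNAs by inter-individual expression variability
#'
#' Applies [robust_cv()] to every row whose median normalized expression is
#' at least `min_median` and ranks ascending by CV (ties broken by miRNA
#' name for determinism).
#'
#' @param normalized matrix of normalized counts, miRNAs x samples
#' @param min_median eligibility threshold on the row median (default 1)
#' @param mad_kind passed to [robust_cv()]
#' @return data.frame (`mirna`, `median_expr`, `mad`, `cv`, `rank`),
#'   ordered by rank
#' @export
cv_ranking <- function(normalized, min_median = 1,
                       mad_kind = c("median", "mean")) {
  mad_kind <- match.arg(mad_kind)
  med <- apply(normalized, 1, stats::median)
  keep <- med >= min_median
  rows <- lapply(which(keep), function(i) {
    r <- robust_cv(normalized[i, ], mad_kind)
    data.frame(mirna = rownames(normalized)[i], median_expr = r$median_expr,
               mad = r$mad, cv = r$cv)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna = character(), median_expr = numeric(),
               mad = numeric(), cv = numeric())
  out <- out[order(out$cv, out$mirna), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Spearman's rank correlation with average ranks
#'
#' Ranks with average ties, then Pearson correlation of the ranks. The
#' p-value uses exact permutation enumeration for n <= 9 and the t
#' approximation above. Zero variance in either rank vector yields an
#' undefined, flagged record.
#'
#' @param x,y numeric vectors of equal length >= 4
#' @param exact_n_max largest n for exact permutation enumeration (default 9)
#' @return list with `scc`, `p`, `defined`
#' @export
spearman_scc <- function(x, y, exact_n_max = 9L) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(scc = NA_real_, p = NA_real_, defined = FALSE))
  }
  rho <- stats::cor(rx, ry)
  if (n <= exact_n_max) {
    perms <- .permutations(n)
    # |rho| is monotone in |sum of rank products - its permutation mean|
    obs <- sum(rx * ry)
    sums <- as.vector(matrix(ry[perms], nrow(perms), n) %*% rx)
    mu <- mean(sums)
    p <- mean(abs(sums - mu) >= abs(obs - mu) - 1e-12)
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  list(scc = rho, p = min(1, p), defined = TRUE)
}

# all permutations of 1..n as an (n! x n) matrix; n <= 9
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Two-sided Wilcoxon signed-rank test
#'
#' Zero differences are dropped; remaining absolute differences are ranked
#' with average ties. For n <= `exact_n_max` the null distribution of the
#' positive-rank sum is built by exact enumeration over all 2^n sign
#' assignments (via convolution over the half-integer rank grid, so ties
#' are handled exactly); above it, the normal approximation with tie
#' correction is used.
#'
#' @param paired_a,paired_b numeric vectors of paired observations
#' @param exact_n_max largest n for exact enumeration (default 25)
#' @return list with `p` (two-sided), `statistic` (positive-rank sum `V`),
#'   `n_used`, `all_zero`
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b, exact_n_max = 25L) {
  stopifnot(length(paired_a) == length(paired_b))
  d <- paired_a - paired_b
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0L) return(list(p = 1, statistic = NA_real_, n_used = 0L,
                           all_zero = TRUE))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_n_max) {
    # distribution of V over 2^n sign vectors by convolution; ranks are
    # multiples of 1/2, so work on a doubled integer grid
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    dist <- numeric(tot + 1L) # index k+1 = P(2V = k) * 2^n
    dist[1L] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), dist[seq_len(tot + 1L - rk)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    v2 <- round(2 * v)
    mu2 <- tot / 2
    dev <- abs(v2 - mu2)
    p <- sum(dist[abs(seq(0, tot) - mu2) >= dev - 1e-9])
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (v - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(p = min(1, p), statistic = v, n_used = n, all_zero = FALSE)
}

#' Intra-individual stability of repeated samples
#'
#' For subjects sampled at two time points, computes the per-subject
#' Spearman correlation between the two normalized expression profiles and,
#' for a designated miRNA subset, a per-miRNA paired Wilcoxon test across
#' subjects.
#'
#' @param matrix_t1,matrix_t2 normalized count matrices sharing row names;
#'   columns are subject ids (at least one shared)
#' @param mirna_subset miRNA names for the per-miRNA Wilcoxon panel
#' @return list with `per_subject` (data.frame: `subject_id`, `scc`,
#'   `scc_p`) and `per_mirna` (data.frame: `mirna`, `wilcoxon_p`)
#' @export
stability_report <- function(matrix_t1, matrix_t2, mirna_subset = NULL) {
  shared <- intersect(colnames(matrix_t1), colnames(matrix_t2))
  if (!length(shared)) stop("no shared subjects between time points")
  per_subject <- do.call(rbind, lapply(shared, function(id) {
    r <- spearman_scc(matrix_t1[, id], matrix_t2[, id])
    data.frame(subject_id = id, scc = r$scc, scc_p = r$p)
  }))
  per_mirna <- NULL
  if (!is.null(mirna_subset) && length(mirna_subset)) {
    per_mirna <- do.call(rbind, lapply(mirna_subset, function(m) {
      w <- wilcoxon_signed_rank(matrix_t1[m, shared], matrix_t2[m, shared])
      data.frame(mirna = m, wilcoxon_p = w$p)
    }))
  }
  list(per_subject = per_subject, per_mirna = per_mirna)
}
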