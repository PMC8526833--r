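#' Method-of-moments negative-binomial dispersion estimates
#'
#' For each feature, normalized counts are grouped into design cells (the
#' distinct rows of the design covariates); within each cell the moment
#' identity Var(y/s) = q/s + alpha q^2 gives a per-cell estimate, and cells
#' are pooled with weights n_c - 1. Estimates are floored at 1e-8 and
#' capped at 10. When every cell has fewer than 2 samples the estimator
#' falls back to a single pooled cell with a warning.
#'
#' With `shrink = TRUE` (the default when enough features are present) the
#' per-feature estimates are moderated toward a parametric mean-dispersion
#' trend, `log alpha ~ 1/mean`, fitted across all features: a log-scale
#' weighted average with weight `trend_weight` on the trend. Per-feature
#' moment estimates from a few dozen samples are noisy, and that noise
#' makes downstream Wald tails liberal; borrowing strength across features
#' is the standard remedy in NB differential expression.
#'
#' @param counts integer matrix, features x samples (a vector is treated as
#'   one feature)
#' @param cells factor of design-cell membership per sample
#' @param s per-sample size factors
#' @param floor,cap bounds on the estimate
#' @param shrink moderate estimates toward the fitted mean-dispersion trend
#'   (applied only when 50+ features are available to fit it)
#' @param trend_weight weight of the trend in the log-scale average
#' @return numeric vector of dispersion estimates, one per feature
#' @export
estimate_dispersion <- function(counts, cells, s,
                                floor = 1e-8, cap = 10,
                                shrink = TRUE, trend_weight = 0.75) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  cells <- as.factor(cells)
  n_c <- table(cells)
  if (all(n_c < 2)) {
    warning("all design cells have < 2 samples; pooling all samples")
    cells <- factor(rep("all", ncol(counts)))
    n_c <- table(cells)
  }
  z <- sweep(counts, 2, s, "/")
  G <- vapply(levels(cells), function(l) as.numeric(cells == l),
              numeric(length(cells)))
  n <- as.vector(n_c[levels(cells)])
  S1 <- z %*% G
  S2 <- z^2 %*% G
  m <- sweep(S1, 2, n, "/")
  v <- sweep(S2 - sweep(m^2, 2, n, "*"), 2, pmax(n - 1, 1), "/")
  inv_s_mean <- as.vector((matrix(1 / s, 1) %*% G) / n)
  a_cell <- (v - sweep(m, 2, inv_s_mean, "*")) / m^2
  w <- matrix(pmax(n - 1, 0), nrow(a_cell), ncol(a_cell), byrow = TRUE)
  w[!is.finite(a_cell) | m <= 0 | w == 0] <- 0
  a_cell[w == 0] <- 0
  alpha <- rowSums(a_cell * w) / pmax(rowSums(w), 1)
  alpha[rowSums(w) == 0] <- floor
  alpha <- pmin(pmax(alpha, floor), cap)
  if (shrink && nrow(counts) >= 50) {
    mu_row <- rowMeans(z)
    ok <- mu_row > 0.5 & alpha > 1e-6
    if (sum(ok) >= 25) {
      trend_fit <- stats::lm(log(alpha[ok]) ~ I(1 / mu_row[ok]))
      trend <- exp(pmin(pmax(
        cbind(1, 1 / pmax(mu_row, 1e-8)) %*% stats::coef(trend_fit),
        log(floor)), log(cap)))
      alpha <- exp((1 - trend_weight) * log(pmax(alpha, 1e-6)) +
                     trend_weight * log(trend))
      alpha <- pmin(pmax(as.vector(alpha), floor), cap)
    }
  }
  alpha
}

#' Negative-binomial Wald fit for one feature
#'
#' Fits a log-link NB regression with offset `log(s)` at fixed dispersion by
#' iteratively reweighted least squares and reports the Wald statistic for
#' one coefficient. Non-convergence within `max_iter` iterations yields a
#' flagged record with missing p; a separated contrast (one group all zero)
#' converges to a large coefficient and is flagged.
#'
#' @param y integer counts for one feature
#' @param X design matrix (first column the intercept)
#' @param s size factors
#' @param alpha fixed NB dispersion (0 gives the Poisson limit)
#' @param coef_index which coefficient to test
#' @param max_iter IRLS iteration cap (default 100)
#' @return list: `log2fc`, `se`, `wald`, `p`, `converged`, `flag`
#'   (`NA`, `"non_convergence"` or `"separated"`)
#' @export
nb_wald <- function(y, X, s, alpha, coef_index, max_iter = 100L) {
  off <- log(s)
  b <- qr.coef(qr(X), log(pmax(y, 0.5)) - off)
  b[is.na(b)] <- 0
  converged <- FALSE
  XtWX <- NULL
  for (iter in seq_len(max_iter)) {
    eta_lin <- drop(X %*% b)
    eta <- pmin(pmax(eta_lin + off, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- eta_lin + (y - mu) / mu
    WX <- X * w
    XtWX <- crossprod(X, WX)
    b_new <- tryCatch(solve(XtWX, crossprod(WX, z)),
                      error = function(e) NULL)
    if (is.null(b_new)) {
      return(list(log2fc = NA_real_, se = NA_real_, wald = NA_real_,
                  p = NA_real_, converged = FALSE, flag = "non_convergence"))
    }
    delta <- max(abs(b_new - b))
    b <- drop(b_new)
    if (delta < 1e-8) { converged <- TRUE; break }
  }
  cov <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(cov)) {
    return(list(log2fc = NA_real_, se = NA_real_, wald = NA_real_,
                p = NA_real_, converged = FALSE, flag = "non_convergence"))
  }
  beta <- unname(b[coef_index])
  se_ln <- unname(sqrt(diag(cov))[coef_index])
  log2fc <- beta / log(2)
  se <- se_ln / log(2)
  wald <- log2fc / se
  flag <- NA_character_
  p <- 2 * stats::pnorm(-abs(wald))
  if (abs(beta) > 10) {
    # a separated contrast walks to a huge coefficient and cannot converge
    flag <- "separated"
  } else if (!converged) {
    flag <- "non_convergence"; p <- NA_real_
  }
  list(log2fc = log2fc, se = se, wald = wald, p = p,
       converged = converged, flag = flag)
}

#' Benjamini-Hochberg adjustment with missing handling
#'
#' Step-up BH with enforced monotonicity, capped at 1. Missing p-values are
#' excluded from the adjustment and reinserted as missing.
#'
#' @param p numeric vector of p-values in `[0, 1]` (or `NA`)
#' @return vector of adjusted p-values, same length and order
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Covariate-adjusted differential expression for one contrast
#'
#' The full DE path: subjects with missing values in any used covariate are
#' dropped from this contrast only; median-of-ratios size factors (computed
#' once on the full matrix) provide offsets; per-feature NB dispersions come
#' from [estimate_dispersion()]; each feature is fit by [nb_wald()] with the
#' contrast coded test-vs-reference and adjustment covariates (and optional
#' library-pool batch) as fixed-effect columns; p-values are BH-adjusted
#' within the contrast.
#'
#' @param counts integer matrix, miRNAs x samples (columns = subject ids)
#' @param cohort categorized cohort data.frame with `subject_id`
#' @param contrast character vector `c(variable, test_level, reference_level)`
#' @param adjust adjustment covariate names (default `c("age", "sex")`;
#'   use `"age"` alone inside sex strata)
#' @param batch optional batch column name (library pool)
#' @param s optional precomputed size factors for all columns of `counts`
#' @param alpha optional fixed dispersion (scalar or per-feature); estimated
#'   when `NULL`
#' @return data.frame (`mirna`, `log2fc`, `se`, `wald`, `p`, `q`,
#'   `median_ref`, `median_test`, `alpha_hat`, `flag`, `is_de`,
#'   `direction`), one row per feature, with attribute `n_used`
#' @export
de_analysis <- function(counts, cohort, contrast, adjust = c("age", "sex"),
                        batch = NULL, s = NULL, alpha = NULL) {
  stopifnot(length(contrast) == 3)
  variable <- contrast[1]; test <- contrast[2]; ref_lv <- contrast[3]
  if (variable %in% adjust) {
    stop("contrast variable cannot also be an adjustment covariate")
  }
  cols <- c(variable, adjust, batch)
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols)) stop("cohort lacks columns: ",
                                 paste(missing_cols, collapse = ", "))
  idx <- match(colnames(counts), cohort$subject_id)
  if (anyNA(idx)) stop("count columns missing from cohort")
  cov <- cohort[idx, cols, drop = FALSE]
  cov[cov == "missing"] <- NA
  in_contrast <- cov[[variable]] %in% c(ref_lv, test)
  used <- in_contrast & stats::complete.cases(cov)
  if (sum(used) < 4) stop("fewer than 4 usable subjects for contrast")
  y <- counts[, used, drop = FALSE]
  if (is.null(s)) s <- size_factors(counts)
  s_used <- s[used]
  grp <- factor(cov[[variable]][used], levels = c(ref_lv, test))

  X <- matrix(1, ncol(y), 1, dimnames = list(NULL, "(Intercept)"))
  X <- cbind(X, contrastTRUE = as.numeric(grp == test))
  cell_parts <- list(grp)
  for (a in c(adjust, batch)) {
    v <- cov[[a]][used]
    if (is.numeric(v)) {
      X <- cbind(X, scale(v)[, 1])
      colnames(X)[ncol(X)] <- a
    } else {
      f <- factor(v)
      cell_parts[[length(cell_parts) + 1L]] <- f
      if (nlevels(f) > 1) {
        mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0(a, levels(f)[-1])
        X <- cbind(X, mm)
      }
    }
  }
  cells <- interaction(cell_parts, drop = TRUE)
  if (is.null(alpha)) {
    alpha <- estimate_dispersion(y, cells, s_used)
  } else if (length(alpha) == 1L) {
    alpha <- rep(alpha, nrow(y))
  }

  norm <- sweep(y, 2, s_used, "/")
  med_ref <- apply(norm[, grp == ref_lv, drop = FALSE], 1, stats::median)
  med_test <- apply(norm[, grp == test, drop = FALSE], 1, stats::median)

  fits <- lapply(seq_len(nrow(y)), function(i) {
    nb_wald(y[i, ], X, s_used, alpha[i], coef_index = 2L)
  })
  res <- data.frame(
    mirna = rownames(y),
    log2fc = vapply(fits, `[[`, numeric(1), "log2fc"),
    se = vapply(fits, `[[`, numeric(1), "se"),
    wald = vapply(fits, `[[`, numeric(1), "wald"),
    p = vapply(fits, `[[`, numeric(1), "p"),
    median_ref = med_ref,
    median_test = med_test,
    alpha_hat = alpha,
    flag = vapply(fits, `[[`, character(1), "flag"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  res$q <- bh_adjust(res$p)
  res <- call_demirnas(res)
  attr(res, "n_used") <- sum(used)
  attr(res, "contrast") <- contrast
  res
}

#' Apply the dual DEmiRNA-calling filter
#'
#' A miRNA is called differentially expressed when its BH-adjusted p-value
#' is below `q_cutoff` and the median normalized expression reaches
#' `min_median` in at least one of the two contrast groups. Direction is
#' up/down in the test level.
#'
#' @param results data.frame with `q`, `median_ref`, `median_test`, `log2fc`
#' @param q_cutoff significance threshold (default 0.05)
#' @param min_median abundance threshold on the group medians (default 10)
#' @return `results` with `is_de` and `direction` columns
#' @export
call_demirnas <- function(results, q_cutoff = 0.05, min_median = 10) {
  results$is_de <- !is.na(results$q) & results$q < q_cutoff &
    pmax(results$median_ref, results$median_test) >= min_median
  results$direction <- ifelse(results$is_de,
                              ifelse(results$log2fc > 0, "up", "down"),
                              NA_character_)
  results
}

#' Spearman correlation of expression with a continuous covariate
#'
#' Restricted to miRNAs whose median normalized expression is at least
#' `min_median`; correlations are BH-adjusted across the retained miRNAs
#' and classified at the +-0.2 SCC boundaries (strict inequalities, so an
#' SCC of exactly 0.2 is `unaltered`). Classification and significance are
#' independent axes.
#'
#' @param normalized normalized count matrix, miRNAs x samples
#' @param covariate_values numeric vector aligned with columns; missing
#'   values are dropped pairwise
#' @param min_median abundance filter (default 10 normalized reads)
#' @param min_pairs minimum complete pairs to test a miRNA (default 4)
#' @return data.frame (`mirna`, `scc`, `p`, `q`, `category`, `flag`)
#' @export
continuous_scc <- function(normalized, covariate_values, min_median = 10,
                           min_pairs = 4L) {
  med <- apply(normalized, 1, stats::median)
  keep <- which(med >= min_median)
  rows <- lapply(keep, function(i) {
    ok <- !is.na(covariate_values) & !is.na(normalized[i, ])
    if (sum(ok) < min_pairs) {
      return(data.frame(mirna = rownames(normalized)[i], scc = NA_real_,
                        p = NA_real_, flag = "too_few_pairs"))
    }
    r <- spearman_scc(normalized[i, ok], covariate_values[ok])
    data.frame(mirna = rownames(normalized)[i], scc = r$scc, p = r$p,
               flag = if (r$defined) NA_character_ else "undefined")
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$category <- scc_category(out$scc)
  rownames(out) <- NULL
  out[, c("mirna", "scc", "p", "q", "category", "flag")]
}

#' Classify a Spearman coefficient at the +-0.2 boundaries
#'
#' Strict inequalities: an SCC of exactly 0.2 (or -0.2) is `unaltered`.
#' Classification is independent of statistical significance.
#'
#' @param scc numeric vector of Spearman coefficients
#' @return character vector (`increasing`/`unaltered`/`decreasing`)
#' @export
scc_category <- function(scc) {
  ifelse(is.na(scc), NA_character_,
         ifelse(scc > 0.2, "increasing",
                ifelse(scc < -0.2, "decreasing", "unaltered")))
}

#' Z-scored expression matrix and dendrograms for heatmap display
#'
#' Rows are z-scores of log10(normalized count + 1); rows and columns are
#' clustered agglomeratively on Euclidean distance (complete linkage by
#' default). Zero-variance rows become all-zero z-rows and are flagged.
#'
#' @param normalized normalized count matrix
#' @param mirnas non-empty subset of row names to display
#' @param linkage agglomeration method for [stats::hclust()]
#' @return list: `z` (matrix), `row_hclust`, `col_hclust`,
#'   `zero_variance` (character vector of flagged rows)
#' @export
heatmap_matrix <- function(normalized, mirnas, linkage = "complete") {
  stopifnot(length(mirnas) >= 1)
  x <- log10(normalized[mirnas, , drop = FALSE] + 1)
  mu <- rowMeans(x)
  sd_ <- apply(x, 1, stats::sd)
  zero_var <- sd_ == 0
  z <- (x - mu) / ifelse(zero_var, 1, sd_)
  z[zero_var, ] <- 0
  row_h <- if (nrow(z) >= 2)
    stats::hclust(stats::dist(z), method = linkage) else NULL
  col_h <- if (ncol(z) >= 2)
    stats::hclust(stats::dist(t(z)), method = linkage) else NULL
  list(z = z, row_hclust = row_h, col_hclust = col_h,
       zero_variance = rownames(z)[zero_var])
}
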