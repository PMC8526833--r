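#' Aggregate differential-expression statistics onto target genes
#'
#' Each gene's score sums, over the miRNAs that target it, the signed
#' quantity `-sign(log2fc) * (-log10 q)`: the negation encodes repression
#' (an up-regulated miRNA predicts a down-regulated target). Adjusted
#' p-values are floored at 1e-300. By default only called DEmiRNAs
#' contribute; `only_de = FALSE` uses every tested miRNA, and
#' `p_kind = "raw"` substitutes raw p-values, as sensitivity switches.
#'
#' @param de_results data.frame from [de_analysis()] (needs `mirna`,
#'   `log2fc`, `q`, `p`, `is_de`)
#' @param target_map data.frame with `mirna`, `gene`
#' @param only_de restrict to `is_de` miRNAs (default `TRUE`)
#' @param p_kind `"adjusted"` (default) or `"raw"`
#' @return data.frame (`gene`, `score`, `n_targeting_mirnas`) covering every
#'   gene in the map (untargeted-by-DE genes score 0), with attribute
#'   `n_unmatched_mirnas`
#' @export
gene_scores <- function(de_results, target_map, only_de = TRUE,
                        p_kind = c("adjusted", "raw")) {
  p_kind <- match.arg(p_kind)
  stopifnot(nrow(target_map) > 0)
  de <- de_results
  if (only_de) de <- de[which(de$is_de), , drop = FALSE]
  n_unmatched <- length(setdiff(unique(target_map$mirna), de_results$mirna))
  m <- match(target_map$mirna, de$mirna)
  hit <- !is.na(m)
  pv <- if (p_kind == "adjusted") de$q else de$p
  contrib <- rep(0, nrow(target_map))
  contrib[hit] <- -sign(de$log2fc[m[hit]]) *
    (-log10(pmax(pv[m[hit]], 1e-300)))
  score <- tapply(contrib, target_map$gene, sum)
  ntarg <- tapply(hit, target_map$gene, sum)
  out <- data.frame(gene = names(score), score = as.vector(score),
                    n_targeting_mirnas = as.integer(ntarg[names(score)]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_unmatched_mirnas") <- n_unmatched
  out
}

#' Test one gene set by logistic regression on gene scores
#'
#' Regresses the membership indicator on the standardized gene score; the
#' slope's sign gives the predicted direction of the process (negative =
#' down-regulated), its Wald test the p-value. Perfect separation triggers
#' a ridge-penalized refit (penalty 1e-4) and a flag.
#'
#' @param scores data.frame from [gene_scores()]
#' @param member_genes character vector; must be a non-empty proper subset
#'   of the scored genes
#' @return list: `coefficient`, `p`, `direction` (`"up"`/`"down"`),
#'   `n_members`, `flag`
#' @export
gene_set_test <- function(scores, member_genes) {
  member <- as.numeric(scores$gene %in% member_genes)
  if (sum(member) == 0 || sum(member) == length(member)) {
    stop("member set must be a non-empty proper subset of scored genes")
  }
  x <- scores$score
  x <- if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
  flag <- NA_character_
  fit <- suppressWarnings(
    stats::glm(member ~ x, family = stats::binomial()))
  b <- stats::coef(fit)[2]
  se <- summary(fit)$coefficients[2, 2]
  separated <- !fit$converged || abs(b) > 15 || se > 100
  if (separated) {
    flag <- "separated_ridge"
    rf <- .ridge_logistic(cbind(1, x), member, lambda = 1e-4)
    b <- rf$b[2]
    se <- rf$se[2]
  }
  wald <- b / se
  list(coefficient = unname(b), p = 2 * stats::pnorm(-abs(wald)),
       direction = if (b > 0) "up" else "down",
       n_members = sum(member), flag = flag)
}

# Newton-Raphson logistic regression with an L2 penalty on all coefficients
.ridge_logistic <- function(X, y, lambda = 1e-4, max_iter = 100L) {
  b <- numeric(ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X %*% b), -30), 30)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    H <- crossprod(X, X * w) + diag(lambda, ncol(X))
    g <- crossprod(X, y - mu) - lambda * b
    step <- solve(H, g)
    b <- b + drop(step)
    if (max(abs(step)) < 1e-10) break
  }
  list(b = b, se = sqrt(diag(solve(H))))
}

#' Enrich every set in a library
#'
#' Runs [gene_set_test()] per set and adjusts p-values by BH within the
#' library; a set is significant at `q < 0.05`. Degenerate sets (all or no
#' scored genes) are reported with missing statistics rather than erroring
#' the batch.
#'
#' @param scores data.frame from [gene_scores()]
#' @param library a `gene_set_library` (named list of gene vectors)
#' @return data.frame (`set_name`, `coefficient`, `p`, `q`, `direction`,
#'   `n_members`, `flag`), one row per set
#' @export
enrich_all <- function(scores, library) {
  rows <- lapply(names(library), function(nm) {
    r <- tryCatch(gene_set_test(scores, library[[nm]]),
                  error = function(e) list(coefficient = NA_real_,
                                           p = NA_real_,
                                           direction = NA_character_,
                                           n_members = sum(scores$gene %in%
                                                             library[[nm]]),
                                           flag = "degenerate"))
    data.frame(set_name = nm, coefficient = r$coefficient, p = r$p,
               direction = r$direction, n_members = r$n_members,
               flag = r$flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out[, c("set_name", "coefficient", "p", "q", "direction",
          "n_members", "flag")]
}
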