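# hand-built two-precursor reference: mirA annotated (arms [0,22) / [48,70)
# on an 80 nt hairpin), mirB unannotated (80 nt, position-based path)
toy_reference <- function() {
  mkseq <- function(n) paste(rep(c("A", "C", "G", "T"), length.out = n),
                             collapse = "")
  prec <- data.frame(
    precursor_id = c("mirA", "mirB"),
    sequence = c(mkseq(80), mkseq(80)),
    chromosome = c("chr1", "chrY"),
    length = c(80L, 80L),
    stringsAsFactors = FALSE
  )
  arms <- data.frame(
    precursor_id = c("mirA", "mirB"),
    arm5p_start = c(0L, NA), arm5p_end = c(22L, NA),
    arm3p_start = c(48L, NA), arm3p_end = c(70L, NA)
  )
  structure(list(precursors = prec, arms = arms), class = "mirna_reference")
}

toy_alignment <- function(precursor_id, start, end) {
  data.frame(read_id = "r", precursor_id = precursor_id,
             start = start, end = end, is_primary = TRUE,
             stringsAsFactors = FALSE)
}

write_toy_sam <- function(body_lines, path, ref = toy_reference()) {
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", ref$precursors$precursor_id,
                       ref$precursors$length),
               body_lines), path)
  path
}

# brute-force Wilcoxon signed-rank two-sided p over all 2^n sign vectors
brute_wilcoxon_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  mu <- sum(r) / 2
  mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-9)
}

# definitional BH step-up
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# average-rank Spearman coefficient, written independently of the package
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
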