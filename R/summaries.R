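#' Percentage of a count over a total
#' @param count,total non-negative numbers, `total > 0`
#' @return `100 * count / total`
#' @export
pct <- function(count, total) {
  stopifnot(total > 0, count >= 0)
  100 * count / total
}

#' Pooled mean from per-group means and sizes
#' @param means per-group means
#' @param ns per-group sizes
#' @return size-weighted overall mean
#' @export
pooled_mean <- function(means, ns) {
  stopifnot(length(means) == length(ns), all(ns > 0))
  sum(means * ns) / sum(ns)
}

#' Printed study-population summary counts
#'
#' The published per-category subject counts, group age means and
#' reference/detection totals of the 335-subject stool miRNome cohort,
#' shipped as plain data so summarization utilities can recompute the
#' derived percentages and pooled means from them.
#'
#' @return named list of numbers
#' @export
study_population_counts <- function() {
  path <- system.file("extdata", "study_population_counts.tsv",
                      package = "faecomir")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.list(tab$value), tab$metric)
}
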