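#!/usr/bin/env Rscript
# Stage 5: covariate-adjusted differential expression.
#
# NB Wald regression per miRNA for every configured contrast (full model
# adjusted for age + sex and library pool; the contrast variable itself is
# never an adjustment), BH correction within contrast, and the dual
# DEmiRNA filter (q < 0.05 and group median >= 10 normalized reads). Also
# the Spearman profile of expression against age and BMI as continuous
# covariates, and recall of the planted truth.

suppressPackageStartupMessages(library(faecomir))

cache <- "scratch/analysis"
counts <- read_count_matrix(file.path(cache, "counts_quantified.tsv"))
cohort <- read.delim(file.path(cache, "cohort_categorized.tsv"),
                     stringsAsFactors = FALSE)
truth <- read.delim("results/analysis/01_truth_ledger.tsv",
                    stringsAsFactors = FALSE)
cfg <- default_config(42L)

s <- size_factors(counts)
rows <- list(); all_calls <- list()
for (ct in cfg$contrasts) {
  lv <- cohort[[ct[1]]]
  if (sum(lv == ct[2], na.rm = TRUE) < 2 ||
      sum(lv == ct[3], na.rm = TRUE) < 2) next
  de <- de_analysis(counts, cohort, ct,
                    adjust = setdiff(cfg$diffexp$adjust, ct[1]),
                    batch = cfg$diffexp$batch, s = s)
  key <- paste(ct, collapse = "_")
  calls <- de[de$is_de, c("mirna", "log2fc", "se", "wald", "p", "q",
                          "median_ref", "median_test", "direction")]
  if (nrow(calls)) all_calls[[key]] <- cbind(contrast = key, calls)
  rows[[key]] <- data.frame(
    contrast = key, n_subjects = attr(de, "n_used"),
    n_tested = sum(!is.na(de$p)), n_demirnas = sum(de$is_de),
    n_up = sum(de$direction == "up", na.rm = TRUE),
    n_down = sum(de$direction == "down", na.rm = TRUE))
  message(sprintf("%-35s n=%3d  DEmiRNAs %2d (%d up / %d down)",
                  key, rows[[key]]$n_subjects, rows[[key]]$n_demirnas,
                  rows[[key]]$n_up, rows[[key]]$n_down))
}
summary <- do.call(rbind, rows)
write.table(summary, "results/analysis/05_de_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
calls <- do.call(rbind, all_calls)
write.table(calls, "results/analysis/05_demirna_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

recalled <- vapply(seq_len(nrow(truth)), function(i) {
  key <- paste(truth$variable[i], truth$test_level[i],
               truth$reference_level[i], sep = "_")
  any(calls$contrast == key & calls$mirna == truth$mirna[i])
}, logical(1))
message(sprintf("planted-effect recall: %d/%d; %d DEmiRNA calls in total",
                sum(recalled), length(recalled), nrow(calls)))

# continuous profiles: age and BMI vs normalized expression
norm <- normalize_counts(counts, s)
for (v in c("age", "bmi")) {
  cc <- continuous_scc(norm, cohort[[v]][match(colnames(norm),
                                               cohort$subject_id)])
  tab <- table(cc$category)
  message(v, " SCC categories: ",
          paste(names(tab), as.integer(tab), collapse = ", "),
          "; significant (q<0.05): ", sum(cc$q < 0.05, na.rm = TRUE))
  write.table(cc[order(cc$q), ][1:20, ],
              sprintf("results/analysis/05_scc_%s_top20.tsv", v),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

# z-score heatmap input for miRNAs called in 2+ contrasts
multi <- names(which(table(calls$mirna) >= 2))
if (length(multi) >= 2) {
  hm <- heatmap_matrix(norm, multi)
  ord <- hm$row_hclust$order
  message("heatmap over ", length(multi),
          " multi-contrast DEmiRNAs; leaf order: ",
          paste(rownames(hm$z)[ord], collapse = ", "))
}
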