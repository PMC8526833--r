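#!/usr/bin/env Rscript
# Stage 4: normalization, detection and variability.
#
# Median-of-ratios size factors, detection prevalence (overall, per sample,
# per chromosome), the MAD/median robust CV ranking of well-expressed
# miRNAs, and intra-individual stability of the six repeated samples
# (per-subject Spearman correlation between time points; paired Wilcoxon
# for the miRNAs detected in every sample).

suppressPackageStartupMessages(library(faecomir))

cache <- "scratch/analysis"
bundle_dir <- file.path(cache, "bundle")
ref <- read_reference(file.path(bundle_dir, "reference.fa"),
                      file.path(bundle_dir, "arms.tsv"))
counts <- read_count_matrix(file.path(cache, "counts_quantified.tsv"))

s <- size_factors(counts)
norm <- normalize_counts(counts, s)
det <- detection_summary(counts, min_reads = 1, ref = ref)

message(sprintf("detected per sample: median %d (range %d-%d) of %d",
                median(det$per_sample_detected),
                min(det$per_sample_detected), max(det$per_sample_detected),
                nrow(counts)))
message(sprintf("%d miRNAs (%.1f%%) detected in at least half the samples",
                sum(det$prevalence >= 0.5),
                100 * mean(det$prevalence >= 0.5)))
write.table(det$per_chromosome, "results/analysis/04_chromosome_detection.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cv <- cv_ranking(norm, min_median = 1)
write.table(head(cv, 25), "results/analysis/04_cv_ranking_top25.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("CV ranking over %d miRNAs with median >= 1; most stable: %s (CV %.2f)",
                nrow(cv), cv$mirna[1], cv$cv[1]))

repeats <- read_count_matrix(file.path(bundle_dir, "counts_repeat.tsv"))
t1 <- norm[, colnames(repeats)]
t2 <- normalize_counts(repeats)
everywhere <- names(which(detection_summary(counts)$prevalence == 1))
stab <- stability_report(t1, t2, everywhere)
write.table(stab$per_subject, "results/analysis/04_stability_subjects.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(stab$per_mirna, "results/analysis/04_stability_mirnas.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("repeated-sample SCC ranges %.2f-%.2f over %d subjects; %d/%d always-detected miRNAs stable (Wilcoxon p >= 0.05)",
                min(stab$per_subject$scc), max(stab$per_subject$scc),
                nrow(stab$per_subject),
                sum(stab$per_mirna$wilcoxon_p >= 0.05),
                nrow(stab$per_mirna)))
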