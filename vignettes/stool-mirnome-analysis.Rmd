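---
title: "Profiling the stool miRNome against common traits and lifestyle: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling the stool miRNome against common traits and lifestyle: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(faecomir)
```

Faecal microRNAs are stable, easily collected, and increasingly studied as
non-invasive biomarkers, but their expression also tracks who the donor is:
age, sex, body mass index, smoking, alcohol, coffee, and physical activity
all leave signatures in stool small RNA-seq profiles. `faecomir` implements
the full analysis chain such a study needs — mature miRNA quantification
from precursor alignments, questionnaire categorization, variability
statistics, covariate-adjusted negative-binomial differential expression,
and miRNA-target gene-set enrichment — together with a synthetic-data
module that plants known effects so every stage can be validated end to
end. This vignette explains the models, the tunable parameters, and the
design decisions; the package tests and `scripts/acceptance.R` compute
every empirical claim the package makes.

## Mature miRNA quantification

Reads are aligned upstream (e.g. with BWA) against precursor hairpins, not
a genome; this package consumes those alignments. All in-memory intervals
are 0-based half-open, converted once from SAM's 1-based coordinates at
ingestion (`read_alignments()`), and only primary mapped alignments are
kept — an aligner run with default settings reports one best hit per read.

Two assignment rules map a read to a mature arm (`assign_read()`):

* **Knowledge-based** — when the precursor's 5p/3p arm intervals are
  annotated, the read goes to the arm with the larger base-pair overlap.
  Zero overlap with both arms leaves the read unassigned (`no_overlap`);
  an exact positive tie is `ambiguous`.
* **Position-based** — without arm annotation, the read midpoint is
  compared with the precursor midpoint: strictly left is `-5p`, strictly
  right `-3p`, exactly equal `ambiguous`.

Ambiguous and non-overlapping reads are dropped rather than fractionally
counted: conservation (assigned + unassigned = input) is then exact and
auditable, and the per-sample log reports every category so the dropped
fraction is visible. The midpoint split and maximal-overlap rule are the
symmetric, parameter-free readings of the two methods; on precursors whose
annotated arms exactly tile the two halves they agree for every read not
crossing the midpoint (a property test enforces this).

The count matrix always spans the full mature name space — two rows per
precursor, detected or not — so matrices from different batches align by
construction.

Adapter trimming (`trim_adapter()`) finds the best semi-global occurrence
of the 3' adapter (or an adapter prefix at the read end) by an exhaustive
cut-point edit-distance scan, allowing mismatches, insertions and deletions
up to `floor(0.15 x matched length)` errors by default. Among feasible
occurrences the one with the most matching bases wins (matched length
minus errors), ties to fewer errors, then leftmost — ranking by raw error
rate instead would let a trailing exact 2-mer beat a genuine degenerate
adapter hit. Trimmed inserts shorter than 14 nt are flagged for discard.
The scan is O(read x adapter x read); at 50 nt small-RNA scale fidelity is
worth more than speed.

## Cohort categorization

`categorize_cohort()` derives every analysis stratum deterministically and
idempotently:

* **BMI** (WHO): underweight < 18.5, normal [18.5, 25), overweight
  [25, 30), obese >= 30 kg/m^2. The boundary 30.0 is obese.
* **Age tertiles**: interior 1/3 and 2/3 empirical quantiles (type 7,
  linear interpolation); a subject exactly on a breakpoint falls in the
  lower class. The tie rule is explicit because published tertile labels
  often overlap at the boundaries (e.g. "18-37" followed by "37-53").
* **Smoking**: never/former pass through; current smokers split at 16
  cigarettes/day, heavy inclusive.
* **Alcohol** (sex-specific): 0 g/day non-drinker; low up to and including
  24 g/day for men and 12 g/day for women; high strictly above.
* **Coffee**: 0 g/day non-drinker; drinkers split at a configurable cutoff
  defaulting to 8 g/day (cohort-median conventions vary — 8 and 16 g/day
  both appear in the literature — so the cutoff is a parameter, not a
  constant).
* **Physical activity index**: recreational + household MET-hours/week
  (equal weight) are quartiled within sex and cross-classified with the
  occupational class through a lookup table. The EPIC-style
  cross-classification is not standardized in print, so the shipped
  default (`default_pai_table()`) follows the Cambridge-index convention —
  sedentary occupation with the lowest quartile is inactive, heavy manual
  work is active regardless — and the whole table is replaceable data.

Missing raw values propagate to a `"missing"` category; differential
expression later drops such subjects from affected contrasts only.

## Normalization, detection, and variability

Size factors use the median-of-ratios rule: for sample *j*,
`s_j = median_i counts[i,j] / geomean_i`, over features positive in every
sample, rescaled to geometric mean 1. "Normalized reads" are
`counts[i,j] / s_j` throughout the pipeline — the same convention the DE
stage assumes, so a single normalization serves all stages. When no
feature is positive everywhere the geometric means fall back to each
feature's positive subset, with a warning.

Inter-individual variability uses a robust coefficient of variation:
`cv = mad(x) / median(x)` with the MAD **unscaled** (no 1.4826
consistency constant) — the ratio itself is the statistic, not a normal
s.d. estimate. Only miRNAs with median normalized expression >= 1 are
ranked, ties broken by name. The estimator pairs a median absolute
deviation with the median; a mean-absolute-deviation variant is available
via `mad_kind = "mean"` because the two names are often conflated in
methods prose.

Intra-individual stability across repeated collections uses per-subject
Spearman correlation between time points plus a per-miRNA paired Wilcoxon
test. Both primitives are implemented with exactly specified small-sample
behaviour:

* `spearman_scc()`: average ranks for ties, Pearson on the ranks; exact
  permutation p for n <= 9 (all n! permutations), t approximation above.
* `wilcoxon_signed_rank()`: zero differences dropped; exact null over all
  2^n sign assignments for n <= 25 — computed by convolution on the
  half-integer rank grid so ties are exact — and the tie-corrected normal
  approximation above. Brute-force enumeration oracles pin both down in
  the tests.

## Differential expression

Each miRNA is modelled as NB(mu_ij, alpha_i) with
`log mu_ij = log s_j + x_j' beta`, fit by iteratively reweighted least
squares at fixed dispersion (100-iteration cap, linear predictor clamped
to +-30). The design holds the contrast indicator (test vs reference
level), adjustment covariates (age and sex in the full model; age only
within sex strata), and the library pool as fixed-effect batch columns.
The reported statistic is the Wald `W = log2FC / SE` with a two-sided
normal p-value; a likelihood-ratio alternative is deliberately out of
scope. A fit whose contrast coefficient exceeds 10 on the natural-log
scale is flagged `separated` (one group essentially all zero);
non-convergence yields a missing p, never a silent number.

Dispersions come from a method-of-moments estimator within design cells
(the distinct covariate combinations): on normalized counts,
`Var(y/s) = q/s + alpha q^2` gives a per-cell estimate, pooled with
weights n_c - 1, floored at 1e-8 and capped at 10. Per-feature moment
estimates from a few dozen samples are noisy, and that noise makes the
far Wald tails liberal — inflating the false discovery rate among called
miRNAs — so by default the estimates are moderated toward a parametric
trend `log alpha ~ 1/mean` fitted across features (log-scale weighted
average, weight 0.75 on the trend, applied when at least 50 features are
available). Borrowing dispersion strength across features is the standard
remedy in NB differential expression; the full empirical-Bayes machinery
of dedicated DE packages (outlier refitting, independent filtering) is
intentionally not reproduced, and agreement with such packages is claimed
only at the level of operating characteristics: the test suite checks
null type-I error in [0.035, 0.065] at 2,000 features x 100 subjects, and
sensitivity >= 0.8 with FDR <= 0.1 for planted |log2FC| = 2 effects at
dispersion 0.3 and ~100 subjects per group, against the generator's truth
ledger.

A **DEmiRNA** requires both `BH-adjusted p < 0.05` and a median normalized
expression of at least 10 reads in at least one of the two contrast
groups; the two filters are independent axes and the abundance medians are
computed on the contrast groups only. BH adjustment is per contrast, since
DE lists are reported per comparison. Continuous covariates (age, BMI) are
profiled separately: Spearman correlation per miRNA with median >= 10
reads, BH across miRNAs, and a three-way classification at the +-0.2
boundaries (strict inequalities, so SCC = 0.2 exactly is "unaltered");
classification and significance are independent, so a significant
correlation need not cross a category boundary.

For display, `heatmap_matrix()` z-scores `log10(normalized + 1)` per
miRNA and clusters rows and columns agglomeratively (Euclidean, complete
linkage by default); zero-variance rows become zero rows and are flagged
rather than producing NaNs.

## Target gene-set enrichment

Differential-expression results are mapped onto validated target genes:
gene *g* scores `S_g = sum over DE miRNAs m targeting g of -sign(log2FC_m)
x (-log10 q_m)`, with q floored at 1e-300. The negation encodes
repression — an up-regulated miRNA predicts a down-regulated target — so
negating every fold change negates every score (an invariant test). The
exact aggregation used by published miRNA gene-set tools is not restated
in print; this signed form is isolated in `gene_scores()` so alternative
aggregations are pluggable, and switches select raw vs adjusted p and
all-miRNA vs DE-only input (DE-only is the default, matching the practice
of enriching called DEmiRNA sets).

Each gene set is then tested by logistic regression of the membership
indicator on the standardized score; the slope's sign gives the predicted
direction of the process (negative = down-regulated), its Wald test the
p-value, BH-corrected within the library. Scores are standardized so
coefficients are comparable across contrasts. Perfect separation — e.g.
when every nonzero-score gene lies inside the set — triggers a
ridge-penalized refit (penalty 1e-4) and a flag; such records are honest
but weakly powered, which is why sparse DE-only scores on tiny toy maps
can fail to reach significance even when visibly concentrated. The test
suite checks calibration (permutation-null p uniform by KS at alpha 0.01)
and planted-set recovery at q < 0.05.

## The synthetic-data generator

Because raw data for such cohorts are typically available only on
request, the generator is a first-class, tested module rather than a
fixture. It emulates:

* **Reference**: precursors of 60-120 nt; a configurable fraction carries
  5p/3p arms of 18-25 nt (knowledge-based path), the rest none
  (position-based path); chromosomes round-robin.
* **Cohort**: category frequencies matching a 335-subject healthy-donor
  profile (63.6% female; age truncated normal, mean 44.7, sd 14.7, range
  18-81; BMI classes 7.5/64/20/5.4%; 54% never smokers; 24-plex library
  pools; menopause age-linked and female-only). A binomial-CI test checks
  the drawn marginals. The physical-activity marginal is *not* matched:
  with within-sex quartiles every quartile holds 25% by construction, so
  no cross-classification table can reproduce an arbitrary printed PAI
  marginal; the PAI column instead exercises the categorizer.
* **Counts**: `y_ij ~ NB(s_j mu_i 2^(x_j' log2fc_i), alpha)` with
  log-normal baseline abundances (long-tailed detection profiles),
  log-normal per-sample assigned-read totals around `library_size_mean x
  mirna_fraction` (defaults 10.3e6 and 0.92%, the throughput scale of
  deep stool sRNA-seq), a shared library-pool factor (sd 0.1) for the
  batch covariate to absorb, and dispersion 0.3 — a typical
  between-subject value for stool counts. Planted effects are declared as
  `effect_spec()` objects and echoed in a truth ledger so recovery tests
  never re-derive them.
* **Alignments**: the exact inverse of quantification — each count unit
  becomes one interval inside its arm (or strictly inside its precursor
  half), so `quantify_sample(simulate_alignments(c)) == c` exactly; this
  inverse identity is the module's core oracle and runs on 1,000
  randomized vectors in the acceptance suite.
* **Repeated samples**: counts re-drawn from each subject's latent means
  under cellwise log-normal drift (`drift_sd`, default 0.2), emulating a
  second collection a year later for six subjects.

Every generator takes an explicit seed and owns its RNG stream; identical
seeds give byte-identical outputs.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: sequence-level artefacts (adapter chimeras,
quality decay), multi-mapping across paralogous precursors, microbiome
co-variation, compositional effects of a few dominant miRNAs, or
covariate-dependent library quality. Results on real cohorts additionally
depend on the external miRNA reference, target database and gene-set
library versions, which the package treats as replaceable inputs.

## Numerical choices and problem sizes

* IRLS convergence at max |delta beta| < 1e-8; eta clamped to +-30;
  singular weighted Hessians yield flagged missing records.
* Dispersion floor 1e-8 and cap 10; trend moderation weight 0.75.
* Exact branches: Wilcoxon n <= 25 (convolution), Spearman n <= 9
  (permutation); both cross-checked against the asymptotic branch.
* Ties: tertile/quartile boundaries to the lower class; CV ranking ties
  by name; hierarchical clustering is deterministic given the matrix.
* Deterministic workflows: the demo bundle (200 precursors, 60 subjects,
  ~7e5 assigned reads) runs end to end in well under a minute and twice
  with the same seed gives byte-identical TSVs. The heavier operating
  characteristic checks use 2,000 features x 100 subjects (null) and
  1,000 features x 200 subjects (planted recovery); these sizes keep the
  whole suite around two minutes while leaving the binomial noise on the
  measured rates well inside the asserted bands.

## Known limitations

* The NB Wald with plug-in moderated dispersion remains very slightly
  liberal (~0.055 observed type-I at nominal 0.05, n = 100); the
  abundance filter and BH step keep called-list FDR at ~0.05 in the
  tested regimes.
* `estimate_dispersion()` assumes the design cells capture the mean
  structure; a continuous covariate with a strong real effect would
  inflate dispersion estimates (conservative direction).
* The enrichment stage models set membership, not gene-gene correlation;
  p-values are calibrated under gene-level exchangeability only.
* Arm annotation is a bespoke 5-column TSV; a GFF3 importer is a natural
  extension point.
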