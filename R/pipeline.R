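#' Default pipeline configuration
#'
#' Returns the full configuration list consumed by [run_pipeline()] and
#' [simulate_bundle()]; any YAML file with the same structure can override
#' it. Contrasts default to the study's full set: sex, age tertiles
#' (pairwise), menopause, BMI classes vs normal, smoking strata vs never,
#' alcohol and coffee strata vs non-drinkers, and activity strata vs active.
#'
#' @param seed global seed
#' @return nested configuration list
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = seed,
    simulate = list(
      n_precursors = 200L, annotated_fraction = 0.5, n_subjects = 60L,
      library_size_mean = 2e4, mirna_fraction = 0.5, dispersion = 0.3,
      baseline_sdlog = 1.5, n_repeat_subjects = 6L, drift_sd = 0.2
    ),
    cohort = list(coffee_cutoff = 8),
    variability = list(min_reads = 1, cv_min_median = 1,
                       mad_kind = "median"),
    diffexp = list(adjust = c("age", "sex"), batch = "library_pool",
                   q_cutoff = 0.05, min_median = 10),
    contrasts = list(
      c("sex", "male", "female"),
      c("age_tertile", "t2", "t1"), c("age_tertile", "t3", "t1"),
      c("age_tertile", "t3", "t2"),
      c("bmi_class", "underweight", "normal"),
      c("bmi_class", "overweight", "normal"),
      c("bmi_class", "obese", "normal"),
      c("smoking", "former", "never"),
      c("smoking", "light_current", "never"),
      c("smoking", "heavy_current", "never"),
      c("alcohol_class", "low", "non_drinker"),
      c("alcohol_class", "high", "non_drinker"),
      c("coffee_class", "low", "non_drinker"),
      c("coffee_class", "high", "non_drinker"),
      c("pai", "inactive", "active"),
      c("pai", "moderately_inactive", "active"),
      c("pai", "moderately_active", "active")
    ),
    enrichment = list(only_de = TRUE, p_kind = "adjusted")
  )
}

#' Load a pipeline configuration from YAML
#'
#' Missing blocks fall back to [default_config()] values.
#'
#' @param path YAML file path
#' @return configuration list
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  merge2 <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
                        nm != "contrasts")
        merge2(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  merge2(cfg, user)
}

.write_manifest <- function(dir, name, inputs, params, seed) {
  manifest <- list(
    output = name,
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    parameters = params,
    seed = seed,
    tool = paste0("faecomir ",
                  as.character(utils::packageVersion("faecomir")))
  )
  jsonlite::write_json(manifest, file.path(dir, paste0(name, ".manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Write a full synthetic input bundle to disk
#'
#' Generates and writes a reference FASTA + arm table, per-sample SAM
#' alignments realizing a simulated count matrix, the raw questionnaire
#' CSV, the repeated-sample count matrix, and the planted-effect truth
#' ledger — the same formats the ingestion stage reads.
#'
#' @param config configuration list (see [default_config()])
#' @param outdir output directory, created if needed
#' @param effects list of [effect_spec()] planted effects (default: one
#'   smoking, one sex and one coffee effect over the first annotated and
#'   unannotated mature names)
#' @return invisibly, a list of written paths plus the `mir_sim` object
#' @export
simulate_bundle <- function(config = default_config(), outdir,
                            effects = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sc <- config$simulate
  seed <- config$seed
  ref <- simulate_reference(sc$n_precursors, sc$annotated_fraction,
                            seed = seed)
  cohort_raw <- simulate_cohort(sc$n_subjects, seed = seed + 1L)
  cohort <- categorize_cohort(cohort_raw,
                              coffee_cutoff = config$cohort$coffee_cutoff)
  cfg <- sim_config(library_size_mean = sc$library_size_mean,
                    mirna_fraction = sc$mirna_fraction,
                    dispersion = sc$dispersion,
                    baseline_sdlog = sc$baseline_sdlog)
  if (is.null(effects)) {
    # plant on well-expressed mature miRNAs (a null pre-draw ranks the
    # baseline) in contrasts with workable group sizes at demo scale
    sim0 <- simulate_counts(ref, cohort, list(), cfg, seed = seed + 2L)
    med <- apply(normalize_counts(sim0$counts), 1, stats::median)
    top <- names(sort(med, decreasing = TRUE))[1:7]
    effects <- list(
      effect_spec("smoking", c("never", "former"),
                  top[1:3], c(2, -2, 2)),
      effect_spec("sex", c("female", "male"), top[4:5], c(1.5, -1.5)),
      effect_spec("coffee_class", c("non_drinker", "high"),
                  top[6:7], c(-2, 2))
    )
  }
  sim <- simulate_counts(ref, cohort, effects, cfg, seed = seed + 2L)

  paths <- list(
    fasta = file.path(outdir, "reference.fa"),
    arms = file.path(outdir, "arms.tsv"),
    questionnaire = file.path(outdir, "questionnaire.csv"),
    counts = file.path(outdir, "counts.tsv"),
    counts_repeat = file.path(outdir, "counts_repeat.tsv"),
    truth = file.path(outdir, "truth_ledger.tsv"),
    sam_dir = file.path(outdir, "sam")
  )
  write_reference(ref, paths$fasta, paths$arms)
  write_cohort(cohort_raw, paths$questionnaire)
  write_count_matrix(sim$counts, paths$counts)
  rep_counts <- simulate_repeated_samples(sim, sc$n_repeat_subjects,
                                          sc$drift_sd, seed = seed + 3L)
  write_count_matrix(rep_counts, paths$counts_repeat)
  utils::write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  dir.create(paths$sam_dir, showWarnings = FALSE)
  for (j in seq_len(ncol(sim$counts))) {
    aln <- simulate_alignments(sim$counts[, j], ref, seed = seed + 10L + j)
    write_sam(aln, ref, file.path(paths$sam_dir,
                                  paste0(colnames(sim$counts)[j], ".sam")))
  }
  .write_manifest(outdir, "simulate",
                  inputs = character(),
                  params = sc, seed = seed)
  invisible(c(paths, list(sim = sim, ref = ref, cohort = cohort)))
}

#' Run the full analysis pipeline from a configuration
#'
#' Stage order follows the study workflow: quantify (from per-sample SAM
#' files; or ingest a precomputed count matrix), categorize the cohort,
#' variability summaries, differential expression for every configured
#' contrast, and target-gene enrichment when a target map and gene-set
#' library are configured. Every output TSV gets a JSON manifest recording
#' input checksums, parameters and the seed; a failing stage aborts with
#' its name and leaves prior outputs under `failed/`.
#'
#' @param config configuration list; `config$paths` must name the inputs
#'   (`fasta`, `arms`, and `sam_dir` or `counts`; `questionnaire`;
#'   optionally `target_map` and `gmt`)
#' @param outdir output directory
#' @return invisibly, a list with the main in-memory results
#' @export
run_pipeline <- function(config, outdir) {
  p <- config$paths
  needed <- c(p$fasta, p$questionnaire,
              if (is.null(p$counts)) p$sam_dir else p$counts)
  absent <- needed[!file.exists(needed)]
  if (length(absent)) {
    stop("missing input path(s): ", paste(absent, collapse = ", "))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  on.exit({
    if (!identical(stage, "done")) {
      failed <- file.path(outdir, "failed")
      dir.create(failed, showWarnings = FALSE)
      message("pipeline aborted in stage: ", stage)
    }
  })

  stage <- "reference"
  ref <- read_reference(p$fasta, p$arms)

  stage <- "quantify"
  if (!is.null(p$counts)) {
    counts <- read_count_matrix(p$counts)
  } else {
    sams <- sort(list.files(p$sam_dir, pattern = "\\.sam$",
                            full.names = TRUE))
    per_sample <- lapply(sams, function(f) {
      quantify_sample(read_alignments(f, ref), ref)
    })
    names(per_sample) <- sub("\\.sam$", "", basename(sams))
    counts <- build_count_matrix(per_sample, ref)
  }
  write_count_matrix(counts, file.path(outdir, "counts.tsv"))
  .write_manifest(outdir, "counts", unlist(p[c("fasta", "arms")]),
                  list(), config$seed)

  stage <- "cohort"
  cohort <- categorize_cohort(read_cohort(p$questionnaire),
                              coffee_cutoff = config$cohort$coffee_cutoff)
  cohort <- cohort[match(colnames(counts), cohort$subject_id), ]
  if (anyNA(cohort$subject_id)) stop("samples missing from questionnaire")
  utils::write.table(cohort, file.path(outdir, "cohort.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .write_manifest(outdir, "cohort", p$questionnaire,
                  config$cohort, config$seed)

  stage <- "variability"
  s <- size_factors(counts)
  norm <- normalize_counts(counts, s)
  det <- detection_summary(counts, config$variability$min_reads, ref)
  cvr <- cv_ranking(norm, config$variability$cv_min_median,
                    config$variability$mad_kind)
  utils::write.table(cvr, file.path(outdir, "cv_ranking.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(mirna = names(det$prevalence), prevalence = det$prevalence),
    file.path(outdir, "detection_summary.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  .write_manifest(outdir, "variability", file.path(outdir, "counts.tsv"),
                  config$variability, config$seed)

  stage <- "diffexp"
  de <- list()
  for (ct in config$contrasts) {
    lv <- cohort[[ct[1]]]
    if (sum(lv == ct[2], na.rm = TRUE) < 2 ||
        sum(lv == ct[3], na.rm = TRUE) < 2) next
    key <- paste(ct, collapse = "_")
    de[[key]] <- de_analysis(counts, cohort, ct,
                             adjust = setdiff(config$diffexp$adjust, ct[1]),
                             batch = config$diffexp$batch, s = s)
    utils::write.table(de[[key]],
                       file.path(outdir, paste0("de_", key, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  .write_manifest(outdir, "diffexp", file.path(outdir, "counts.tsv"),
                  config$diffexp, config$seed)

  stage <- "enrichment"
  enr <- NULL
  if (!is.null(p$target_map) && !is.null(p$gmt) && length(de)) {
    tm <- read_target_map(p$target_map)
    lib <- read_gmt(p$gmt)
    enr <- list()
    for (key in names(de)) {
      if (!any(de[[key]]$is_de)) next
      sc <- gene_scores(de[[key]], tm,
                        only_de = config$enrichment$only_de,
                        p_kind = config$enrichment$p_kind)
      enr[[key]] <- enrich_all(sc, lib)
      utils::write.table(enr[[key]],
                         file.path(outdir, paste0("enrichment_", key, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    .write_manifest(outdir, "enrichment",
                    c(p$target_map, p$gmt), config$enrichment, config$seed)
  }
  stage <- "done"
  invisible(list(counts = counts, cohort = cohort, size_factors = s,
                 detection = det, cv = cvr, de = de, enrichment = enr))
}
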