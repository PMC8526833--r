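#' Simulate a precursor miRNA reference
#'
#' Precursor lengths are uniform on 60-120 nt. A fraction of precursors
#' carries annotated 5p/3p arm intervals of 18-25 nt (placed at the two
#' hairpin ends, never overlapping) and is quantified by the knowledge-based
#' path; the remainder has no arm annotation and exercises the
#' position-based path. Chromosome labels are assigned round-robin.
#'
#' @param n_precursors number of precursors (>= 1)
#' @param annotated_fraction fraction with arm annotation, in `[0, 1]`
#' @param seed integer seed; identical seeds give identical references
#' @param chromosomes label set for round-robin assignment
#' @return a `mirna_reference`
#' @export
simulate_reference <- function(n_precursors, annotated_fraction = 0.5, seed,
                               chromosomes = c(paste0("chr", 1:22),
                                               "chrX", "chrY")) {
  stopifnot(n_precursors >= 1, annotated_fraction >= 0,
            annotated_fraction <= 1)
  set.seed(seed)
  lens <- sample(60:120, n_precursors, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  ids <- sprintf("prec%04d", seq_len(n_precursors))
  n_ann <- round(annotated_fraction * n_precursors)
  annotated <- seq_len(n_precursors) <= n_ann
  arms <- data.frame(precursor_id = ids,
                     arm5p_start = NA_integer_, arm5p_end = NA_integer_,
                     arm3p_start = NA_integer_, arm3p_end = NA_integer_)
  for (i in which(annotated)) {
    l5 <- sample(18:25, 1); l3 <- sample(18:25, 1)
    s5 <- sample(0:3, 1)
    e3 <- lens[i] - sample(0:3, 1)
    arms$arm5p_start[i] <- s5
    arms$arm5p_end[i] <- s5 + l5
    arms$arm3p_start[i] <- e3 - l3
    arms$arm3p_end[i] <- e3
  }
  prec <- data.frame(
    precursor_id = ids, sequence = seqs,
    chromosome = rep_len(chromosomes, n_precursors),
    length = lens, stringsAsFactors = FALSE)
  ref <- structure(list(precursors = prec, arms = arms),
                   class = "mirna_reference")
  validate_reference(ref)
  ref
}

#' Default cohort category marginals
#'
#' Frequencies of the raw covariate categories emulating a healthy-donor
#' stool-collection cohort of 335 adults (63.6% female, mean age 44.7
#' years): BMI classes, smoking strata, sex-specific alcohol strata, coffee
#' strata and occupational classes. Each marginal vector sums to 1.
#'
#' @return named list of named probability vectors
#' @export
default_cohort_marginals <- function() {
  norm1 <- function(x) x / sum(x)
  list(
    sex = norm1(c(female = 213, male = 122)),
    bmi_class = norm1(c(underweight = 25, normal = 215, overweight = 66,
                        obese = 18, missing = 11)),
    smoking = norm1(c(never = 181, former = 94, light_current = 41,
                      heavy_current = 16, missing = 3)),
    alcohol_class = norm1(c(non_drinker = 29, low = 230, high = 75)),
    coffee_class = norm1(c(non_drinker = 135, low = 149, high = 50)),
    occupational = norm1(c(sedentary = 40, standing = 22, manual = 10,
                           heavy_manual = 4, unemployed = 24))
  )
}

#' Simulate a raw questionnaire cohort
#'
#' Draws per-subject raw covariates whose derived categories reproduce the
#' supplied marginals: age from a truncated normal (mean 44.7, sd 14.7,
#' range 18-81), sex, height/weight implying the BMI-class frequencies,
#' smoking status with cigarettes/day, alcohol and coffee grams/day drawn
#' within the category bounds of the default cutoffs, recreational and
#' household MET-hours/week, occupational class, menopausal status for
#' females only (post-menopause age-linked), and a 24-plex library pool
#' label.
#'
#' @param n_subjects number of subjects (>= 4)
#' @param marginals list as returned by [default_cohort_marginals()];
#'   each vector must sum to 1 within 1e-9
#' @param seed integer seed
#' @param age_mean,age_sd,age_range truncated-normal age parameters
#' @return data.frame of raw covariates, one row per subject
#' @export
simulate_cohort <- function(n_subjects = 335,
                            marginals = default_cohort_marginals(),
                            seed = 1L,
                            age_mean = 44.7, age_sd = 14.7,
                            age_range = c(18, 81)) {
  stopifnot(n_subjects >= 4)
  for (nm in names(marginals)) {
    if (abs(sum(marginals[[nm]]) - 1) > 1e-9) {
      stop("marginal '", nm, "' does not sum to 1")
    }
  }
  set.seed(seed)
  n <- n_subjects
  draw <- function(m) sample(names(m), n, replace = TRUE, prob = m)

  age <- numeric(0)
  while (length(age) < n) {
    cand <- stats::rnorm(2 * n, age_mean, age_sd)
    age <- c(age, cand[cand >= age_range[1] & cand <= age_range[2]])
  }
  age <- round(age[seq_len(n)], 1)
  sex <- draw(marginals$sex)

  bmi_cat <- draw(marginals$bmi_class)
  bmi <- ifelse(bmi_cat == "underweight", stats::runif(n, 15.4, 18.4),
         ifelse(bmi_cat == "normal", stats::runif(n, 18.5, 24.9),
         ifelse(bmi_cat == "overweight", stats::runif(n, 25.0, 29.9),
         ifelse(bmi_cat == "obese", stats::runif(n, 30.0, 39.9), NA))))
  height_cm <- round(ifelse(sex == "female", stats::rnorm(n, 165, 6),
                            stats::rnorm(n, 178, 7)), 1)
  weight_kg <- round(bmi * (height_cm / 100)^2, 1)

  smoke_cat <- draw(marginals$smoking)
  smoking_status <- ifelse(smoke_cat %in% c("light_current", "heavy_current"),
                           "current",
                           ifelse(smoke_cat == "missing", NA, smoke_cat))
  cigs_per_day <- ifelse(smoke_cat == "light_current", sample(1:15, n, TRUE),
                         ifelse(smoke_cat == "heavy_current",
                                sample(16:40, n, TRUE), 0))
  cigs_per_day[is.na(smoking_status)] <- NA

  alc_cat <- draw(marginals$alcohol_class)
  alc_cut <- ifelse(sex == "male", 24, 12)
  alcohol_g_day <- round(ifelse(alc_cat == "non_drinker", 0,
                         ifelse(alc_cat == "low",
                                stats::runif(n, 0.1, alc_cut),
                                stats::runif(n, alc_cut + 0.1,
                                             3 * alc_cut))), 1)

  cof_cat <- draw(marginals$coffee_class)
  coffee_g_day <- round(ifelse(cof_cat == "non_drinker", 0,
                        ifelse(cof_cat == "low", stats::runif(n, 0.5, 8),
                               stats::runif(n, 8.5, 40))), 1)

  recreational_met_h <- round(stats::rlnorm(n, log(18), 0.8), 1)
  household_met_h <- round(stats::rlnorm(n, log(14), 0.9), 1)
  occupational <- draw(marginals$occupational)

  menopausal <- rep(NA_character_, n)
  fem <- sex == "female"
  menop_missing <- fem & stats::runif(n) < 4 / 213
  post <- fem & !menop_missing & (age + stats::rnorm(n, 0, 3) > 50.5)
  menopausal[fem & !menop_missing] <- ifelse(post[fem & !menop_missing],
                                             "post", "pre")

  data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = age, sex = sex, height_cm = height_cm, weight_kg = weight_kg,
    smoking_status = smoking_status, cigs_per_day = cigs_per_day,
    alcohol_g_day = alcohol_g_day, coffee_g_day = coffee_g_day,
    recreational_met_h = recreational_met_h,
    household_met_h = household_met_h,
    occupational = occupational, menopausal = menopausal,
    library_pool = paste0("pool", (seq_len(n) - 1L) %/% 24L + 1L),
    stringsAsFactors = FALSE
  )
}

#' Declare a planted expression effect
#'
#' @param variable cohort column the effect attaches to
#' @param contrast `c(reference_level, test_level)` for a categorical
#'   effect, or the string `"continuous"`
#' @param mirnas mature miRNA names carrying the effect
#' @param log2fc signed log2 fold change per miRNA (recycled)
#' @return list of class `effect_spec`
#' @export
effect_spec <- function(variable, contrast, mirnas, log2fc) {
  log2fc <- rep_len(log2fc, length(mirnas))
  stopifnot(all(is.finite(log2fc)), length(mirnas) >= 1)
  structure(list(variable = variable, contrast = contrast,
                 mirnas = mirnas, log2fc = log2fc), class = "effect_spec")
}

#' Simulation configuration for count generation
#'
#' Defaults emulate the throughput of a stool small-RNA-seq study: total
#' library size near 10.3 million reads of which about 0.92% are assigned
#' to miRNAs, long-tailed log-normal baseline abundances, negative-binomial
#' noise with dispersion 0.3, and mild library-pool batch variation.
#'
#' @param library_size_mean mean total reads per sample
#' @param mirna_fraction fraction of reads assigned to miRNAs, in `[0, 1]`
#' @param dispersion NB dispersion alpha (scalar or per-feature), >= 0
#' @param baseline_sdlog sd of log baseline abundances (long-tail control)
#' @param libsize_sdlog lognormal sd of per-sample assigned-read totals
#' @param batch_sd lognormal sd of the shared library-pool factor
#' @return list of class `sim_config`
#' @export
sim_config <- function(library_size_mean = 10.3e6, mirna_fraction = 0.0092,
                       dispersion = 0.3, baseline_sdlog = 2.2,
                       libsize_sdlog = 0.4, batch_sd = 0.1) {
  stopifnot(mirna_fraction >= 0, mirna_fraction <= 1,
            all(dispersion >= 0), library_size_mean > 0)
  structure(list(library_size_mean = library_size_mean,
                 mirna_fraction = mirna_fraction,
                 dispersion = dispersion,
                 baseline_sdlog = baseline_sdlog,
                 libsize_sdlog = libsize_sdlog,
                 batch_sd = batch_sd), class = "sim_config")
}

#' Simulate a mature miRNA count matrix with planted effects
#'
#' Counts follow `y_ij ~ NB(mean = s_j * mu_i * 2^(x_j * log2fc_i),
#' dispersion alpha)`: per-sample assigned-read totals `s_j` are drawn
#' lognormally around `library_size_mean * mirna_fraction` (with a shared
#' library-pool factor), baseline relative abundances `mu_i` are log-normal
#' and sum to 1, and each planted effect multiplies its miRNAs' means by
#' `2^log2fc` on the subjects at the test level (or proportionally to the
#' standardized covariate for continuous effects). The truth ledger listing
#' every planted (miRNA, variable, log2fc) is a first-class output.
#'
#' @param ref a `mirna_reference`
#' @param cohort data.frame from [simulate_cohort()] (categorized or raw;
#'   effect variables must resolve against its columns)
#' @param effects list of [effect_spec()] objects
#' @param config a [sim_config()]
#' @param seed integer seed
#' @return list of class `mir_sim`: `counts` (integer matrix, mature x
#'   subjects), `truth` (data.frame), `mu` (per-cell NB means),
#'   `size_factors_true`, `alpha`
#' @export
simulate_counts <- function(ref, cohort, effects = list(),
                            config = sim_config(), seed = 1L) {
  set.seed(seed)
  nm <- mature_names(ref)
  M <- length(nm)
  n <- nrow(cohort)
  stopifnot(n >= 4)
  base <- stats::rlnorm(M, 0, config$baseline_sdlog)
  base <- base / sum(base)
  target <- config$library_size_mean * config$mirna_fraction
  s <- stats::rlnorm(n, log(target), config$libsize_sdlog)
  if (!is.null(cohort$library_pool) && config$batch_sd > 0) {
    pools <- factor(cohort$library_pool)
    pool_fac <- exp(stats::rnorm(nlevels(pools), 0, config$batch_sd))
    s <- s * pool_fac[as.integer(pools)]
  }
  logmu <- outer(log(base), log(s), "+")
  truth <- list()
  for (ef in effects) {
    if (!ef$variable %in% names(cohort)) {
      stop("effect on missing covariate: ", ef$variable)
    }
    bad <- setdiff(ef$mirnas, nm)
    if (length(bad)) stop("effect on unknown miRNA: ", bad[1])
    v <- cohort[[ef$variable]]
    if (identical(ef$contrast, "continuous")) {
      x <- as.vector(scale(as.numeric(v)))
      x[is.na(x)] <- 0
    } else {
      x <- as.numeric(v == ef$contrast[2])
      x[is.na(x)] <- 0
    }
    rows <- match(ef$mirnas, nm)
    logmu[rows, ] <- logmu[rows, , drop = FALSE] +
      log(2) * outer(ef$log2fc, x)
    truth[[length(truth) + 1L]] <- data.frame(
      mirna = ef$mirnas, variable = ef$variable,
      reference_level = if (identical(ef$contrast, "continuous"))
        "continuous" else ef$contrast[1],
      test_level = if (identical(ef$contrast, "continuous"))
        "continuous" else ef$contrast[2],
      log2fc = ef$log2fc, stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(mirna = character(), variable = character(),
               reference_level = character(), test_level = character(),
               log2fc = numeric())
  mu <- exp(logmu)
  dimnames(mu) <- list(nm, cohort$subject_id)
  alpha <- rep_len(config$dispersion, M)
  y <- matrix(0L, M, n, dimnames = list(nm, cohort$subject_id))
  for (i in seq_len(M)) {
    y[i, ] <- if (alpha[i] == 0) stats::rpois(n, mu[i, ])
    else stats::rnbinom(n, mu = mu[i, ], size = 1 / alpha[i])
  }
  structure(list(counts = y, truth = truth, mu = mu,
                 size_factors_true = s, alpha = alpha),
            class = "mir_sim")
}

#' Simulate alignment records realizing a mature count vector
#'
#' The inverse of the quantification stage: each unit of count becomes one
#' alignment interval lying inside the corresponding annotated arm
#' (knowledge path) or strictly inside the corresponding precursor half
#' (position path), so `quantify_sample(simulate_alignments(c)) == c`
#' exactly for every valid count vector.
#'
#' @param counts_for_sample named integer vector over (a subset of)
#'   [mature_names()]
#' @param ref a `mirna_reference`
#' @param seed integer seed
#' @param read_prefix prefix for generated read ids
#' @return data.frame of alignment records (`read_id`, `precursor_id`,
#'   `start`, `end`, `is_primary`)
#' @export
simulate_alignments <- function(counts_for_sample, ref, seed = 1L,
                                read_prefix = "r") {
  set.seed(seed)
  counts_for_sample <- counts_for_sample[counts_for_sample > 0]
  if (!length(counts_for_sample)) {
    return(data.frame(read_id = character(), precursor_id = character(),
                      start = integer(), end = integer(),
                      is_primary = logical()))
  }
  prec_of <- sub("-(5p|3p)$", "", names(counts_for_sample))
  arm_of <- sub("^.*-(5p|3p)$", "\\1", names(counts_for_sample))
  i <- match(prec_of, ref$precursors$precursor_id)
  if (anyNA(i)) stop("count names not derivable from reference: ",
                     names(counts_for_sample)[is.na(i)][1])
  ann <- is_annotated(ref)[i]
  rows <- vector("list", length(counts_for_sample))
  for (k in seq_along(counts_for_sample)) {
    cnt <- counts_for_sample[[k]]
    len <- ref$precursors$length[i[k]]
    if (ann[k]) {
      a <- ref$arms[i[k], ]
      lo <- if (arm_of[k] == "5p") a$arm5p_start else a$arm3p_start
      hi <- if (arm_of[k] == "5p") a$arm5p_end else a$arm3p_end
    } else if (arm_of[k] == "5p") {
      lo <- 0L; hi <- floor(len / 2)
    } else {
      lo <- ceiling(len / 2); hi <- len
    }
    L <- pmin(hi - lo, sample(16:24, cnt, replace = TRUE))
    st <- lo + vapply(hi - lo - L, function(slack) {
      if (slack == 0) 0L else sample.int(slack + 1L, 1L) - 1L
    }, integer(1))
    rows[[k]] <- data.frame(
      read_id = sprintf("%s_%s_%d", read_prefix,
                        names(counts_for_sample)[k], seq_len(cnt)),
      precursor_id = prec_of[k], start = as.integer(st),
      end = as.integer(st + L), is_primary = TRUE,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate repeated (second time point) samples
#'
#' For a subset of subjects, re-draws counts from the subject's latent NB
#' means perturbed cellwise by lognormal drift of scale `drift_sd`,
#' emulating a second stool collection about one year later.
#'
#' @param sim a `mir_sim` from [simulate_counts()]
#' @param n_repeat_subjects how many subjects provide a second sample
#'   (default 6)
#' @param drift_sd lognormal drift scale (0 = pure NB resampling)
#' @param seed integer seed
#' @param subjects optional explicit subject ids (overrides the random
#'   subset)
#' @return integer count matrix over the same mature names, columns the
#'   repeated subjects
#' @export
simulate_repeated_samples <- function(sim, n_repeat_subjects = 6L,
                                      drift_sd = 0.2, seed = 1L,
                                      subjects = NULL) {
  set.seed(seed)
  ids <- colnames(sim$counts)
  if (is.null(subjects)) {
    stopifnot(n_repeat_subjects <= length(ids))
    subjects <- sort(sample(ids, n_repeat_subjects))
  }
  mu <- sim$mu[, subjects, drop = FALSE]
  if (drift_sd > 0) {
    mu <- mu * matrix(stats::rlnorm(length(mu), 0, drift_sd), nrow(mu))
  }
  y <- matrix(0L, nrow(mu), ncol(mu),
              dimnames = list(rownames(sim$counts), subjects))
  for (i in seq_len(nrow(mu))) {
    y[i, ] <- if (sim$alpha[i] == 0) stats::rpois(ncol(mu), mu[i, ])
    else stats::rnbinom(ncol(mu), mu = mu[i, ], size = 1 / sim$alpha[i])
  }
  y
}
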