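#' WHO BMI class
#'
#' `underweight` < 18.5, `normal` 18.5-24.9, `overweight` 25.0-29.9,
#' `obese` >= 30.0 kg/m2 (the boundary 30.0 is obese, following WHO).
#' Missing BMI maps to `"missing"`.
#'
#' @param bmi numeric vector, kg/m2
#' @return character vector of classes
#' @export
bmi_class <- function(bmi) {
  out <- rep("missing", length(bmi))
  ok <- !is.na(bmi)
  if (any(bmi[ok] <= 0)) stop("BMI must be positive")
  out[ok & bmi < 18.5] <- "underweight"
  out[ok & bmi >= 18.5 & bmi < 25] <- "normal"
  out[ok & bmi >= 25 & bmi < 30] <- "overweight"
  out[ok & bmi >= 30] <- "obese"
  out
}

#' Age tertiles
#'
#' Breakpoints are the empirical 1/3 and 2/3 quantiles (type 7, linear
#' interpolation). Assignment is left-closed on the lowest class and a
#' subject exactly on a breakpoint falls into the lower class, making the
#' overlapping printed labels ("18-37", "37-53") deterministic.
#'
#' @param ages numeric vector, length >= 3
#' @return list with `breaks` (the two interior quantiles) and `tertile`
#'   (factor `t1` < `t2` < `t3`); a single class with a warning when all
#'   ages are identical
#' @export
age_tertiles <- function(ages) {
  stopifnot(length(ages) >= 3)
  if (length(unique(ages[!is.na(ages)])) == 1L) {
    warning("all ages identical: a single age class")
    return(list(breaks = c(NA_real_, NA_real_),
                tertile = factor(rep("t1", length(ages)),
                                 levels = c("t1", "t2", "t3"))))
  }
  br <- stats::quantile(ages, c(1, 2) / 3, na.rm = TRUE, names = FALSE)
  tert <- ifelse(is.na(ages), NA,
                 ifelse(ages <= br[1], "t1", ifelse(ages <= br[2], "t2", "t3")))
  list(breaks = br, tertile = factor(tert, levels = c("t1", "t2", "t3")))
}

#' Smoking category
#'
#' Never and former smokers pass through; current smokers are split into
#' light (< 16 cigarettes/day) and heavy (>= 16 cigarettes/day, boundary
#' inclusive). A current smoker with unknown consumption is `"missing"`.
#'
#' @param status character vector in `never`/`former`/`current`
#' @param cigs_per_day numeric vector
#' @param heavy_cutoff cigarettes/day at and above which current smokers are
#'   heavy (default 16, the cohort median)
#' @return character vector
#' @export
smoking_category <- function(status, cigs_per_day, heavy_cutoff = 16) {
  stopifnot(all(status %in% c("never", "former", "current") | is.na(status)))
  out <- ifelse(is.na(status), "missing", status)
  cur <- !is.na(status) & status == "current"
  out[cur] <- ifelse(is.na(cigs_per_day[cur]), "missing",
                     ifelse(cigs_per_day[cur] >= heavy_cutoff,
                            "heavy_current", "light_current"))
  out
}

#' Alcohol intake category (sex-specific)
#'
#' Non-drinkers at 0 g/day; low intake up to and including 24.0 g/day for
#' males and 12.0 g/day for females; high intake strictly above.
#'
#' @param g_day grams of alcohol per day, >= 0
#' @param sex `"male"` or `"female"`
#' @return character vector (`non_drinker`/`low`/`high`/`missing`)
#' @export
alcohol_category <- function(g_day, sex) {
  if (any(g_day < 0, na.rm = TRUE)) stop("negative alcohol intake")
  cutoff <- ifelse(sex == "male", 24, 12)
  ifelse(is.na(g_day), "missing",
         ifelse(g_day == 0, "non_drinker",
                ifelse(g_day <= cutoff, "low", "high")))
}

#' Coffee intake category
#'
#' Non-drinkers at 0 g/day; drinkers split at a configurable cutoff
#' (default 8 g/day, the cohort median; boundary value is low).
#'
#' @param g_day grams of coffee per day, >= 0
#' @param cutoff split point in g/day (default 8)
#' @return character vector (`non_drinker`/`low`/`high`/`missing`)
#' @export
coffee_category <- function(g_day, cutoff = 8) {
  stopifnot(cutoff > 0)
  if (any(g_day < 0, na.rm = TRUE)) stop("negative coffee intake")
  ifelse(is.na(g_day), "missing",
         ifelse(g_day == 0, "non_drinker",
                ifelse(g_day <= cutoff, "low", "high")))
}

#' Default physical-activity cross-classification table
#'
#' Rows are occupational classes, columns the sex-specific quartiles of
#' non-occupational (recreational + household) MET-hours/week, following the
#' EPIC/Cambridge-index convention: a sedentary job with the lowest quartile
#' is inactive, heavy manual work is active regardless of quartile. The
#' table is plain data and can be replaced wholesale via configuration.
#'
#' @return 5x4 character matrix, dimnames occupational x quartile
#' @export
default_pai_table <- function() {
  lv <- c("inactive", "moderately_inactive", "moderately_active", "active")
  m <- rbind(
    sedentary    = lv[c(1, 2, 3, 4)],
    standing     = lv[c(2, 3, 4, 4)],
    manual       = lv[c(3, 4, 4, 4)],
    heavy_manual = lv[c(4, 4, 4, 4)],
    unemployed   = lv[c(1, 2, 3, 4)]
  )
  colnames(m) <- c("low", "medium", "high", "very_high")
  m
}

#' Physical activity index (PAI)
#'
#' Total non-occupational MET-hours/week (recreational + household, equal
#' weight) are split into sex-specific quartiles within the cohort and
#' cross-classified with the occupational class via a lookup table.
#'
#' @param recreational_met_h,household_met_h MET-hours/week, >= 0
#' @param occupational character vector over the rownames of `pai_table`
#' @param sex `"male"`/`"female"`, used to form sex-specific quartiles
#' @param pai_table cross-classification matrix (see [default_pai_table()])
#' @return list with `pai` (character vector), `quartile` (factor) and
#'   `breaks` (list of per-sex quartile breakpoints)
#' @export
physical_activity_index <- function(recreational_met_h, household_met_h,
                                    occupational, sex,
                                    pai_table = default_pai_table()) {
  total <- recreational_met_h + household_met_h
  if (any(total < 0, na.rm = TRUE)) stop("MET-hours must be non-negative")
  qlab <- colnames(pai_table)
  quart <- rep(NA_character_, length(total))
  breaks <- list()
  for (sx in unique(sex[!is.na(sex)])) {
    idx <- which(sex == sx & !is.na(total))
    if (!length(idx)) next
    br <- stats::quantile(total[idx], c(1, 2, 3) / 4, names = FALSE)
    breaks[[sx]] <- br
    # boundary values fall in the lower quartile, as for age tertiles
    quart[idx] <- qlab[1L + (total[idx] > br[1]) + (total[idx] > br[2]) +
                         (total[idx] > br[3])]
  }
  pai <- rep("missing", length(total))
  ok <- !is.na(occupational) & !is.na(quart) &
    occupational %in% rownames(pai_table)
  pai[ok] <- pai_table[cbind(occupational[ok], quart[ok])]
  list(pai = pai,
       quartile = factor(quart, levels = qlab),
       breaks = breaks)
}

#' Derive every analysis stratum from raw questionnaire covariates
#'
#' Adds (or recomputes) `bmi`, `bmi_class`, `age_tertile`, `smoking`,
#' `alcohol_class`, `coffee_class`, `pai` and passes `menopausal` through
#' (validated to be female-only). Idempotent: re-categorizing a categorized
#' table is a no-op.
#'
#' @param raw data.frame with columns `subject_id`, `age`, `sex`,
#'   `height_cm`, `weight_kg` (or `bmi`), `smoking_status`, `cigs_per_day`,
#'   `alcohol_g_day`, `coffee_g_day`, `recreational_met_h`,
#'   `household_met_h`, `occupational`, optional `menopausal`
#' @param coffee_cutoff passed to [coffee_category()]
#' @param pai_table passed to [physical_activity_index()]
#' @return the input data.frame with derived category columns appended
#' @export
categorize_cohort <- function(raw, coffee_cutoff = 8,
                              pai_table = default_pai_table()) {
  out <- raw
  if (!"bmi" %in% names(out)) {
    out$bmi <- out$weight_kg / (out$height_cm / 100)^2
  }
  if (!is.null(out$menopausal)) {
    bad <- !is.na(out$menopausal) & out$sex != "female"
    if (any(bad)) stop("menopausal status set for non-female subject: ",
                       out$subject_id[bad][1])
  }
  out$bmi_class <- bmi_class(out$bmi)
  tert <- age_tertiles(out$age)
  out$age_tertile <- as.character(tert$tertile)
  out$smoking <- smoking_category(out$smoking_status, out$cigs_per_day)
  out$alcohol_class <- alcohol_category(out$alcohol_g_day, out$sex)
  out$coffee_class <- coffee_category(out$coffee_g_day, coffee_cutoff)
  pai <- physical_activity_index(out$recreational_met_h, out$household_met_h,
                                 out$occupational, out$sex, pai_table)
  out$pai <- pai$pai
  attr(out, "age_breaks") <- tert$breaks
  attr(out, "met_breaks") <- pai$breaks
  out
}
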