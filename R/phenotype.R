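#' Fatty liver index (FLI)
#'
#' Logistic-scale steatosis score from triglycerides, BMI,
#' gamma-glutamyl transferase and waist circumference:
#' `FLI = 100 * plogis(0.953*ln(TG) + 0.139*BMI + 0.718*ln(GGT)
#' + 0.053*WC - 15.745)`.  The coefficients are unit-bound: TG must be in
#' mg/dL and GGT in U/L (cohorts reporting TG in mmol/L should convert
#' with [tgToMgdl()]).  A unit mismatch cannot be detected from the values
#' themselves.  FLI >= 60 is the hepatic-steatosis cutoff used throughout
#' this package.
#'
#' @param tg triglycerides, mg/dL (> 0).
#' @param bmi body mass index, kg/m^2 (> 0).
#' @param ggt gamma-glutamyl transferase, U/L (> 0).
#' @param wc waist circumference, cm (> 0).
#' @return FLI, strictly inside (0, 100). Vectorized.
#' @examples
#' fattyLiverIndex(tg = 150, bmi = 30, ggt = 50, wc = 100)
#' @export
fattyLiverIndex <- function(tg, bmi, ggt, wc) {
  for (nm in c("tg", "bmi", "ggt", "wc")) {
    v <- get(nm)
    if (any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("'%s' must be strictly positive", nm), call. = FALSE)
    }
  }
  z <- 0.953 * log(tg) + 0.139 * bmi + 0.718 * log(ggt) + 0.053 * wc - 15.745
  100 * plogis(z)
}

#' Laboratory unit conversions
#'
#' Standard conversion factors between SI and conventional units for the
#' analytes the fatty liver index and the MASLD criteria use:
#' triglycerides 1 mmol/L = 88.57 mg/dL, glucose 1 mmol/L = 18.016 mg/dL.
#'
#' @param x nonnegative concentration.
#' @return converted concentration.
#' @export
tgToMgdl <- function(x) {
  if (any(x < 0)) stop("concentration must be nonnegative", call. = FALSE)
  x * 88.57
}

#' @rdname tgToMgdl
#' @export
tgToMmol <- function(x) {
  if (any(x < 0)) stop("concentration must be nonnegative", call. = FALSE)
  x / 88.57
}

#' @rdname tgToMgdl
#' @export
glucoseToMgdl <- function(x) {
  if (any(x < 0)) stop("concentration must be nonnegative", call. = FALSE)
  x * 18.016
}

#' MASLD diagnosis from steatosis plus cardiometabolic criteria
#'
#' MASLD requires hepatic steatosis (FLI >= 60) plus at least one of three
#' arms: (1) type 2 diabetes; (2) overweight/obesity, BMI >= 25 kg/m^2;
#' (3) metabolic abnormality, read as at least two of: insulin resistance;
#' prediabetes (fasting glucose >= 100 mg/dL or HbA1c >= 5.7%); low HDL
#' (< 1.03 mmol/L males, < 1.29 females); hypertriglyceridemia
#' (TG >= 1.7 mmol/L); hypertension (SBP >= 130 or DBP >= 85 mmHg or
#' antihypertensive use); increased waist circumference (>= 102 cm males,
#' >= 88 cm females).  Unknown insulin resistance counts as not met, so
#' the criterion count is conservative toward non-MASLD.
#'
#' @param fli fatty liver index (0-100).
#' @param t2dm logical, type 2 diabetes.
#' @param bmi kg/m^2.
#' @param fasting_glucose mg/dL.
#' @param hba1c percent.
#' @param hdl mmol/L.
#' @param tg mmol/L.
#' @param sbp,dbp mmHg.
#' @param antihypertensive logical.
#' @param wc cm.
#' @param sex `"male"` or `"female"` (needed for HDL and WC cutoffs).
#' @param insulin_resistance logical or NA (NA treated as not met).
#' @param fliCutoff steatosis threshold, default 60.
#' @return a list with `masld` (logical), `basis` (`"t2dm"`,
#'   `"overweight"`, `"metabolic"` or `"none"`), `steatosis`, and
#'   `criteria` (named logical matrix of the six metabolic criteria for
#'   audit). Vectorized over participants.
#' @export
diagnoseMASLD <- function(fli, t2dm, bmi, fasting_glucose, hba1c, hdl, tg,
                          sbp, dbp, antihypertensive, wc, sex,
                          insulin_resistance = NA, fliCutoff = 60) {
  n <- length(fli)
  sex <- as.character(sex)
  if (anyNA(sex) || !all(sex %in% c("male", "female"))) {
    stop("'sex' must be 'male' or 'female' for every participant",
         call. = FALSE)
  }
  male <- sex == "male"
  ir <- rep_len(insulin_resistance, n)
  ir[is.na(ir)] <- FALSE
  criteria <- cbind(
    insulin_resistance = as.logical(ir),
    prediabetes = fasting_glucose >= 100 | hba1c >= 5.7,
    low_hdl = ifelse(male, hdl < 1.03, hdl < 1.29),
    high_tg = tg >= 1.7,
    hypertension = sbp >= 130 | dbp >= 85 | as.logical(antihypertensive),
    high_wc = ifelse(male, wc >= 102, wc >= 88)
  )
  steatosis <- fli >= fliCutoff
  armT2dm <- as.logical(t2dm)
  armOverweight <- bmi >= 25
  armMetabolic <- rowSums(criteria) >= 2
  masld <- steatosis & (armT2dm | armOverweight | armMetabolic)
  basis <- rep("none", n)
  basis[masld & armMetabolic] <- "metabolic"
  basis[masld & armOverweight] <- "overweight"
  basis[masld & armT2dm] <- "t2dm"
  list(masld = masld, basis = basis, steatosis = steatosis,
       criteria = criteria)
}

#' Composite sleep score and sleep pattern
#'
#' One point for each low-risk sleep behaviour: early chronotype (either of
#' the two most morning-leaning questionnaire options), sleeping 7-8 hours
#' per 24 h, insomnia "never/rarely", no snoring, and daytime sleepiness
#' "never/rarely" or "sometimes".  Scores >= 4 define a healthy sleep
#' pattern, <= 1 poor, otherwise intermediate.  Sleep duration is also
#' categorized as short (< 7 h), normal (7-8 h) or long (>= 9 h).
#'
#' @param chronotype integer 1-4, 1 = definite morning; 1-2 count as early.
#' @param duration_hours hours of sleep per 24 h (integer questionnaire
#'   hours; non-integer values are floored with a warning).
#' @param insomnia one of `"never/rarely"`, `"sometimes"`, `"usually"`.
#' @param snoring logical.
#' @param daytime_sleepiness one of `"never/rarely"`, `"sometimes"`,
#'   `"often"`.
#' @return list with `score` (0-5), `pattern` (`"healthy"`,
#'   `"intermediate"`, `"poor"`), `duration_category` and `components`
#'   (named logical matrix of the five items). Vectorized.
#' @export
sleepScore <- function(chronotype, duration_hours, insomnia, snoring,
                       daytime_sleepiness) {
  args <- list(chronotype, duration_hours, insomnia, snoring,
               daytime_sleepiness)
  if (any(vapply(args, anyNA, logical(1)))) {
    stop("all five sleep items must be present (no partial scores)",
         call. = FALSE)
  }
  if (any(duration_hours < 0)) {
    stop("sleep duration must be nonnegative", call. = FALSE)
  }
  if (any(duration_hours != floor(duration_hours))) {
    warning("non-integer sleep durations floored to whole hours")
    duration_hours <- floor(duration_hours)
  }
  insomnia <- match.arg(as.character(insomnia),
                        c("never/rarely", "sometimes", "usually"),
                        several.ok = TRUE)
  daytime_sleepiness <- match.arg(as.character(daytime_sleepiness),
                                  c("never/rarely", "sometimes", "often"),
                                  several.ok = TRUE)
  components <- cbind(
    early_chronotype = chronotype %in% c(1L, 2L),
    normal_duration = duration_hours >= 7 & duration_hours <= 8,
    no_insomnia = insomnia == "never/rarely",
    no_snoring = !as.logical(snoring),
    low_sleepiness = daytime_sleepiness %in% c("never/rarely", "sometimes")
  )
  score <- rowSums(components)
  pattern <- ifelse(score >= 4, "healthy",
                    ifelse(score <= 1, "poor", "intermediate"))
  duration_category <- ifelse(duration_hours < 7, "short",
                              ifelse(duration_hours >= 9, "long", "normal"))
  list(score = as.integer(score), pattern = pattern,
       duration_category = duration_category, components = components)
}

#' BMI category on the conventional four-level scale
#'
#' Level 1: < 18.5; level 2: 18.5 to < 25; level 3: 25 to < 30;
#' level 4: >= 30 (lower bounds inclusive).
#'
#' @param bmi kg/m^2, > 0.
#' @return integer 1-4. Vectorized.
#' @export
bmiCategory <- function(bmi) {
  if (any(!is.finite(bmi)) || any(bmi <= 0)) {
    stop("'bmi' must be strictly positive", call. = FALSE)
  }
  findInterval(bmi, c(18.5, 25, 30)) + 1L
}

#' Derive all phenotypes for a participant table
#'
#' Convenience wrapper applying [fattyLiverIndex()], [diagnoseMASLD()],
#' [sleepScore()] and [bmiCategory()] to a cohort table with the standard
#' column names produced by [generateCohort()] (`tg_mmol`, `ggt`, `bmi`,
#' `wc`, `sex`, `t2dm`, `fasting_glucose_mgdl`, `hba1c`, `hdl_mmol`,
#' `sbp`, `dbp`, `antihypertensive`, `chronotype`, `sleep_hours`,
#' `insomnia`, `snoring`, `sleepiness`).
#'
#' @param df participant `data.frame`.
#' @return `df` with added columns `fli`, `steatosis`, `masld_derived`,
#'   `masld_basis`, `bmi_level`, `sleep_score`, `sleep_pattern`,
#'   `duration_category`.
#' @export
derivePhenotypes <- function(df) {
  df$fli <- fattyLiverIndex(tgToMgdl(df$tg_mmol), df$bmi, df$ggt, df$wc)
  dx <- diagnoseMASLD(
    fli = df$fli, t2dm = df$t2dm, bmi = df$bmi,
    fasting_glucose = df$fasting_glucose_mgdl, hba1c = df$hba1c,
    hdl = df$hdl_mmol, tg = df$tg_mmol, sbp = df$sbp, dbp = df$dbp,
    antihypertensive = df$antihypertensive, wc = df$wc, sex = df$sex
  )
  df$steatosis <- dx$steatosis
  df$masld_derived <- dx$masld
  df$masld_basis <- dx$basis
  df$bmi_level <- bmiCategory(df$bmi)
  ss <- sleepScore(df$chronotype, df$sleep_hours, df$insomnia, df$snoring,
                   df$sleepiness)
  df$sleep_score <- ss$score
  df$sleep_pattern <- ss$pattern
  df$duration_category <- ss$duration_category
  df
}
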