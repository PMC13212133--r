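#' Configuration for the synthetic-cohort generator
#'
#' Bundles and validates every parameter of [generateCohort()].  The
#' defaults describe a mid-life population with accelerometer-style
#' activity (arbitrary milli-gravity-like units), a small latent group
#' with damped circadian amplitude, and a proteome in which the first
#' `n_mediators` proteins carry a planted exposure -> protein -> outcome
#' mediation path.
#'
#' @param n_participants cohort size.
#' @param n_proteins proteins in the simulated proteome.
#' @param n_mediators planted mediator proteins (<= `n_proteins`).
#' @param mesor mean activity level, > 0.
#' @param amplitude_range length-2 nonnegative vector `c(low, high)`:
#'   cosinor amplitudes of the damped (low-RA) and intact (high-RA)
#'   regimes; requires `low <= high`.
#' @param acrophase_hours peak-activity clock hour in `[0, 24)`.
#' @param noise_sd hourly activity noise SD, >= 0.
#' @param prop_low probability of the latent damped-amplitude group.
#' @param mediator_a exposure -> protein effect (abundance units).
#' @param mediator_b protein -> outcome effect (log-odds per abundance
#'   unit).
#' @param direct_c direct exposure -> outcome log-odds.
#' @param covariate_effects named log-odds coefficients for the
#'   standardized covariates `age_z`, `sex_male`, `bmi_z`.
#' @param outcome_intercept log-odds intercept.
#' @param seed integer seed (required; expanded into per-component
#'   substreams).
#' @return validated list of class `"synthConfig"`.
#' @export
synthConfig <- function(n_participants = 2000,
                        n_proteins = 300,
                        n_mediators = 6,
                        mesor = 28,
                        amplitude_range = c(6, 24),
                        acrophase_hours = 14,
                        noise_sd = 2,
                        prop_low = 0.05,
                        mediator_a = 0.6,
                        mediator_b = 0.5,
                        direct_c = 0.3,
                        covariate_effects = c(age_z = 0.3, sex_male = 0.6,
                                              bmi_z = 0.8),
                        outcome_intercept = -1.3,
                        seed = NULL) {
  if (is.null(seed)) stop("'seed' is required", call. = FALSE)
  cfg <- list(
    n_participants = assertCount(n_participants, "n_participants"),
    n_proteins = assertCount(n_proteins, "n_proteins"),
    n_mediators = assertCount(n_mediators, "n_mediators", min = 0L),
    mesor = assertScalarNumber(mesor, "mesor", lower = 0, strict = TRUE),
    amplitude_range = amplitude_range,
    acrophase_hours = acrophase_hours,
    noise_sd = assertScalarNumber(noise_sd, "noise_sd", lower = 0),
    prop_low = prop_low,
    mediator_a = mediator_a,
    mediator_b = mediator_b,
    direct_c = direct_c,
    covariate_effects = covariate_effects,
    outcome_intercept = outcome_intercept,
    seed = assertCount(seed, "seed", min = 0L)
  )
  if (length(amplitude_range) != 2L || any(amplitude_range < 0) ||
      amplitude_range[1] > amplitude_range[2]) {
    stop("'amplitude_range' must be c(low, high) with 0 <= low <= high",
         call. = FALSE)
  }
  if (acrophase_hours < 0 || acrophase_hours >= 24) {
    stop("'acrophase_hours' must lie in [0, 24)", call. = FALSE)
  }
  if (cfg$n_mediators > cfg$n_proteins) {
    stop("'n_mediators' cannot exceed 'n_proteins'", call. = FALSE)
  }
  if (prop_low <= 0 || prop_low >= 1) {
    stop("'prop_low' must be in (0, 1)", call. = FALSE)
  }
  class(cfg) <- "synthConfig"
  cfg
}

#' One cosinor activity profile
#'
#' Hourly expected activity follows a 24-hour cosinor,
#' `max(0, mesor + amplitude * cos(2*pi*(h - acrophase)/24) + noise)`;
#' the clip at zero reflects that acceleration cannot be negative (it
#' slightly attenuates relative amplitude when the amplitude approaches
#' the mesor).
#'
#' @param amplitude cosinor amplitude, >= 0.
#' @param mesor mean level, > 0.
#' @param acrophase peak hour.
#' @param noise_sd Gaussian noise SD (draws from the current RNG state).
#' @return numeric vector of 24 nonnegative hourly values.
#' @export
generateActivityProfile <- function(amplitude, mesor, acrophase, noise_sd) {
  assertScalarNumber(amplitude, "amplitude", lower = 0)
  assertScalarNumber(mesor, "mesor", lower = 0, strict = TRUE)
  h <- 0:23
  mu <- mesor + amplitude * cos(2 * pi * (h - acrophase) / 24)
  eps <- if (noise_sd > 0) rnorm(24L, 0, noise_sd) else 0
  pmax(0, mu + eps)
}

#' Generate a synthetic accelerometry + proteomics cohort
#'
#' Produces a [SyntheticCohort-class] whose statistical structure matches
#' what the downstream stages assume.  A latent binary exposure group
#' (damped vs intact circadian amplitude, probability `prop_low`) drives
#' three things: the cosinor amplitude of each activity profile, the
#' abundance of the planted mediator proteins
#' (`M_j = mediator_a * group + noise`), and, together with the mediators
#' and covariates, a logistic outcome
#' `logit P(Y=1) = intercept + direct_c * group +
#' sum_j mediator_b * M_j + covariate effects`.  Non-mediator proteins
#' are independent standard-normal noise.  The root seed is expanded into
#' per-component substreams, so enlarging the proteome does not perturb
#' the covariate or profile draws.
#'
#' @param config a [synthConfig()].
#' @return a [SyntheticCohort-class]; `cohortTruth()` records the latent
#'   group, per-protein effects and all planted parameters.
#' @export
generateCohort <- function(config) {
  if (!inherits(config, "synthConfig")) {
    stop("'config' must come from synthConfig()", call. = FALSE)
  }
  n <- config$n_participants
  ids <- sprintf("p%05d", seq_len(n))

  covs <- withStream(config$seed, 1L, simulateCovariates(n))
  covs$participant_id <- ids
  covs <- covs[, c("participant_id", setdiff(names(covs), "participant_id"))]

  grp <- withStream(config$seed, 2L, {
    latentLow <- runif(n) < config$prop_low
    r <- diff(config$amplitude_range)
    lowA <- config$amplitude_range[1] + 0.25 * r * runif(n)
    highA <- config$amplitude_range[2] - 0.25 * r * runif(n)
    list(low = latentLow, amplitude = ifelse(latentLow, lowA, highA))
  })

  profiles <- withStream(config$seed, 3L, {
    t(vapply(seq_len(n), function(i) {
      generateActivityProfile(grp$amplitude[i], config$mesor,
                              config$acrophase_hours, config$noise_sd)
    }, numeric(24L)))
  })
  rownames(profiles) <- ids
  colnames(profiles) <- paste0("hour_", 0:23)

  proteinIds <- sprintf("PROT%04d", seq_len(config$n_proteins))
  mediatorIds <- head(proteinIds, config$n_mediators)
  a <- setNames(rep(0, config$n_proteins), proteinIds)
  a[mediatorIds] <- config$mediator_a
  b <- setNames(rep(0, config$n_proteins), proteinIds)
  b[mediatorIds] <- config$mediator_b
  x <- as.numeric(grp$low)
  abundance <- withStream(config$seed, 4L, {
    noise <- matrix(rnorm(config$n_proteins * n), nrow = config$n_proteins)
    noise + outer(a, x)
  })
  rownames(abundance) <- proteinIds
  colnames(abundance) <- ids

  ce <- config$covariate_effects
  lp <- config$outcome_intercept + config$direct_c * x +
    drop(crossprod(abundance, b)) +
    ce[["age_z"]] * (covs$age - 56) / 8 +
    ce[["sex_male"]] * (covs$sex == "male") +
    ce[["bmi_z"]] * (covs$bmi - 27) / 4
  covs$masld <- withStream(config$seed, 5L,
                           as.integer(runif(n) < plogis(lp)))

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = abundance),
    colData = S4Vectors::DataFrame(participant_id = ids, row.names = ids)
  )
  new("SyntheticCohort",
      participants = covs, profiles = profiles, proteome = se,
      truth = list(
        latent_low = grp$low, amplitude = grp$amplitude,
        mediator_ids = mediatorIds, a = a, b = b,
        direct_c = config$direct_c,
        outcome_intercept = config$outcome_intercept,
        covariate_effects = ce, linear_predictor = lp,
        config = config
      ))
}

simulateCovariates <- function(n) {
  data.frame(
    age = rnorm(n, 56, 8),
    sex = ifelse(runif(n) < 0.44, "male", "female"),
    bmi = rlnorm(n, log(27), 0.15),
    wc = rnorm(n, 90, 12),
    tg_mmol = rlnorm(n, log(1.5), 0.4),
    ggt = rlnorm(n, log(30), 0.5),
    hdl_mmol = rlnorm(n, log(1.45), 0.2),
    fasting_glucose_mgdl = rnorm(n, 95, 12),
    hba1c = rnorm(n, 5.5, 0.5),
    sbp = rnorm(n, 137, 17),
    dbp = rnorm(n, 82, 10),
    antihypertensive = runif(n) < 0.15,
    t2dm = runif(n) < 0.03,
    tdi = rnorm(n, -1.7, 2.8),
    education = sample(c("College", "Other", "Unknown"), n, TRUE,
                       prob = c(0.43, 0.48, 0.09)),
    ethnicity = sample(c("White", "Other"), n, TRUE, prob = c(0.97, 0.03)),
    smoking = sample(c("Never", "Previous", "Current"), n, TRUE,
                     prob = c(0.56, 0.36, 0.08)),
    drinking = sample(c("Current", "Never", "Previous"), n, TRUE,
                      prob = c(0.94, 0.03, 0.03)),
    chronotype = sample(1:4, n, TRUE, prob = c(0.24, 0.32, 0.28, 0.16)),
    sleep_hours = sample(4:11, n, TRUE,
                         prob = c(0.01, 0.04, 0.18, 0.41, 0.28, 0.06,
                                  0.015, 0.005)),
    insomnia = sample(c("never/rarely", "sometimes", "usually"), n, TRUE,
                      prob = c(0.24, 0.47, 0.29)),
    snoring = runif(n) < 0.37,
    sleepiness = sample(c("never/rarely", "sometimes", "often"), n, TRUE,
                        prob = c(0.77, 0.20, 0.03)),
    stringsAsFactors = FALSE
  )
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits `participants.csv`, `profiles.csv` (wide, `hour_0..hour_23`),
#' `proteome.csv` (participants as rows, proteins as columns) and
#' `truth.json`.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(participants(cohort), file.path(dir, "participants.csv"),
            row.names = FALSE)
  prof <- data.frame(participant_id = rownames(activityProfiles(cohort)),
                     activityProfiles(cohort), check.names = FALSE)
  write.csv(prof, file.path(dir, "profiles.csv"), row.names = FALSE)
  ab <- t(SummarizedExperiment::assay(proteome(cohort), "abundance"))
  write.csv(data.frame(participant_id = rownames(ab), ab,
                       check.names = FALSE),
            file.path(dir, "proteome.csv"), row.names = FALSE)
  truth <- cohortTruth(cohort)
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
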