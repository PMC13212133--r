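# shared fixtures, built in code

# brute-force circular window search, independent of the package's
# cumulative-sum implementation
bruteWindow <- function(hourly, width, which = c("max", "min")) {
  which <- match.arg(which)
  means <- vapply(0:23, function(s) {
    mean(hourly[(s + 0:(width - 1)) %% 24 + 1])
  }, numeric(1))
  pick <- if (which == "max") which.max(means) else which.min(means)
  list(value = means[pick], start = pick - 1L)
}

# small participant table with every column the phenotype/assoc layers need
makeParticipants <- function(n, seed = 42) {
  set.seed(seed)
  df <- data.frame(
    participant_id = sprintf("p%04d", seq_len(n)),
    age = rnorm(n, 56, 8),
    sex = sample(c("male", "female"), n, TRUE),
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
    education = sample(c("College", "Other", "Unknown"), n, TRUE),
    ethnicity = sample(c("White", "Other"), n, TRUE, prob = c(0.95, 0.05)),
    smoking = sample(c("Never", "Previous", "Current"), n, TRUE),
    drinking = sample(c("Current", "Never", "Previous"), n, TRUE),
    chronotype = sample(1:4, n, TRUE),
    sleep_hours = sample(5:10, n, TRUE),
    insomnia = sample(c("never/rarely", "sometimes", "usually"), n, TRUE),
    snoring = runif(n) < 0.4,
    sleepiness = sample(c("never/rarely", "sometimes", "often"), n, TRUE),
    stringsAsFactors = FALSE
  )
  df
}

smallConfig <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(n_participants = 400, n_proteins = 60, n_mediators = 4,
         prop_low = 0.1, seed = seed),
    list(...)
  )
  do.call(synthConfig, args)
}
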