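#' M10, L5 and relative amplitude from a 24-hour activity profile
#'
#' Nonparametric circadian metrics: `M10` is the mean acceleration over the
#' most active 10-hour window and `L5` the mean over the least active
#' 5-hour window, both searched over all 24 circularly wrapped window start
#' hours (the least active window commonly spans midnight, so the search
#' must wrap).  Relative amplitude is `(M10 - L5) / (M10 + L5)`, a
#' unit-free contrast in `[0, 1]`; values near 0 indicate a damped
#' rest-activity rhythm.
#'
#' Ties between windows are broken by the smallest start hour.
#'
#' @param hourly numeric vector of 24 nonnegative hourly mean accelerations
#'   (hour of day 0-23, averaged over the wear period).
#' @return `computeM10L5`: a one-row `data.frame` with `m10`, `l5`,
#'   `m10_start_hour`, `l5_start_hour`.
#' @examples
#' prof <- pmax(0, 28 + 20 * cos(2 * pi * (0:23 - 14) / 24))
#' m <- computeM10L5(prof)
#' relativeAmplitude(m$m10, m$l5)
#' @export
computeM10L5 <- function(hourly) {
  hourly <- validateProfile(hourly)
  m10w <- windowMeans(hourly, 10L)
  l5w <- windowMeans(hourly, 5L)
  i10 <- which.max(m10w) # which.max returns first index: smallest start hour
  i5 <- which.min(l5w)
  data.frame(
    m10 = m10w[i10], l5 = l5w[i5],
    m10_start_hour = i10 - 1L, l5_start_hour = i5 - 1L
  )
}

validateProfile <- function(hourly) {
  hourly <- as.numeric(hourly)
  if (length(hourly) != 24L || anyNA(hourly)) {
    stop("activity profile must be 24 non-missing hourly values",
         call. = FALSE)
  }
  if (any(hourly < 0)) {
    stop("activity profile values must be nonnegative", call. = FALSE)
  }
  hourly
}

# circular window means for all 24 start hours, via wrap-around cumsum
windowMeans <- function(hourly, width) {
  ext <- c(hourly, hourly[seq_len(width - 1L)])
  cs <- c(0, cumsum(ext))
  (cs[seq_len(24L) + width] - cs[seq_len(24L)]) / width
}

#' @rdname computeM10L5
#' @param m10,l5 window means, `m10 >= l5 >= 0`, not both zero.
#' @return `relativeAmplitude`: a number in `[0, 1]`.
#' @export
relativeAmplitude <- function(m10, l5) {
  if (any(m10 < 0) || any(l5 < 0) || any(m10 < l5)) {
    stop("need m10 >= l5 >= 0", call. = FALSE)
  }
  if (any(m10 + l5 == 0)) {
    stop("relative amplitude undefined for an all-zero profile",
         call. = FALSE)
  }
  (m10 - l5) / (m10 + l5)
}

#' Relative-amplitude metrics for a whole cohort
#'
#' Applies [computeM10L5()] and [relativeAmplitude()] to every row of a
#' profile matrix.
#'
#' @param profiles numeric matrix, participants x 24 (row names taken as
#'   participant ids), or a [SyntheticCohort].
#' @return `data.frame` with columns `participant_id`, `m10`, `l5`,
#'   `m10_start_hour`, `l5_start_hour`, `ra`.
#' @export
raMetrics <- function(profiles) {
  if (is(profiles, "SyntheticCohort")) profiles <- activityProfiles(profiles)
  if (!is.matrix(profiles) || ncol(profiles) != 24L) {
    stop("'profiles' must be a participants x 24 matrix", call. = FALSE)
  }
  res <- do.call(rbind, lapply(seq_len(nrow(profiles)), function(i) {
    computeM10L5(profiles[i, ])
  }))
  ids <- rownames(profiles)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(profiles)))
  data.frame(participant_id = ids, res,
             ra = relativeAmplitude(res$m10, res$l5),
             row.names = NULL)
}

#' Classify participants into low / high relative-amplitude groups
#'
#' The low-RA group is defined as participants whose RA lies more than two
#' sample standard deviations below the sample mean (strict `<`); everyone
#' else, including participants exactly at the threshold, is "high".
#'
#' @param ra numeric vector of per-participant relative amplitudes, no
#'   missing values, length >= 2.
#' @param sdMultiplier how many SDs below the mean the cutoff sits
#'   (default 2).
#' @return a list with `threshold`, `mean_ra`, `sd_ra`, and `low` (logical
#'   vector aligned to `ra`).
#' @examples
#' classifyLowRA(c(0.9, 0.9, 0.9, 0.3))$threshold # 0.15
#' @export
classifyLowRA <- function(ra, sdMultiplier = 2) {
  if (anyNA(ra)) stop("RA values must not be missing", call. = FALSE)
  if (length(ra) < 2L) {
    stop("need at least 2 participants to form RA groups", call. = FALSE)
  }
  m <- mean(ra)
  s <- sd(ra) # sample (n-1) SD
  thr <- m - sdMultiplier * s
  list(threshold = thr, mean_ra = m, sd_ra = s, low = ra < thr)
}
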