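#' Per-protein two-group linear fits
#'
#' For each protein (row) fits the two-group mean model: `log_fc` is the
#' group mean difference (group 1 minus group 0), `s2_g` the pooled
#' residual variance on `n - 2` degrees of freedom, and `t_ordinary` the
#' classical pooled-variance t-statistic.
#'
#' @param mat numeric matrix, proteins x participants (or a
#'   `SummarizedExperiment` with an `"abundance"` assay).
#' @param group binary vector (0/1 or logical) aligned to the columns;
#'   both groups need at least 2 members.
#' @return `data.frame` with `protein_id`, `log_fc`, `s2_g`, `df_g`,
#'   `t_ordinary`.
#' @export
fitPerProtein <- function(mat, group) {
  mat <- asAbundanceMatrix(mat)
  group <- as.integer(as.logical(group))
  if (length(group) != ncol(mat)) {
    stop("'group' must align with the participant columns", call. = FALSE)
  }
  n1 <- sum(group == 1L)
  n0 <- sum(group == 0L)
  if (n1 < 2L || n0 < 2L) {
    stop("each group needs at least 2 members", call. = FALSE)
  }
  m1 <- rowMeans(mat[, group == 1L, drop = FALSE])
  m0 <- rowMeans(mat[, group == 0L, drop = FALSE])
  ss1 <- rowSums((mat[, group == 1L, drop = FALSE] - m1)^2)
  ss0 <- rowSums((mat[, group == 0L, drop = FALSE] - m0)^2)
  df <- n1 + n0 - 2L
  s2 <- (ss1 + ss0) / df
  seFac <- sqrt(1 / n1 + 1 / n0)
  data.frame(
    protein_id = rownames(mat),
    log_fc = m1 - m0,
    s2_g = s2,
    df_g = df,
    t_ordinary = (m1 - m0) / (sqrt(s2) * seFac),
    row.names = NULL
  )
}

asAbundanceMatrix <- function(mat) {
  if (is(mat, "SummarizedExperiment")) {
    mat <- SummarizedExperiment::assay(mat, "abundance")
  }
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (is.null(rownames(mat))) {
    rownames(mat) <- paste0("P", seq_len(nrow(mat)))
  }
  mat
}

#' Empirical-Bayes moderation of per-protein variances
#'
#' Shrinks each residual variance toward a shared prior estimated from all
#' proteins.  The prior degrees of freedom `d0` and prior variance `s0_sq`
#' are obtained by matching the first two moments of `log(s2_g)` to the
#' scaled-F sampling model (digamma/trigamma moment equations, with the
#' trigamma equation inverted by Newton iteration).  The moderated
#' variance is the degrees-of-freedom-weighted average
#' `s2_tilde = (d0*s0_sq + df*s2_g) / (d0 + df)`; when the observed
#' variances show no excess spread over pure sampling noise, `d0` is
#' capped at 1e6 and every `s2_tilde` collapses to `s0_sq`.
#'
#' @param s2 per-protein residual variances (length >= 10).
#' @param df shared residual degrees of freedom (scalar).
#' @return list with `d0`, `s0_sq`, `s2_tilde`.
#' @export
moderateVariances <- function(s2, df) {
  if (length(s2) < 10L) {
    stop("need at least 10 proteins to estimate the variance prior",
         call. = FALSE)
  }
  assertScalarNumber(df, "df", lower = 1)
  s2 <- pmax(s2, 1e-300)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e)
  excess <- evar - trigamma(df / 2)
  if (excess > 0) {
    d0 <- 2 * trigammaInverse(excess)
    if (!is.finite(d0) || d0 > 1e6) d0 <- 1e6
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread beyond sampling noise: infinite prior df limit,
    # where the prior variance is the plain mean of the observed variances
    d0 <- 1e6
    s0_sq <- mean(s2)
  }
  list(d0 = d0, s0_sq = s0_sq,
       s2_tilde = (d0 * s0_sq + df * s2) / (d0 + df))
}

# Newton inversion of trigamma (monotone decreasing, convex)
trigammaInverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in seq_len(50L)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Moderated t differential-abundance screen
#'
#' Runs [fitPerProtein()] and [moderateVariances()] and reports the
#' moderated t-statistic `log_fc / sqrt(s2_tilde * (1/n1 + 1/n2))` against
#' a t reference with `d0 + df_g` degrees of freedom, together with raw
#' and Benjamini-Hochberg adjusted p-values and volcano-plot coordinates.
#'
#' @inheritParams fitPerProtein
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @return `data.frame` with per-protein `log_fc`, `s2_g`, `df_g`, `d0`,
#'   `s0_sq`, `s2_tilde`, `t_moderated`, `p_value`, `p_adjusted`,
#'   `neg_log10_p_adjusted`.
#' @export
moderatedTTest <- function(mat, group, adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  mat <- asAbundanceMatrix(mat)
  group <- as.integer(as.logical(group))
  fits <- fitPerProtein(mat, group)
  mod <- moderateVariances(fits$s2_g, fits$df_g[1])
  n1 <- sum(group == 1L)
  n0 <- sum(group == 0L)
  seFac <- sqrt(1 / n1 + 1 / n0)
  tMod <- fits$log_fc / sqrt(mod$s2_tilde * seFac^2)
  dfTotal <- min(mod$d0 + fits$df_g[1], 1e6)
  p <- 2 * pt(-abs(tMod), df = dfTotal)
  padj <- bhAdjust(p, method = adjust)
  cbind(fits,
        d0 = mod$d0, s0_sq = mod$s0_sq, s2_tilde = mod$s2_tilde,
        t_moderated = tMod, p_value = p, p_adjusted = padj,
        neg_log10_p_adjusted = -log10(pmax(padj, 1e-300)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1), with
#' input validation.
#'
#' @param p p-values in `[0, 1]`.
#' @param method `"BH"` or `"bonferroni"`.
#' @return adjusted p-values, same order as the input.
#' @export
bhAdjust <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = method)
}

#' Prepare a protein matrix: missingness filter and mean imputation
#'
#' Drops proteins with more than `maxMissing` missing values (fraction)
#' and mean-imputes the remainder per protein, reporting the dropped
#' count via a message.
#'
#' @param mat proteins x participants matrix.
#' @param maxMissing maximum tolerated missing fraction per protein
#'   (default 0.2).
#' @return the filtered, imputed matrix.
#' @export
prepareProteinMatrix <- function(mat, maxMissing = 0.2) {
  mat <- asAbundanceMatrix(mat)
  frac <- rowMeans(is.na(mat))
  drop <- frac > maxMissing
  if (any(drop)) {
    message(sum(drop), " proteins dropped for >",
            round(100 * maxMissing), "% missing values")
    mat <- mat[!drop, , drop = FALSE]
  }
  if (anyNA(mat)) {
    rm <- rowMeans(mat, na.rm = TRUE)
    idx <- which(is.na(mat), arr.ind = TRUE)
    mat[idx] <- rm[idx[, 1]]
  }
  mat
}

#' Intersect differentially abundant protein sets from two contrasts
#'
#' A protein is a DEP under a contrast when its adjusted p-value is below
#' `alpha`; the common set is the intersection across the two contrasts
#' (as visualized by a Venn diagram).
#'
#' @param resultsA,resultsB `data.frame`s from [moderatedTTest()] over the
#'   same protein universe.
#' @param alpha adjusted-p cutoff, default 0.05.
#' @return list with `deps_a`, `deps_b`, `common` (character id vectors).
#' @export
intersectDEPs <- function(resultsA, resultsB, alpha = 0.05) {
  if (!setequal(resultsA$protein_id, resultsB$protein_id)) {
    stop("contrasts cover different protein universes", call. = FALSE)
  }
  depsA <- resultsA$protein_id[resultsA$p_adjusted < alpha]
  depsB <- resultsB$protein_id[resultsB$p_adjusted < alpha]
  list(deps_a = depsA, deps_b = depsB, common = intersect(depsA, depsB))
}
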