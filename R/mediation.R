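#' Causal mediation of a binary exposure through one protein
#'
#' Estimates how much of the exposure's effect on a binary outcome is
#' transmitted through one mediator protein.  The mediator model is a
#' linear regression of the protein on exposure plus covariates; the
#' outcome model is a logistic regression of the outcome on exposure,
#' mediator and covariates.  Effects are computed by the
#' counterfactual / g-computation recipe on the outcome-probability
#' scale: for every participant, predicted outcome probabilities under
#' the four combinations of exposure level x and mediator regime x' are
#' averaged, giving
#' `p(x, x') = mean_i plogis(eta_i(x, mhat_i(x')))`.  ACME is the
#' mediator contrast averaged over the two exposure arms, ADE the
#' exposure contrast averaged over the two mediator regimes, and
#' `total = p(1,1) - p(0,0) = ACME + ADE` exactly.
#'
#' Uncertainty comes from a nonparametric bootstrap (participants
#' resampled with replacement): percentile 95% intervals and a two-sided
#' percentile p-value `2 * min(frac <= 0, frac >= 0)` floored at
#' `1/n_boot`.
#'
#' @param exposure binary 0/1 vector (low-RA indicator).
#' @param mediator numeric protein abundances.
#' @param outcome binary 0/1 vector (MASLD).
#' @param covariates optional numeric matrix / data.frame of adjustment
#'   covariates.
#' @param nBoot bootstrap resamples, >= 200 (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return one-row `data.frame`: `acme`, `ade`, `total`, `prop_mediated`
#'   (`acme / total`, evaluated at point estimates and not clamped),
#'   `acme_p`, percentile bounds `acme_lo`/`acme_hi`, `ade_lo`/`ade_hi`,
#'   `total_lo`/`total_hi`, `n_boot`, `seed`, `reliable` (FALSE when the
#'   outcome model showed signs of separation).
#' @export
mediate <- function(exposure, mediator, outcome, covariates = NULL,
                    nBoot = 1000, seed = 1) {
  nBoot <- assertCount(nBoot, "nBoot", min = 200L)
  X <- as.numeric(exposure)
  M <- as.numeric(mediator)
  Y <- as.numeric(outcome)
  n <- length(X)
  if (length(M) != n || length(Y) != n) {
    stop("exposure, mediator and outcome must be aligned", call. = FALSE)
  }
  if (anyNA(X) || anyNA(M) || anyNA(Y)) {
    stop("mediation inputs must not contain missing values", call. = FALSE)
  }
  if (var(M) == 0) stop("constant mediator (zero variance)", call. = FALSE)
  C <- if (is.null(covariates)) {
    matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    as.matrix(covariates)
  }
  est <- medPointEstimate(X, M, Y, C)
  set.seed(seed)
  boot <- matrix(NA_real_, nrow = nBoot, ncol = 3L)
  for (b in seq_len(nBoot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot[b, ] <- medPointEstimate(X[idx], M[idx], Y[idx],
                                  C[idx, , drop = FALSE])$effects
  }
  ci <- apply(boot, 2L, quantile, probs = c(0.025, 0.975), names = FALSE)
  acmeBoot <- boot[, 1L]
  p <- 2 * min(mean(acmeBoot <= 0), mean(acmeBoot >= 0))
  p <- min(max(p, 1 / nBoot), 1)
  eff <- est$effects
  data.frame(
    acme = eff[1L], ade = eff[2L], total = eff[3L],
    prop_mediated = eff[1L] / eff[3L],
    acme_p = p,
    acme_lo = ci[1L, 1L], acme_hi = ci[2L, 1L],
    ade_lo = ci[1L, 2L], ade_hi = ci[2L, 2L],
    total_lo = ci[1L, 3L], total_hi = ci[2L, 3L],
    n_boot = nBoot, seed = seed, reliable = est$reliable
  )
}

# point estimates by plug-in g-computation; returns effects = (acme, ade,
# total) and a reliability flag for the outcome model
medPointEstimate <- function(X, M, Y, C) {
  n <- length(X)
  Zm <- cbind(1, X, C)
  am <- .lm.fit(Zm, M)$coefficients
  Zy <- cbind(1, X, M, C)
  fit <- suppressWarnings(
    stats::glm.fit(Zy, Y, family = binomial(),
                   control = glm.control(epsilon = 1e-8, maxit = 100))
  )
  by <- fit$coefficients
  mu <- fit$fitted.values
  reliable <- fit$converged && !(any(mu > 1 - 1e-8) | any(mu < 1e-8))
  covPartM <- if (ncol(C)) drop(C %*% am[-(1:2)]) else 0
  covPartY <- if (ncol(C)) drop(C %*% by[-(1:3)]) else 0
  mhat <- function(x) am[1L] + am[2L] * x + covPartM
  pxy <- function(x, xprime) {
    mean(plogis(by[1L] + by[2L] * x + by[3L] * mhat(xprime) + covPartY))
  }
  p00 <- pxy(0, 0); p01 <- pxy(0, 1)
  p10 <- pxy(1, 0); p11 <- pxy(1, 1)
  acme <- 0.5 * ((p01 - p00) + (p11 - p10))
  ade <- 0.5 * ((p10 - p00) + (p11 - p01))
  list(effects = c(acme, ade, p11 - p00), reliable = reliable)
}

#' Mediation screen over a set of candidate proteins
#'
#' Runs [mediate()] for every listed protein with a per-protein seed
#' derived deterministically from `seed` and the protein's position, then
#' applies the two screening filters via [screenMediators()].
#'
#' @param mat proteins x participants abundance matrix (or
#'   `SummarizedExperiment`).
#' @param proteinIds candidate protein ids (rows of `mat`).
#' @inheritParams mediate
#' @param acmeAlpha ACME p-value cutoff (default 0.05).
#' @param propCutoff minimum proportion mediated (default 0.10).
#' @return list with `estimates` (one row per protein) and `passing`
#'   (ids meeting both filters).
#' @export
mediationScreen <- function(mat, proteinIds, exposure, outcome,
                            covariates = NULL, nBoot = 1000, seed = 1,
                            acmeAlpha = 0.05, propCutoff = 0.10) {
  mat <- asAbundanceMatrix(mat)
  missing <- setdiff(proteinIds, rownames(mat))
  if (length(missing)) {
    stop("proteins not in matrix: ", paste(head(missing), collapse = ", "),
         call. = FALSE)
  }
  estimates <- do.call(rbind, lapply(seq_along(proteinIds), function(j) {
    cbind(protein_id = proteinIds[j],
          mediate(exposure, mat[proteinIds[j], ], outcome, covariates,
                  nBoot = nBoot, seed = streamSeed(seed, 100L + j)))
  }))
  rownames(estimates) <- NULL
  scr <- screenMediators(estimates, acmeAlpha = acmeAlpha,
                         propCutoff = propCutoff)
  list(estimates = estimates, passing = scr)
}

#' Apply the mediation screening filters
#'
#' A protein passes when its ACME bootstrap p-value is below `acmeAlpha`
#' and its point-estimate proportion mediated exceeds `propCutoff`.
#'
#' @param estimates `data.frame` of per-protein mediation estimates with
#'   columns `protein_id`, `acme_p`, `prop_mediated`.
#' @inheritParams mediationScreen
#' @return character vector of passing protein ids.
#' @export
screenMediators <- function(estimates, acmeAlpha = 0.05,
                            propCutoff = 0.10) {
  estimates$protein_id[
    estimates$acme_p < acmeAlpha & estimates$prop_mediated > propCutoff
  ]
}
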