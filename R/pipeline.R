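#' Run the full analysis pipeline on a (synthetic) cohort
#'
#' Orchestrates every stage: cohort generation (or a supplied
#' [SyntheticCohort-class]); relative-amplitude metrics and low-RA
#' grouping; phenotype derivation and covariate imputation; the crude and
#' adjusted logistic-model ladder for the RA-MASLD association; moderated-t
#' differential-abundance screens against both the low-RA group and the
#' MASLD outcome with their intersection; the per-protein mediation screen
#' (ACME p < `acme_alpha`, proportion mediated > `prop_cutoff`); LASSO
#' panel construction with the incremental-AUC parsimony rule; and
#' four-classifier evaluation on a stratified held-out split.  A manifest
#' records the participant/protein counts after every filter.
#'
#' @param config either a [synthConfig()] or a list with components
#'   `synth` (a `synthConfig`) or `cohort` (a `SyntheticCohort`), plus
#'   optional threshold overrides `dep_alpha` (0.05), `acme_alpha`
#'   (0.05), `prop_cutoff` (0.10), `parsimony_tol` (0.01),
#'   `sd_multiplier` (2), `train_fraction` (0.7), `cv_folds` (10),
#'   `n_boot` (500) and `seed`.
#' @param outDir optional directory; when given, stage outputs are
#'   written as CSV/JSON.
#' @return a list with `cohort`, `ra`, `grouping`, `ladder`,
#'   `de_ra`, `de_masld`, `deps`, `mediation`, `lasso`, `ranking`,
#'   `auc_curve`, `panel`, `models`, `manifest`; on an empty
#'   intermediate set the list carries `stopped_at` and `message`
#'   instead of the later stages.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (inherits(config, "synthConfig")) config <- list(synth = config)
  thr <- function(nm, default) if (is.null(config[[nm]])) default else config[[nm]]
  depAlpha <- thr("dep_alpha", 0.05)
  acmeAlpha <- thr("acme_alpha", 0.05)
  propCutoff <- thr("prop_cutoff", 0.10)
  parsTol <- thr("parsimony_tol", 0.01)
  sdMult <- thr("sd_multiplier", 2)
  trainFrac <- thr("train_fraction", 0.7)
  cvFolds <- thr("cv_folds", 10)
  nBoot <- thr("n_boot", 500)

  cohort <- if (!is.null(config$cohort)) {
    config$cohort
  } else {
    generateCohort(config$synth)
  }
  seed <- thr("seed", if (!is.null(config$synth)) config$synth$seed else 1L)
  manifest <- list(seed = seed,
                   n_participants = nrow(participants(cohort)),
                   n_proteins = nrow(proteome(cohort)))

  ra <- raMetrics(cohort)
  grouping <- classifyLowRA(ra$ra, sdMultiplier = sdMult)
  pheno <- participants(cohort)
  pheno$ra <- ra$ra
  pheno$low_ra <- grouping$low
  pheno <- derivePhenotypes(pheno)
  pheno <- imputeCovariates(pheno)
  manifest$n_low_ra <- sum(pheno$low_ra)
  manifest$n_masld <- sum(pheno$masld)

  ladder <- modelLadder(pheno)

  abundance <- prepareProteinMatrix(proteome(cohort))
  deRA <- moderatedTTest(abundance, pheno$low_ra)
  deMASLD <- moderatedTTest(abundance, pheno$masld)
  deps <- intersectDEPs(deRA, deMASLD, alpha = depAlpha)
  manifest$n_deps_ra <- length(deps$deps_a)
  manifest$n_deps_masld <- length(deps$deps_b)
  manifest$n_deps_common <- length(deps$common)

  out <- list(cohort = cohort, ra = ra, grouping = grouping,
              phenotyped = pheno, ladder = ladder,
              de_ra = deRA, de_masld = deMASLD, deps = deps,
              manifest = manifest)
  if (!length(deps$common)) {
    out$stopped_at <- "mediation"
    out$message <- "no common differentially abundant proteins at this alpha"
    return(finishPipeline(out, outDir))
  }

  covMat <- mediationCovariates(pheno)
  med <- mediationScreen(abundance, deps$common,
                         exposure = as.numeric(pheno$low_ra),
                         outcome = pheno$masld, covariates = covMat,
                         nBoot = nBoot, seed = seed,
                         acmeAlpha = acmeAlpha, propCutoff = propCutoff)
  out$mediation <- med
  out$manifest$n_mediation_pass <- length(med$passing)
  if (length(med$passing) < 2L) {
    out$stopped_at <- "panel"
    out$message <- "fewer than 2 proteins passed the mediation screen"
    return(finishPipeline(out, outDir))
  }

  features <- t(abundance[med$passing, , drop = FALSE])
  lasso <- lassoLogisticCV(features, pheno$masld, nFolds = cvFolds,
                           seed = seed)
  ranking <- rankProteins(lasso)
  out$lasso <- lasso
  out$manifest$n_lasso_nonzero <- length(ranking)
  if (!length(ranking)) {
    out$stopped_at <- "panel"
    out$message <- "LASSO selected no proteins"
    return(finishPipeline(out, outDir))
  }

  split <- splitStratified(pheno$masld, trainFraction = trainFrac,
                           seed = seed)
  curve <- incrementalAUC(features, pheno$masld, ranking,
                          split$train, split$test)
  sel <- selectParsimonious(curve, tolerance = parsTol)
  out$auc_curve <- curve
  out$panel <- sel
  out$ranking <- ranking
  out$manifest$k_star <- sel$k_star

  models <- trainClassifiers(features[, sel$panel, drop = FALSE],
                             pheno$masld, split, seed = seed)
  out$models <- models
  out$split <- split
  out$manifest$auc <- vapply(models, panelAUC, numeric(1))
  finishPipeline(out, outDir)
}

mediationCovariates <- function(pheno) {
  d <- refactorCovariates(pheno)
  mm <- model.matrix(~ age + sex + education + ethnicity + tdi +
                       fasting_glucose_mgdl + drinking + smoking, d)
  mm[, -1L, drop = FALSE]
}

finishPipeline <- function(out, outDir) {
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(out$ra, file.path(outDir, "ra_metrics.csv"),
              row.names = FALSE)
    write.csv(out$ladder, file.path(outDir, "model_ladder.csv"),
              row.names = FALSE)
    write.csv(out$de_ra, file.path(outDir, "de_ra.csv"), row.names = FALSE)
    write.csv(out$de_masld, file.path(outDir, "de_masld.csv"),
              row.names = FALSE)
    if (!is.null(out$mediation)) {
      write.csv(out$mediation$estimates,
                file.path(outDir, "mediation.csv"), row.names = FALSE)
    }
    if (!is.null(out$auc_curve)) {
      write.csv(out$auc_curve, file.path(outDir, "auc_curve.csv"),
                row.names = FALSE)
    }
    jsonlite::write_json(out$manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Predict MASLD risk for new protein measurements
#'
#' Applies a fitted [PanelModel-class] to new participants: panel
#' proteins are extracted by name, standardized with the stored training
#' parameters, and passed through the stored classifier's probability
#' output.  Proteins outside the panel are ignored with a warning;
#' missing panel proteins are an error listing the absent ids.
#'
#' @param model a `PanelModel`.
#' @param newdata named numeric vector (one participant) or a
#'   matrix/data.frame with proteins as named columns.
#' @return numeric vector of outcome probabilities in `[0, 1]`.
#' @export
predictRisk <- function(model, newdata) {
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1L,
                      dimnames = list(NULL, names(newdata)))
  }
  newdata <- as.matrix(newdata)
  absent <- setdiff(model@panelIds, colnames(newdata))
  if (length(absent)) {
    stop("missing panel proteins: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(colnames(newdata), model@panelIds)
  if (length(extra)) {
    warning("ignoring proteins outside the panel: ",
            paste(head(extra), collapse = ", "))
  }
  xs <- scale(newdata[, model@panelIds, drop = FALSE],
              center = model@center[model@panelIds],
              scale = model@scale[model@panelIds])
  unname(predictProbability(model@classifierName, model@fit, xs))
}
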