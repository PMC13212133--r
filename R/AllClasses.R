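#' SyntheticCohort: container for a generated study cohort
#'
#' Holds the three linked components of a simulated accelerometry +
#' proteomics cohort: a participant table (covariates, labs, sleep items and
#' the binary MASLD outcome), a matrix of 24-hour activity profiles (one row
#' per participant, columns `hour_0` .. `hour_23`), and a proteome stored as
#' a [SummarizedExperiment::SummarizedExperiment] with proteins as rows and
#' participants as columns.  The `truth` slot records every planted
#' parameter (per-protein exposure effects `a`, outcome effects `b`, the
#' direct effect, the latent low-amplitude group) so downstream estimates
#' can be compared against ground truth.
#'
#' @slot participants `data.frame` keyed by `participant_id`.
#' @slot profiles numeric matrix, participants x 24 hours, row names are
#'   participant ids.
#' @slot proteome a `SummarizedExperiment` (assay `"abundance"`).
#' @slot truth named `list` of planted generation parameters.
#'
#' @aliases SyntheticCohort-class
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
  representation(
    participants = "data.frame",
    profiles = "matrix",
    proteome = "ANY",
    truth = "list"
  )
)

setValidity("SyntheticCohort", function(object) {
  msgs <- character()
  ids <- object@participants$participant_id
  if (is.null(ids)) {
    msgs <- c(msgs, "participants must have a 'participant_id' column")
  } else {
    if (anyDuplicated(ids)) msgs <- c(msgs, "duplicated participant ids")
    if (!identical(as.character(ids), rownames(object@profiles))) {
      msgs <- c(msgs, "profile rows must match participant ids in order")
    }
    if (!identical(as.character(ids), colnames(object@proteome))) {
      msgs <- c(msgs, "proteome columns must match participant ids in order")
    }
  }
  if (ncol(object@profiles) != 24L) {
    msgs <- c(msgs, "profiles must have 24 hourly columns")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SyntheticCohort participant table accessor
#' @param object,x a `SyntheticCohort`
#' @export
setGeneric("participants", function(object) standardGeneric("participants"))

#' @rdname SyntheticCohort-class
#' @export
setMethod("participants", "SyntheticCohort", function(object) {
  object@participants
})

#' @describeIn SyntheticCohort activity-profile matrix accessor
#' @export
setGeneric("activityProfiles", function(object) {
  standardGeneric("activityProfiles")
})

#' @rdname SyntheticCohort-class
#' @export
setMethod("activityProfiles", "SyntheticCohort", function(object) {
  object@profiles
})

#' @describeIn SyntheticCohort proteome accessor (a `SummarizedExperiment`)
#' @export
setGeneric("proteome", function(object) standardGeneric("proteome"))

#' @rdname SyntheticCohort-class
#' @export
setMethod("proteome", "SyntheticCohort", function(object) object@proteome)

#' @describeIn SyntheticCohort planted-truth accessor
#' @export
setGeneric("cohortTruth", function(object) standardGeneric("cohortTruth"))

#' @rdname SyntheticCohort-class
#' @export
setMethod("cohortTruth", "SyntheticCohort", function(object) object@truth)

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort with", nrow(object@participants), "participants\n")
  cat("  proteome:", nrow(object@proteome), "proteins (",
      length(object@truth$mediator_ids), "planted mediators )\n")
  cat("  MASLD prevalence:",
      sprintf("%.3f", mean(object@participants$masld)), "\n")
})

#' @rdname SyntheticCohort-class
#' @export
setMethod("dim", "SyntheticCohort", function(x) {
  c(nrow(x@participants), nrow(x@proteome))
})

#' PanelModel: a fitted protein risk panel
#'
#' A selected protein panel together with a fitted classifier satisfying a
#' fit/predict-probability contract, the feature standardization learned on
#' the training split, and the held-out ROC curve and AUC.
#'
#' @slot panelIds character, ordered selected protein ids.
#' @slot classifierName one of `"logistic"`, `"random-forest"`,
#'   `"gradient-boosted-trees"`, `"support-vector"`.
#' @slot fit the underlying fitted object (opaque).
#' @slot center,scale named numeric, training-split standardization.
#' @slot roc `data.frame` with `threshold`, `fpr`, `tpr`.
#' @slot auc held-out area under the ROC curve.
#' @slot splitSeed integer seed of the stratified split.
#'
#' @aliases PanelModel-class
#' @exportClass PanelModel
setClass("PanelModel",
  representation(
    panelIds = "character",
    classifierName = "character",
    fit = "ANY",
    center = "numeric",
    scale = "numeric",
    roc = "data.frame",
    auc = "numeric",
    splitSeed = "integer"
  )
)

setValidity("PanelModel", function(object) {
  msgs <- character()
  if (!object@classifierName %in%
      c("logistic", "random-forest", "gradient-boosted-trees",
        "support-vector")) {
    msgs <- c(msgs, "unknown classifier name")
  }
  if (length(object@auc) == 1L && (object@auc < 0 || object@auc > 1)) {
    msgs <- c(msgs, "auc must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "PanelModel", function(object) {
  cat("PanelModel (", object@classifierName, ") with ",
      length(object@panelIds), " proteins; held-out AUC = ",
      sprintf("%.3f", object@auc), "\n", sep = "")
})

#' @describeIn PanelModel held-out AUC accessor
#' @param object a `PanelModel`
#' @export
setGeneric("panelAUC", function(object) standardGeneric("panelAUC"))

#' @rdname PanelModel-class
#' @export
setMethod("panelAUC", "PanelModel", function(object) object@auc)

#' @describeIn PanelModel selected protein ids
#' @export
setGeneric("panelProteins", function(object) standardGeneric("panelProteins"))

#' @rdname PanelModel-class
#' @export
setMethod("panelProteins", "PanelModel", function(object) object@panelIds)
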