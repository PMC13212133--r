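#' Stratified train/test split
#'
#' Splits participants into train and test sets preserving the outcome
#' prevalence: within each class, `floor(fraction * n_class)` or its
#' ceiling go to training, with ceilings assigned to the classes with the
#' largest fractional remainders so the overall training fraction is as
#' close as possible to the target.
#'
#' @param outcome binary vector; both classes must have >= 2 members.
#' @param trainFraction in (0, 1), default 0.7.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
splitStratified <- function(outcome, trainFraction = 0.7, seed = 1) {
  if (trainFraction <= 0 || trainFraction >= 1) {
    stop("'trainFraction' must be in (0, 1)", call. = FALSE)
  }
  y <- as.integer(as.logical(outcome))
  n <- length(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L || any(table(y) < 2L)) {
    stop("cannot stratify: each class needs at least 2 members",
         call. = FALSE)
  }
  sizes <- vapply(classes, function(cl) sum(y == cl), integer(1))
  exact <- trainFraction * sizes
  take <- floor(exact)
  deficit <- round(trainFraction * n) - sum(take)
  if (deficit > 0) {
    ord <- order(exact - take, decreasing = TRUE)
    take[ord[seq_len(deficit)]] <- take[ord[seq_len(deficit)]] + 1L
  }
  set.seed(seed)
  train <- unlist(lapply(seq_along(classes), function(k) {
    idx <- which(y == classes[k])
    sample(idx, take[k])
  }))
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' ROC curve and AUC with midrank tie handling
#'
#' The AUC is the Mann-Whitney U statistic scaled to `[0, 1]` (midranks
#' for ties): the probability that a random positive scores above a
#' random negative, counting ties as 1/2.  The curve thresholds at every
#' distinct score (ties advance diagonally), so its trapezoidal area
#' equals the rank AUC exactly.
#'
#' @param scores numeric risk scores.
#' @param labels binary vector, both classes present.
#' @return list with `curve` (`data.frame`: `threshold`, `fpr`, `tpr`)
#'   and `auc`.
#' @examples
#' rocAuc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))$auc # 0.75
#' @export
rocAuc <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  nPos <- sum(y == 1L)
  nNeg <- sum(y == 0L)
  if (nPos == 0L || nNeg == 0L) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores) # midranks
  auc <- (sum(r[y == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  ord <- order(scores, decreasing = TRUE)
  uniq <- !duplicated(scores[ord])
  tp <- cumsum(y[ord] == 1L)
  fp <- cumsum(y[ord] == 0L)
  last <- c(which(uniq)[-1L] - 1L, length(scores)) # end of each tie group
  curve <- data.frame(
    threshold = c(Inf, scores[ord][uniq]),
    fpr = c(0, fp[last] / nNeg),
    tpr = c(0, tp[last] / nPos)
  )
  list(curve = curve, auc = auc)
}

trapezoidArea <- function(fpr, tpr) {
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

#' L1-penalized logistic regression with stratified cross-validation
#'
#' Features are standardized internally (training means and SDs stored);
#' the penalized deviance is minimized over a 100-point log-spaced lambda
#' grid running four decades down from `lambda_max` (the smallest lambda
#' that zeroes every coefficient).  The regularization parameter is
#' chosen at the minimum mean cross-validated binomial deviance over
#' outcome-stratified folds.
#'
#' @param features participants x proteins numeric matrix with column
#'   names.
#' @param outcome binary vector.
#' @param nFolds folds (default 10); every fold needs >= 5 participants.
#' @param seed integer seed controlling fold assignment.
#' @return list of class `"lassoFit"`: `lambda_grid`, `cv_error`,
#'   `cv_sd`, `lambda_star`, `coefficients_std` (standardized scale,
#'   incl. intercept), `coefficients_raw`, `nonzero_ids`, `folds`,
#'   `center`, `scale`, `seed`, `glmnet_fit`.
#' @export
lassoLogisticCV <- function(features, outcome, nFolds = 10, seed = 1) {
  x <- as.matrix(features)
  y <- as.integer(as.logical(outcome))
  if (nrow(x) / nFolds < 5) {
    stop("need at least 5 participants per cross-validation fold",
         call. = FALSE)
  }
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    warning("dropping constant features: ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  ctr <- colMeans(x)
  xs <- scale(x, center = ctr, scale = sds)
  n <- nrow(xs)
  lambdaMax <- max(abs(crossprod(xs, y - mean(y)))) / n
  grid <- exp(seq(log(lambdaMax), log(lambdaMax * 1e-4), length.out = 100))
  foldid <- stratifiedFolds(y, nFolds, seed)
  cvfit <- glmnet::cv.glmnet(xs, y, family = "binomial", lambda = grid,
                             standardize = FALSE, foldid = foldid,
                             type.measure = "deviance")
  beta <- as.matrix(coef(cvfit, s = "lambda.min"))
  coefStd <- setNames(drop(beta), rownames(beta))
  nz <- names(coefStd)[-1L][coefStd[-1L] != 0]
  coefRaw <- coefStd
  coefRaw[-1L] <- coefStd[-1L] / sds
  coefRaw[1L] <- coefStd[1L] - sum(coefStd[-1L] * ctr / sds)
  structure(list(
    lambda_grid = grid,
    cv_error = cvfit$cvm,
    cv_sd = cvfit$cvsd,
    lambda_star = cvfit$lambda.min,
    coefficients_std = coefStd,
    coefficients_raw = coefRaw,
    nonzero_ids = nz,
    folds = foldid,
    center = ctr,
    scale = sds,
    seed = seed,
    glmnet_fit = cvfit
  ), class = "lassoFit")
}

stratifiedFolds <- function(y, nFolds, seed) {
  set.seed(seed)
  foldid <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    foldid[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  foldid
}

#' Rank proteins by penalized-coefficient magnitude
#'
#' Nonzero proteins ordered by decreasing absolute standardized
#' coefficient at the selected lambda; ties broken by protein id.
#'
#' @param fit a `"lassoFit"` from [lassoLogisticCV()].
#' @return character vector of ordered protein ids.
#' @export
rankProteins <- function(fit) {
  coefs <- fit$coefficients_std[-1L]
  coefs <- coefs[coefs != 0]
  if (!length(coefs)) {
    warning("no nonzero coefficients at the selected lambda")
    return(character(0))
  }
  names(coefs)[order(-abs(coefs), names(coefs))]
}

#' Validation AUC as a function of panel size
#'
#' For each k, fits an unpenalized logistic model on the top-k ranked
#' proteins using the training split and evaluates its AUC on the
#' held-out validation split.  Separation at small k is tolerated: the
#' scores are still ranked, and the affected k is flagged.
#'
#' @param features participants x proteins matrix.
#' @param outcome binary vector.
#' @param ranking ordered protein ids from [rankProteins()].
#' @param trainIdx,testIdx disjoint index vectors.
#' @return `data.frame` with `k`, `protein_added`, `auc`, `separable`.
#' @export
incrementalAUC <- function(features, outcome, ranking, trainIdx, testIdx) {
  if (!length(ranking)) stop("empty ranking", call. = FALSE)
  if (length(intersect(trainIdx, testIdx))) {
    stop("train and validation sets must be disjoint", call. = FALSE)
  }
  x <- as.matrix(features)
  y <- as.integer(as.logical(outcome))
  res <- lapply(seq_along(ranking), function(k) {
    cols <- ranking[seq_len(k)]
    Ztr <- cbind(1, x[trainIdx, cols, drop = FALSE])
    fit <- suppressWarnings(
      stats::glm.fit(Ztr, y[trainIdx], family = binomial(),
                     control = glm.control(epsilon = 1e-8, maxit = 100))
    )
    mu <- fit$fitted.values
    sep <- !fit$converged || any(mu > 1 - 1e-8) || any(mu < 1e-8)
    scores <- drop(cbind(1, x[testIdx, cols, drop = FALSE]) %*%
                     fit$coefficients)
    data.frame(k = k, protein_added = ranking[k],
               auc = rocAuc(scores, y[testIdx])$auc, separable = sep)
  })
  do.call(rbind, res)
}

#' Parsimonious panel size by the incremental-AUC rule
#'
#' Chooses the smallest panel whose validation AUC is within `tolerance`
#' of the best AUC over all panel sizes.
#'
#' @param curve `data.frame` from [incrementalAUC()] (columns `k`,
#'   `auc`) with the ranking in `protein_added`, or any data.frame with
#'   those columns.
#' @param tolerance allowed AUC deficit, default 0.01.
#' @return list with `k_star` and `panel` (the first `k_star` ranked
#'   proteins, when available).
#' @export
selectParsimonious <- function(curve, tolerance = 0.01) {
  if (!nrow(curve)) stop("empty AUC curve", call. = FALSE)
  cutoff <- max(curve$auc) - tolerance
  kStar <- curve$k[which(curve$auc >= cutoff)[1L]]
  panel <- if (!is.null(curve$protein_added)) {
    as.character(curve$protein_added[curve$k <= kStar])
  } else {
    character(0)
  }
  list(k_star = kStar, panel = panel)
}

#' Train and evaluate panel classifiers on a stratified split
#'
#' Fits up to four classifiers on the training split of the selected
#' panel and evaluates ROC/AUC on the held-out split.  All methods
#' satisfy a fit / predict-probability contract: logistic regression via
#' [fitLogistic()]; random forest ([randomForest::randomForest]);
#' gradient-boosted trees ([xgboost::xgboost]); and a radial-kernel
#' support-vector machine ([e1071::svm]) with Platt-style sigmoid
#' probability calibration fitted on training folds
#' (`probability = TRUE`).  Features are standardized with training-split
#' parameters, which are stored in the returned models.
#'
#' @param features participants x proteins matrix.
#' @param outcome binary vector.
#' @param split list with `train` and `test` from [splitStratified()].
#' @param methods subset of `c("logistic", "random-forest",
#'   "gradient-boosted-trees", "support-vector")`.
#' @param seed integer seed for the stochastic learners.
#' @return named list of [PanelModel-class] objects.
#' @export
trainClassifiers <- function(features, outcome, split,
                             methods = c("logistic", "random-forest",
                                         "gradient-boosted-trees",
                                         "support-vector"),
                             seed = 1) {
  known <- c("logistic", "random-forest", "gradient-boosted-trees",
             "support-vector")
  bad <- setdiff(methods, known)
  if (length(bad)) {
    stop("unknown method(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(features)
  y <- as.integer(as.logical(outcome))
  tr <- split$train
  te <- split$test
  ctr <- colMeans(x[tr, , drop = FALSE])
  sds <- apply(x[tr, , drop = FALSE], 2L, sd)
  sds[sds == 0] <- 1
  xs <- scale(x, center = ctr, scale = sds)
  models <- lapply(methods, function(m) {
    set.seed(streamSeed(seed, match(m, known)))
    fitted <- switch(m,
      "logistic" = {
        df <- data.frame(y = y[tr], xs[tr, , drop = FALSE])
        fitLogistic(y ~ ., df)
      },
      "random-forest" = randomForest::randomForest(
        xs[tr, , drop = FALSE], factor(y[tr], levels = c(0, 1))
      ),
      "gradient-boosted-trees" = xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3,
                      eta = 0.1, nthread = 1),
        data = xgboost::xgb.DMatrix(xs[tr, , drop = FALSE],
                                    label = y[tr], nthread = 1),
        nrounds = 100, verbose = 0
      ),
      "support-vector" = e1071::svm(
        xs[tr, , drop = FALSE], factor(y[tr], levels = c(0, 1)),
        kernel = "radial", probability = TRUE
      )
    )
    scores <- predictProbability(m, fitted, xs[te, , drop = FALSE])
    roc <- rocAuc(scores, y[te])
    new("PanelModel", panelIds = colnames(x), classifierName = m,
        fit = fitted, center = ctr, scale = sds, roc = roc$curve,
        auc = roc$auc, splitSeed = as.integer(seed))
  })
  names(models) <- methods
  models
}

predictProbability <- function(method, fitted, xs) {
  switch(method,
    "logistic" = {
      df <- as.data.frame(xs)
      drop(plogis(cbind(1, as.matrix(df[, names(coef(fitted$fit))[-1L],
                                        drop = FALSE])) %*%
                    fitted$coefficients))
    },
    "random-forest" = predict(fitted, xs, type = "prob")[, "1"],
    "gradient-boosted-trees" = predict(
      fitted, xgboost::xgb.DMatrix(xs, nthread = 1)
    ),
    "support-vector" = {
      pr <- predict(fitted, xs, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    }
  )
}
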