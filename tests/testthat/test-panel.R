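test_that("stratified split hits the exact per-class arithmetic", {
  y <- rep(c(1, 0), c(30, 70))
  sp <- splitStratified(y, 0.7, seed = 1)
  expect_equal(sum(y[sp$train]), 21)
  expect_equal(sum(y[sp$train] == 0), 49)
  expect_equal(sort(c(sp$train, sp$test)), 1:100)

  sp2 <- splitStratified(c(1, 1, 0, 0), 0.5, seed = 2)
  expect_equal(sum(sp2$train %in% 1:2), 1)
  expect_equal(sum(sp2$train %in% 3:4), 1)

  # prevalence property across random class balances
  set.seed(3)
  for (i in 1:20) {
    y <- rbinom(150, 1, runif(1, 0.2, 0.8))
    if (sum(y) < 2 || sum(1 - y) < 2) next
    sp <- splitStratified(y, 0.7, seed = i)
    expect_lte(abs(mean(y[sp$train]) - mean(y[sp$test])),
               1 / min(sum(y), sum(1 - y)) + 1e-12)
  }
  expect_error(splitStratified(c(1, 0, 0, 0), 0.5), "at least 2")
  expect_error(splitStratified(y, 1.2), "in \\(0, 1\\)")
})

test_that("rank AUC equals pair enumeration, trapezoid and symmetries", {
  r <- rocAuc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
  expect_equal(r$auc, 3 / 4) # 3 of 4 positive-negative pairs ordered

  expect_equal(rocAuc(c(5, 6, 1, 2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(rocAuc(rep(2, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)

  set.seed(41)
  for (i in 1:30) {
    s <- sample(round(rnorm(40), 1)) # ties on purpose
    y <- rbinom(40, 1, 0.4)
    if (sum(y) == 0 || sum(y) == 40) next
    r <- rocAuc(s, y)
    # trapezoidal area under the tie-aware curve equals the rank AUC
    expect_equal(circMASLD:::trapezoidArea(r$curve$fpr, r$curve$tpr),
                 r$auc, tolerance = 1e-12)
    # invariance under strictly increasing transforms
    expect_equal(rocAuc(exp(s / 2), y)$auc, r$auc)
    # reversing scores complements the AUC exactly
    expect_equal(rocAuc(-s, y)$auc + r$auc, 1)
    expect_equal(r$curve$fpr[1], 0)
    expect_equal(r$curve$tpr[nrow(r$curve)], 1)
    expect_true(all(diff(r$curve$fpr) >= 0) && all(diff(r$curve$tpr) >= 0))
  }
  expect_error(rocAuc(1:3, c(1, 1, 1)), "both classes")
})

test_that("lasso path shrinks fully at lambda_max and relaxes to the MLE", {
  set.seed(42)
  n <- 600
  x <- matrix(rnorm(n * 3), ncol = 3,
              dimnames = list(NULL, c("A", "B", "C")))
  y <- rbinom(n, 1, plogis(0.8 * x[, 1] - 0.6 * x[, 2]))
  fit <- lassoLogisticCV(x, y, nFolds = 5, seed = 1)
  # at the top of the grid every protein coefficient is zero
  top <- as.matrix(coef(fit$glmnet_fit$glmnet.fit,
                        s = fit$lambda_grid[1]))[-1, ]
  expect_true(all(top == 0))
  expect_true(fit$lambda_star %in% fit$lambda_grid)
  expect_setequal(fit$nonzero_ids,
                  names(which(fit$coefficients_std[-1] != 0)))
  # glmnet deviance explained is monotone as the penalty relaxes
  expect_true(all(diff(fit$glmnet_fit$glmnet.fit$dev.ratio) >= -1e-8))

  # near-zero penalty reproduces the unpenalized fit on standardized x
  xs <- scale(x)
  small <- as.matrix(coef(fit$glmnet_fit$glmnet.fit,
                          s = min(fit$lambda_grid), exact = TRUE,
                          x = xs, y = y))
  ref <- glm(y ~ xs, family = binomial())
  expect_equal(drop(small), unname(coef(ref)), tolerance = 1e-3,
               ignore_attr = TRUE)

  # constant feature dropped with a warning
  xc <- cbind(x, D = 1)
  expect_warning(fit2 <- lassoLogisticCV(xc, y, nFolds = 5, seed = 1),
                 "constant")
  expect_false("D" %in% names(fit2$coefficients_std))
})

test_that("protein ranking orders by |standardized coefficient|", {
  fit <- structure(list(coefficients_std = c("(Intercept)" = 0.2,
                                             A = -0.9, B = 0.5, C = 0.1,
                                             D = 0)),
                   class = "lassoFit")
  expect_equal(rankProteins(fit), c("A", "B", "C"))
  fit$coefficients_std <- c("(Intercept)" = 0, B = 0.5, A = -0.5)
  expect_equal(rankProteins(fit), c("A", "B")) # tie -> lexicographic
  fit$coefficients_std <- c("(Intercept)" = 0, A = 0, B = 0)
  expect_warning(r <- rankProteins(fit), "no nonzero")
  expect_equal(r, character(0))
})

test_that("ranking is invariant to feature column order", {
  set.seed(43)
  n <- 400
  x <- matrix(rnorm(n * 6), ncol = 6,
              dimnames = list(NULL, paste0("P", 1:6)))
  y <- rbinom(n, 1, plogis(x %*% c(1, -0.8, 0.5, 0, 0, 0)))
  r1 <- rankProteins(lassoLogisticCV(x, y, nFolds = 5, seed = 9))
  perm <- sample(6)
  r2 <- rankProteins(lassoLogisticCV(x[, perm], y, nFolds = 5, seed = 9))
  expect_equal(r1, r2)
})

test_that("incremental AUC curve behaves at its limits", {
  set.seed(44)
  n <- 300
  x <- matrix(rnorm(n * 4), ncol = 4,
              dimnames = list(NULL, paste0("P", 1:4)))
  y <- rbinom(n, 1, plogis(1.2 * x[, 1] + 0.6 * x[, 2]))
  sp <- splitStratified(y, 0.7, seed = 4)
  curve <- incrementalAUC(x, y, paste0("P", 1:4), sp$train, sp$test)
  expect_equal(nrow(curve), 4)
  expect_true(all(curve$auc >= 0 & curve$auc <= 1))

  # k = full set equals the all-protein model's AUC by construction
  full <- incrementalAUC(x, y, paste0("P", 1:4), sp$train, sp$test)
  expect_equal(curve$auc[4], full$auc[4])

  # a perfectly separating first protein gives AUC 1 at k = 1
  xsep <- cbind(P1 = ifelse(y == 1, 1, -1) * (1 + runif(n)), x[, 2:4])
  csep <- suppressWarnings(
    incrementalAUC(xsep, y, colnames(xsep), sp$train, sp$test)
  )
  expect_equal(csep$auc[1], 1)

  # pure noise fluctuates around 0.5
  ynull <- rbinom(n, 1, 0.5)
  cnull <- incrementalAUC(x, ynull, paste0("P", 1:4), sp$train, sp$test)
  expect_true(all(abs(cnull$auc - 0.5) < 0.2))

  expect_error(incrementalAUC(x, y, character(0), sp$train, sp$test),
               "empty ranking")
  expect_error(incrementalAUC(x, y, "P1", 1:10, 5:20), "disjoint")
})

test_that("the parsimony rule picks the smallest near-best panel", {
  curve <- data.frame(k = 1:6,
                      auc = c(0.70, 0.80, 0.93, 0.935, 0.936, 0.9365),
                      protein_added = paste0("P", 1:6))
  sel <- selectParsimonious(curve, tolerance = 0.01)
  expect_equal(sel$k_star, 3)
  expect_equal(sel$panel, c("P1", "P2", "P3"))

  expect_equal(selectParsimonious(curve, tolerance = 0)$k_star, 6)
  dec <- data.frame(k = 1:3, auc = c(0.9, 0.85, 0.8),
                    protein_added = paste0("P", 1:3))
  expect_equal(selectParsimonious(dec)$k_star, 1)
})

test_that("all four classifiers separate separable data", {
  set.seed(45)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * 3), ncol = 3,
              dimnames = list(NULL, paste0("P", 1:3)))
  x[, 1] <- x[, 1] + 6 * y
  sp <- splitStratified(y, 0.7, seed = 5)
  models <- suppressWarnings(trainClassifiers(x, y, sp, seed = 5))
  expect_named(models, c("logistic", "random-forest",
                         "gradient-boosted-trees", "support-vector"))
  for (m in models) expect_gte(panelAUC(m), 0.99)
  expect_error(trainClassifiers(x, y, sp, methods = "nearest-centroid"),
               "unknown method")
})

test_that("label shuffling drives every classifier to chance", {
  set.seed(46)
  aucs <- replicate(20, {
    n <- 120
    x <- matrix(rnorm(n * 4), ncol = 4,
                dimnames = list(NULL, paste0("P", 1:4)))
    y <- sample(rep(c(0, 1), each = n / 2))
    sp <- splitStratified(y, 0.7, seed = sample.int(1e6, 1))
    vapply(suppressWarnings(
      trainClassifiers(x, y, sp, seed = sample.int(1e6, 1))
    ), panelAUC, numeric(1))
  })
  expect_true(all(rowMeans(aucs) > 0.4 & rowMeans(aucs) < 0.6))
})

test_that("the logistic panel model agrees with the incremental curve", {
  set.seed(47)
  n <- 400
  x <- matrix(rnorm(n * 3), ncol = 3,
              dimnames = list(NULL, paste0("P", 1:3)))
  y <- rbinom(n, 1, plogis(0.9 * x[, 1] - 0.5 * x[, 2]))
  sp <- splitStratified(y, 0.7, seed = 6)
  curve <- incrementalAUC(x, y, paste0("P", 1:3), sp$train, sp$test)
  kStar <- selectParsimonious(curve)$k_star
  panel <- paste0("P", seq_len(kStar))
  mod <- trainClassifiers(x[, panel, drop = FALSE], y, sp,
                          methods = "logistic", seed = 6)$logistic
  expect_equal(panelAUC(mod), curve$auc[kStar], tolerance = 1e-10)
})

test_that("risk prediction round-trips the stored model", {
  set.seed(48)
  n <- 300
  x <- matrix(rnorm(n * 2), ncol = 2,
              dimnames = list(NULL, c("PA", "PB")))
  y <- rbinom(n, 1, plogis(x[, 1]))
  sp <- splitStratified(y, 0.7, seed = 7)
  mod <- trainClassifiers(x, y, sp, methods = "logistic", seed = 7)$logistic

  # batch prediction over the held-out split reproduces the stored AUC
  pr <- predictRisk(mod, x[sp$test, ])
  expect_equal(rocAuc(pr, y[sp$test])$auc, panelAUC(mod))

  # inputs equal to the training means give plogis(intercept)
  atMean <- predictRisk(mod, setNames(mod@center, c("PA", "PB")))
  expect_equal(atMean, plogis(mod@fit$coefficients[["(Intercept)"]]),
               tolerance = 1e-12)

  expect_error(predictRisk(mod, c(PA = 1)), "missing panel proteins")
  expect_warning(predictRisk(mod, c(PA = 1, PB = 0, PZ = 3)), "ignoring")
})

test_that("rank AUC agrees with the established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(49)
  for (i in 1:10) {
    s <- round(rnorm(60), 1)
    y <- rbinom(60, 1, 0.4)
    if (sum(y) == 0 || sum(y) == 60) next
    ref <- suppressMessages(pROC::auc(pROC::roc(y, s, direction = "<")))
    expect_equal(rocAuc(s, y)$auc, as.numeric(ref), tolerance = 1e-12)
  }
})
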