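test_that("2x2 odds ratio, correction and invariances behave", {
  bal <- oddsRatio2x2(10, 10, 10, 10)
  expect_equal(bal$or_, 1)
  expect_equal(log(bal$ci_low), -log(bal$ci_high)) # symmetric on log scale

  # zero cell: result equals hand computation on the +0.5 table
  z <- oddsRatio2x2(0, 10, 5, 20)
  or_hand <- (0.5 * 20.5) / (10.5 * 5.5)
  se_hand <- sqrt(1 / 0.5 + 1 / 10.5 + 1 / 5.5 + 1 / 20.5)
  expect_equal(z$or_, or_hand)
  expect_equal(z$ci_high, exp(log(or_hand) + 1.96 * se_hand))

  # multiplying all cells by a positive integer leaves the OR unchanged
  a <- oddsRatio2x2(12, 7, 30, 44)
  b <- oddsRatio2x2(12 * 5, 7 * 5, 30 * 5, 44 * 5)
  expect_equal(a$or_, b$or_)

  expect_error(oddsRatio2x2(0, 0, 5, 5), "row or column")
  expect_error(oddsRatio2x2(-1, 2, 3, 4), "nonnegative")
})

test_that("logistic fit matches closed forms and the 2x2 oracle", {
  # intercept-only, 25% positives
  d <- data.frame(y = rep(c(1, 0), c(25, 75)))
  f <- fitLogistic(y ~ 1, d)
  expect_equal(unname(f$coefficients), log(0.25 / 0.75), tolerance = 1e-8)

  # single binary predictor: exp(coefficient) equals the 2x2 odds ratio
  d2 <- data.frame(
    y = rep(c(1, 0, 1, 0), c(40, 60, 25, 90)),
    x = rep(c(1, 1, 0, 0), c(40, 60, 25, 90))
  )
  f2 <- fitLogistic(y ~ x, d2)
  or <- oddsRatio2x2(40, 60, 25, 90)
  expect_equal(exp(f2$coefficients[["x"]]), or$or_, tolerance = 1e-6)
  expect_equal(logisticOR(f2, "x")$ci_low, or$ci_low, tolerance = 1e-4)

  expect_error(fitLogistic(y ~ x, data.frame(y = c(1, 0, NA), x = 1:3)),
               "missing")
})

test_that("IRLS deviance never increases across iterations", {
  set.seed(31)
  d <- data.frame(x1 = rnorm(200), x2 = rnorm(200))
  d$y <- rbinom(200, 1, plogis(0.5 * d$x1 - d$x2))
  trace <- capture.output(
    glm(y ~ x1 + x2, data = d, family = binomial(),
        control = glm.control(trace = TRUE))
  )
  dev <- as.numeric(sub(".*Deviance = ([0-9.eE+-]+) Iterations.*", "\\1",
                        trace[grepl("Deviance = ", trace, fixed = TRUE)]))
  expect_true(length(dev) >= 2)
  expect_true(all(diff(dev) <= 1e-8))
})

test_that("null logistic p-values are approximately uniform", {
  set.seed(77)
  ps <- replicate(200, {
    d <- data.frame(x = rnorm(80))
    d$y <- rbinom(80, 1, 0.4)
    f <- fitLogistic(y ~ x, d)
    2 * pnorm(-abs(f$coefficients[["x"]] / f$standard_errors[["x"]]))
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
})

test_that("perfect separation is flagged", {
  d <- data.frame(x = c(-2, -1.5, -1, 1, 1.5, 2),
                  y = c(0, 0, 0, 1, 1, 1))
  expect_warning(f <- fitLogistic(y ~ x, d), "separation")
  expect_false(f$converged)
})

test_that("baseline table reproduces printed percent arithmetic", {
  # expand a two-group cohort from marginal counts
  d <- data.frame(
    grp = rep(c("high", "low"), c(8, 5)),
    sex = c(rep(c("male", "female"), c(3, 5)),
            rep(c("male", "female"), c(3, 2)))
  )
  tab <- baselineTable(d, "grp", "sex")
  expect_equal(tab[tab$level == "male", "low"], "3 (60.0)")
  expect_equal(tab[tab$level == "male", "high"], "3 (37.5)")
  expect_equal(unique(tab$test), "chi-square")

  # hand-sized 2x3 chi-square equals the textbook formula
  d2 <- data.frame(g = rep(c("a", "b"), c(30, 30)),
                   v = c(rep(c("x", "y", "z"), c(10, 12, 8)),
                         rep(c("x", "y", "z"), c(15, 5, 10))))
  t2 <- baselineTable(d2, "g", "v")
  obs <- table(d2$v, d2$g)
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  expect_equal(t2$statistic[1], sum((obs - expd)^2 / expd))

  # identical groups: ANOVA F = 0, p = 1
  d3 <- data.frame(g = rep(c("a", "b"), each = 10), v = rep(rnorm(10), 2))
  t3 <- baselineTable(d3, "g", "v")
  expect_equal(t3$statistic, 0, tolerance = 1e-10)
  expect_equal(t3$p_value, 1, tolerance = 1e-10)

  expect_error(baselineTable(data.frame(g = factor("a", levels = c("a", "b")),
                                        v = 1), "g", "v"),
               "empty group")
})

test_that("covariate imputation uses medians, modes and audit flags", {
  d <- data.frame(bmi = c(20, 22, 30, NA),
                  edu = c("b", "a", "b", "a"),
                  stringsAsFactors = FALSE)
  out <- imputeCovariates(d)
  expect_equal(out$bmi[4], 22)
  expect_equal(out$bmi_imputed, c(FALSE, FALSE, FALSE, TRUE))

  # mode tie: lexicographically smallest category wins
  d2 <- data.frame(edu = c("b", "a", NA), stringsAsFactors = FALSE)
  expect_equal(imputeCovariates(d2)$edu[3], "a")

  # no missing values: identity
  d3 <- data.frame(x = 1:3)
  expect_identical(imputeCovariates(d3), d3)

  expect_error(imputeCovariates(data.frame(x = c(NA_real_, NA_real_))),
               "cannot impute")
})

test_that("model ladder recovers the 2x2 OR and adjusts for confounding", {
  # crude model on an expanded 2x2 cohort equals the closed-form OR
  counts <- c(a = 120, b = 250, c = 380, d = 900)
  d <- data.frame(
    masld = rep(c(1, 0, 1, 0), counts),
    low_ra = rep(c(TRUE, TRUE, FALSE, FALSE), counts)
  )
  f <- fitLogistic(masld ~ low_ra, d)
  expect_equal(exp(f$coefficients[["low_raTRUE"]]),
               oddsRatio2x2(120, 250, 380, 900)$or_, tolerance = 1e-6)

  # planted confounder: adjusted OR closer to the direct effect than crude
  set.seed(55)
  n <- 4000
  z <- rnorm(n)
  low_ra <- runif(n) < plogis(-2 + 1.5 * z)
  direct <- 0.5
  masld <- rbinom(n, 1, plogis(-1 + direct * low_ra + 1.2 * z))
  pd <- makeParticipants(n)
  pd$low_ra <- low_ra
  pd$masld <- masld
  pd$age <- 56 + 8 * z # confounder enters through age
  lad <- modelLadder(pd)
  crude <- log(lad$or_[lad$model == "crude"])
  adj <- log(lad$or_[lad$model == "adjusted1"])
  expect_lt(abs(adj - direct), abs(crude - direct))
})
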