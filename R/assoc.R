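#' Odds ratio with Wald interval from a 2x2 table
#'
#' Cells follow the exposure x outcome layout: `a` = exposed with outcome,
#' `b` = exposed without, `c` = unexposed with outcome, `d` = unexposed
#' without.  If any cell is zero the Haldane-Anscombe correction adds 0.5
#' to every cell before computing `OR = (a*d)/(b*c)`,
#' `SE = sqrt(1/a + 1/b + 1/c + 1/d)` on the log scale, the 95% Wald
#' interval `exp(log(OR) +/- 1.96 SE)` and a two-sided Wald z p-value.
#'
#' @param a,b,c,d nonnegative counts.
#' @return `data.frame` with `or_`, `ci_low`, `ci_high`, `p_value`,
#'   `method`.
#' @examples
#' # low-RA MASLD vs high-RA as reference
#' oddsRatio2x2(a = 1633, b = 1387, c = 24390, d = 54020)
#' @export
oddsRatio2x2 <- function(a, b, c, d) {
  cells <- unname(c(a, b, c, d))
  if (any(cells < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0 ||
      sum(cells[c(1, 3)]) == 0 || sum(cells[c(2, 4)]) == 0) {
    stop("odds ratio undefined: a row or column of the table is empty",
         call. = FALSE)
  }
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- log(or) / se
  data.frame(
    or_ = or,
    ci_low = exp(log(or) - 1.96 * se),
    ci_high = exp(log(or) + 1.96 * se),
    p_value = 2 * pnorm(-abs(z)),
    method = "wald"
  )
}

#' Maximum-likelihood logistic regression
#'
#' Binomial GLM with logit link fitted by iteratively reweighted least
#' squares (convergence when the relative deviance change drops below
#' 1e-8, at most 100 iterations), with Wald standard errors from the
#' inverse observed information.  Perfect separation is flagged (fitted
#' probabilities collapsing to 0/1 together with exploding standard
#' errors) and reported via `converged = FALSE` plus a warning;
#' rank-deficient designs raise an error naming the aliased columns.
#'
#' @param formula model formula.
#' @param data `data.frame`; the response must be 0/1 or logical, no
#'   missing values among model variables.
#' @return a list of class `"logisticFit"`: `coefficients`,
#'   `standard_errors`, `covariance`, `converged`, `n_obs`,
#'   `log_likelihood`, `deviance`, `fit` (the underlying `glm`).
#' @export
fitLogistic <- function(formula, data) {
  vars <- all.vars(formula)
  if (!all(complete.cases(data[, intersect(vars, names(data)), drop = FALSE]))) {
    stop("model variables contain missing values; impute first",
         call. = FALSE)
  }
  # muffle glm.fit's raw 0/1-probability warning; separation is re-reported
  # below with a clearer message
  fit <- withCallingHandlers(
    glm(formula, data = data, family = binomial(),
        control = glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  if (anyNA(coef(fit))) {
    stop("rank-deficient design; aliased columns: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  se <- sqrt(diag(vcov(fit)))
  mu <- fit$fitted.values
  separated <- !fit$converged ||
    (any(mu > 1 - 1e-8) || any(mu < 1e-8)) && any(se > 50)
  if (separated) {
    warning("possible perfect separation: estimates unreliable")
  }
  structure(list(
    coefficients = coef(fit),
    standard_errors = se,
    covariance = vcov(fit),
    converged = fit$converged && !separated,
    n_obs = length(fit$y),
    log_likelihood = as.numeric(stats::logLik(fit)),
    deviance = fit$deviance,
    fit = fit
  ), class = "logisticFit")
}

#' Wald effect estimates from a logistic fit
#'
#' @param fit a `"logisticFit"`.
#' @param term coefficient name.
#' @return `data.frame` with the odds ratio, 95% Wald CI and p-value for
#'   `term`.
#' @export
logisticOR <- function(fit, term) {
  b <- fit$coefficients[[term]]
  se <- fit$standard_errors[[term]]
  data.frame(
    term = term, or_ = exp(b),
    ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
    p_value = 2 * pnorm(-abs(b / se)), method = "logistic"
  )
}

#' Nested covariate-adjustment ladder for the RA-MASLD association
#'
#' Fits four nested logistic models for MASLD on the low-RA indicator:
#' crude; + age and gender; + education, ethnicity and deprivation index;
#' + glucose, drinking and smoking status.  Categorical covariates are
#' dummy-coded against fixed reference levels (gender female, education
#' College, ethnicity White, smoking and drinking Never).
#'
#' @param data phenotyped cohort `data.frame` with columns `masld`,
#'   `low_ra`, `age`, `sex`, `education`, `ethnicity`, `tdi`,
#'   `fasting_glucose_mgdl`, `drinking`, `smoking`.
#' @return `data.frame`, one row per model, with the low-RA odds ratio,
#'   CI and p-value.
#' @export
modelLadder <- function(data) {
  data <- refactorCovariates(data)
  forms <- list(
    crude = masld ~ low_ra,
    adjusted1 = masld ~ low_ra + age + sex,
    adjusted2 = masld ~ low_ra + age + sex + education + ethnicity + tdi,
    adjusted3 = masld ~ low_ra + age + sex + education + ethnicity + tdi +
      fasting_glucose_mgdl + drinking + smoking
  )
  out <- do.call(rbind, lapply(names(forms), function(nm) {
    fit <- fitLogistic(forms[[nm]], data)
    cbind(model = nm, logisticOR(fit, "low_raTRUE"))
  }))
  rownames(out) <- NULL
  out
}

refactorCovariates <- function(data) {
  data$low_ra <- factor(as.logical(data$low_ra), levels = c(FALSE, TRUE))
  if (!is.null(data$sex)) data$sex <- stats::relevel(factor(data$sex), "female")
  for (nm in c("education", "ethnicity")) {
    if (!is.null(data[[nm]])) data[[nm]] <- factor(data[[nm]])
  }
  if (!is.null(data$education) && "College" %in% levels(data$education)) {
    data$education <- stats::relevel(data$education, "College")
  }
  if (!is.null(data$ethnicity) && "White" %in% levels(data$ethnicity)) {
    data$ethnicity <- stats::relevel(data$ethnicity, "White")
  }
  for (nm in c("smoking", "drinking")) {
    if (!is.null(data[[nm]])) {
      data[[nm]] <- factor(data[[nm]])
      if ("Never" %in% levels(data[[nm]])) {
        data[[nm]] <- stats::relevel(data[[nm]], "Never")
      }
    }
  }
  data
}

#' Baseline characteristics table with group tests
#'
#' Continuous variables are summarized as mean (SD) per group and compared
#' with one-way ANOVA; categorical variables as count (percent) per group
#' and compared with Pearson's chi-squared test without continuity
#' correction.
#'
#' @param data cohort `data.frame`.
#' @param group name of the grouping column (2 or more groups, all
#'   non-empty).
#' @param variables character vector of column names to summarize;
#'   numeric columns are treated as continuous, everything else as
#'   categorical.
#' @return `data.frame` with columns `variable`, `level`, one summary
#'   column per group, `statistic`, `p_value`, `test`.
#' @export
baselineTable <- function(data, group, variables) {
  g <- data[[group]]
  g <- if (is.factor(g)) g else factor(g)
  if (any(table(g) == 0)) stop("empty group in baseline table", call. = FALSE)
  rows <- lapply(variables, function(v) {
    x <- data[[v]]
    if (is.numeric(x) && !is.logical(x)) {
      sums <- vapply(split(x, g), function(xx) {
        sprintf("%.2f (%.2f)", mean(xx), sd(xx))
      }, character(1))
      fit <- aov(x ~ g)
      tab <- summary(fit)[[1]]
      out <- data.frame(variable = v, level = "",
                        t(sums), statistic = tab$`F value`[1],
                        p_value = tab$`Pr(>F)`[1], test = "anova",
                        check.names = FALSE)
    } else {
      tab <- table(factor(x), g)
      chi <- suppressWarnings(chisq.test(tab, correct = FALSE))
      pct <- sweep(tab, 2, colSums(tab), "/") * 100
      out <- do.call(rbind, lapply(rownames(tab), function(lv) {
        cells <- sprintf("%d (%.1f)", tab[lv, ], pct[lv, ])
        data.frame(variable = v, level = lv, t(cells),
                   statistic = unname(chi$statistic),
                   p_value = chi$p.value, test = "chi-square",
                   check.names = FALSE)
      }))
    }
    names(out)[3:(2 + nlevels(g))] <- levels(g)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median / mode imputation of covariates
#'
#' Continuous covariates are imputed with the median of observed values,
#' categorical ones with the mode (ties broken by the lexicographically
#' smallest category).  For every imputed covariate an audit indicator
#' column `<name>_imputed` is appended.
#'
#' @param data cohort `data.frame`.
#' @param covariates columns eligible for imputation (outcome and exposure
#'   columns must not be listed).
#' @return the completed `data.frame`.
#' @export
imputeCovariates <- function(data, covariates = names(data)) {
  for (v in covariates) {
    x <- data[[v]]
    miss <- is.na(x)
    if (!any(miss)) next
    if (all(miss)) {
      stop(sprintf("cannot impute '%s': all values missing", v),
           call. = FALSE)
    }
    if (is.numeric(x) && !is.logical(x)) {
      x[miss] <- median(x[!miss])
    } else {
      tab <- table(as.character(x[!miss]))
      modes <- names(tab)[tab == max(tab)]
      x[miss] <- sort(modes)[1L]
    }
    data[[v]] <- x
    data[[paste0(v, "_imputed")]] <- miss
  }
  data
}
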