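#' @keywords internal
"_PACKAGE"

#' @import methods
#' @importFrom stats rnorm runif rbinom rlnorm plogis qlogis sd var median
#'   glm binomial glm.control coef vcov predict lm pnorm pt qnorm phyper
#'   p.adjust aov chisq.test quantile setNames rchisq model.matrix as.formula
#'   anova complete.cases
#' @importFrom utils head read.csv read.delim write.csv modifyList
NULL

# Deterministic substream seeds derived from one root seed, so that adding
# draws to one component never perturbs another.  Kept below 2^31.
streamSeed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 2011L + 7919L * as.integer(stream) %% 97L +
    as.integer(stream)
}

withStream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(streamSeed(seed, stream))
  expr
}

assertScalarNumber <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (strict && x <= lower) {
    stop(sprintf("'%s' must be > %s", name, lower), call. = FALSE)
  }
  if (!strict && x < lower) {
    stop(sprintf("'%s' must be >= %s", name, lower), call. = FALSE)
  }
  invisible(x)
}

assertCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      x < min) {
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}
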