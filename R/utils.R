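#' @keywords internal
"_PACKAGE"

#' @importFrom stats glm binomial coef predict plogis qlogis rlogis rbinom
#'   rpois rbeta runif rnorm uniroot quantile sd qnorm pnorm wilcox.test
#'   setNames
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

utils::globalVariables(c("threshold", "value", "strategy", "panel"))

#' Evaluate code with a temporary RNG seed
#'
#' Sets the random seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so package functions are reproducible without
#' clobbering the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  code
}

# Derive a stream-specific child seed from a user seed; kept inside 32-bit
# integer range whatever the inputs.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(stream)) %% 2147483587)
}

stop_if_not_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must contain probabilities in [0, 1]", what),
         call. = FALSE)
  }
  invisible(x)
}

#' Confidence interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param level confidence level (default 0.95).
#' @param method `"wilson"` (score interval, default) or `"wald"` (normal
#'   approximation, as used in some clinical reports).
#' @return Numeric vector `c(lower, upper)`, clipped to \[0, 1\]; `NA` if
#'   `n == 0`.
#' @examples
#' prop_ci(18, 1348, method = "wald")
#' @export
prop_ci <- function(x, n, level = 0.95, method = c("wilson", "wald")) {
  method <- match.arg(method)
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  ci <- if (method == "wald") {
    se <- sqrt(p * (1 - p) / n)
    c(p - z * se, p + z * se)
  } else {
    den <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / den
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    c(centre - half, centre + half)
  }
  pmin(pmax(ci, 0), 1)
}

# Poisson-binomial pmf of the number of successes among independent
# Bernoulli(p_j) draws, by dynamic programming. Returns length(p)+1 vector
# for counts 0..length(p).
poisbinom_pmf <- function(p) {
  f <- 1
  for (pj in p) f <- c(f * (1 - pj), 0) + c(0, f * pj)
  f
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

clamp01 <- function(x) pmin(pmax(x, 0), 1)
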