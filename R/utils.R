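#' @importFrom methods new validObject is slot
#' @importFrom stats pnorm dnorm qnorm rnorm runif rbinom plogis pbinom
#'   wilcox.test setNames sd cor quantile
#' @importFrom utils head read.delim combn
NULL

# numerically stable log(exp(a) + exp(b)), elementwise
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  m + log1p(exp(pmin(a, b) - m))
}

# phi(x)/Phi(x) computed in log space; stable for x << 0
millsRatioInv <- function(x) {
  exp(dnorm(x, log = TRUE) - pnorm(x, log.p = TRUE))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# master-seed splitting: derive independent stream seeds below 2^31
# (double arithmetic: products stay well under 2^53)
deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(k) * 40014) %% 2147483563)
}
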