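#' Gamma-density smooth basis filters
#'
#' Builds the set of `K` lag filters used to represent spike response
#' functions. The `k`-th basis is the Gamma probability density with mean and
#' variance both equal to `k^2 / 2` bins (shape `k^2/2`, rate 1), evaluated at
#' integer lags `s = 1..M`. Small `k` gives a sharp short-latency filter,
#' large `k` a broad long-latency one, so a handful of bases spans fast and
#' slow postsynaptic responses while keeping the estimate smooth.
#'
#' @param K number of bases (`>= 1`); default `floor(sqrt(2 * M))`, the
#'   largest `K` whose mean lag `K^2/2` stays within the window.
#' @param M maximum lag in bins (`>= 1`).
#' @param integrate if `TRUE`, each value is the Gamma mass integrated over
#'   the bin `(s - 1/2, s + 1/2]` instead of the density at `s`.
#' @return object of class `basis_set`: `K`, `M`, `values` (`K x M`),
#'   `means`, `vars`, `kind = "gamma"`.
#' @examples
#' b <- make_gamma_basis(4, 16)
#' b$values[2, 1]  # Ga(1; shape 2, rate 1) = exp(-1)
#' @export
make_gamma_basis <- function(K = NULL, M, integrate = FALSE) {
  if (!is.numeric(M) || M < 1) stop("M must be a positive integer")
  if (is.null(K)) K <- floor(sqrt(2 * M))
  if (!is.numeric(K) || K < 1) stop("K must be a positive integer")
  K <- as.integer(K); M <- as.integer(M)
  s <- seq_len(M)
  vals <- matrix(0, K, M)
  means <- vars <- numeric(K)
  for (k in seq_len(K)) {
    shape <- k^2 / 2  # mean = variance = k^2/2 with rate 1
    means[k] <- shape; vars[k] <- shape
    vals[k, ] <- if (integrate) {
      pgamma(s + 0.5, shape = shape, rate = 1) -
        pgamma(s - 0.5, shape = shape, rate = 1)
    } else {
      dgamma(s, shape = shape, rate = 1)
    }
  }
  structure(list(K = K, M = M, values = vals, means = means, vars = vars,
                 kind = "gamma"), class = "basis_set")
}

#' Identity (raw-lag) basis
#'
#' One indicator basis per lag (`K = M`), i.e. the unsmoothed spike response
#' parameterization with one free coefficient per lag. Used by the classical
#' likelihood-ratio chi-square test, whose statistic is asymptotically
#' chi-square with `M` degrees of freedom under this parameterization.
#'
#' @param M maximum lag in bins.
#' @export
make_identity_basis <- function(M) {
  if (!is.numeric(M) || M < 1) stop("M must be a positive integer")
  M <- as.integer(M)
  structure(list(K = M, M = M, values = diag(M), means = as.numeric(seq_len(M)),
                 vars = rep(0, M), kind = "identity"), class = "basis_set")
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("<basis_set> %s, K=%d filters over lags 1..%d\n",
              x$kind, x$K, x$M))
  invisible(x)
}

#' Link functions mapping total spike response to spike probability
#'
#' `logistic`: `1 / (1 + exp(-x))`. `cloglog`: `1 - exp(-exp(x))`, which makes
#' the per-bin Bernoulli model approximate a Poisson spike process at small
#' bin width. Both saturate smoothly and are evaluated overflow-safely.
#'
#' @param x numeric vector of total responses.
#' @param kind `"logistic"` or `"cloglog"`.
#' @return probabilities in (0, 1).
#' @export
link_prob <- function(x, kind = c("logistic", "cloglog")) {
  kind <- match.arg(kind)
  x <- pmin(pmax(x, -700), 700)
  if (kind == "logistic") {
    1 / (1 + exp(-x))
  } else {
    -expm1(-exp(pmin(x, 700)))
  }
}

link_code <- function(kind) match(kind, c("logistic", "cloglog")) - 1L
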