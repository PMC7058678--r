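#' Empirical probability mass function on integers
#'
#' The basic distributional building block of the package: every estimated
#' quantity (daily emergency admission counts, ward lengths-of-stay) is held
#' as an empirical pmf on a finite, strictly increasing integer support.
#'
#' @param support Integer vector, strictly increasing.
#' @param prob Numeric vector of the same length; non-negative, summing to 1
#'   (within 1e-12).
#' @param n Sample size behind the estimate, or `NA` for exact/constructed
#'   distributions.
#' @return An object of class `empirical_pmf` with elements `support`,
#'   `prob`, `n`.
#' @export
empirical_pmf <- function(support, prob, n = NA_integer_) {
  support <- as.integer(support)
  prob <- as.numeric(prob)
  if (length(support) == 0L) stop("empirical_pmf: empty support")
  if (length(support) != length(prob))
    stop("empirical_pmf: support and prob lengths differ")
  if (any(diff(support) <= 0L))
    stop("empirical_pmf: support must be strictly increasing")
  if (any(prob < 0)) stop("empirical_pmf: negative probability")
  if (abs(sum(prob) - 1) > 1e-12)
    stop(sprintf("empirical_pmf: probabilities sum to %.15f, not 1", sum(prob)))
  structure(list(support = support, prob = prob, n = as.integer(n)),
            class = "empirical_pmf")
}

#' Empirical pmf from a sample of integers
#'
#' @param x Integer sample (length >= 1).
#' @return An `empirical_pmf` whose probabilities are the observed
#'   proportions and whose `n` is `length(x)`.
#' @export
pmf_from_samples <- function(x) {
  if (length(x) == 0L) stop("pmf_from_samples: empty sample")
  x <- as.integer(x)
  tab <- table(x)
  support <- as.integer(names(tab))
  prob <- as.numeric(tab) / length(x)
  # counts/length sums to 1 exactly up to fp; renormalise defensively
  empirical_pmf(support, prob / sum(prob), n = length(x))
}

#' Geometric length-of-stay pmf
#'
#' Truncated geometric distribution, the package's stock parametric choice
#' for ward length-of-stay in synthetic scenarios. With `start = 1` the
#' support is \{1, ..., max\} and P(T = k) is proportional to p(1-p)^(k-1)
#' (at least one midnight, as in the simulation model).
#'
#' @param p Success probability in (0, 1].
#' @param max Largest support value.
#' @param start Smallest support value (default 1).
#' @param renormalize If `TRUE` (default) the truncated probabilities are
#'   rescaled to sum to 1; if `FALSE` the raw geometric probabilities are
#'   kept, which is only valid when the truncated tail mass is below 1e-12.
#' @return An `empirical_pmf`.
#' @export
geometric_pmf <- function(p, max, start = 1L, renormalize = TRUE) {
  stopifnot(p > 0, p <= 1, max >= start)
  k <- seq.int(start, max)
  pr <- p * (1 - p)^(k - start)
  if (renormalize) pr <- pr / sum(pr)
  empirical_pmf(k, pr, n = NA_integer_)
}

#' Poisson daily-count pmf truncated to negligible tail mass
#'
#' @param lambda Mean daily count (>= 0).
#' @param tail Tail mass at which to truncate (default 1e-10).
#' @return An `empirical_pmf` over \{0, ..., qpois(1 - tail)\}.
#' @export
poisson_pmf <- function(lambda, tail = 1e-10) {
  stopifnot(lambda >= 0)
  if (lambda == 0) return(empirical_pmf(0L, 1))
  kmax <- stats::qpois(1 - tail, lambda)
  pr <- stats::dpois(0:kmax, lambda)
  empirical_pmf(0:kmax, pr / sum(pr))
}

#' Inverse-transform sample from an empirical pmf
#'
#' Maps uniform draws through the right-continuous generalized inverse of
#' the CDF: the result is the smallest support value x with CDF(x) > u.
#'
#' @param pmf An `empirical_pmf`.
#' @param u Numeric vector of uniform(0,1) draws.
#' @return Integer vector of support values, one per element of `u`.
#' @export
sample_pmf <- function(pmf, u) {
  stopifnot(inherits(pmf, "empirical_pmf"))
  cdf <- cumsum(pmf$prob)
  idx <- findInterval(u, cdf) + 1L   # count of cdf values <= u, then next
  idx[idx > length(cdf)] <- length(cdf)  # guard fp at u ~ 1
  pmf$support[idx]
}

#' @export
#' @rdname empirical_pmf
#' @param x,... Print method arguments.
print.empirical_pmf <- function(x, ...) {
  cat(sprintf("empirical pmf on {%d..%d} (%d atoms), mean %.3f",
              min(x$support), max(x$support), length(x$support), pmf_mean(x)))
  if (!is.na(x$n)) cat(sprintf(", n = %d", x$n))
  cat("\n")
  invisible(x)
}

#' Mean and variance of an empirical pmf
#' @param pmf An `empirical_pmf`.
#' @return A numeric scalar.
#' @export
pmf_mean <- function(pmf) sum(pmf$support * pmf$prob)

#' @rdname pmf_mean
#' @export
pmf_var <- function(pmf) sum(pmf$support^2 * pmf$prob) - pmf_mean(pmf)^2

# CDF evaluated at integer t with the F(-1) = 0 style convention:
# P(X <= t) for any t (not just support points).
pmf_cdf <- function(pmf, t) {
  cdf <- cumsum(pmf$prob)
  i <- findInterval(t, pmf$support)
  out <- numeric(length(t))
  out[i > 0] <- cdf[i[i > 0]]
  out
}
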