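## Length-proportional binomial enrichment test, computed entirely in
## log-space so that counts in the millions never overflow.

# log(k!) for k = 0..63, exact by cumulative summation
.LOGFACT_SMALL <- c(0, cumsum(log(seq_len(63))))

#' Log-factorial via a Stirling series with exact small-argument fallback
#'
#' Computes \eqn{\log n!}. For \eqn{n < 64} the value is an exact cumulative
#' sum of logs; above that the Stirling series
#' \deqn{\log n! \approx n\log n - n + \tfrac12\log(2\pi n) + \frac{1}{12n}
#'   - \frac{1}{360 n^3} + \frac{1}{1260 n^5}}
#' is used, whose truncation error at \eqn{n \ge 64} is below
#' \eqn{10^{-12}} absolute. Vectorised over \code{n}.
#'
#' @param n Non-negative integer(s).
#' @return \code{log(n!)} as a numeric vector.
#' @examples
#' logFactorial(5) # log(120)
#' @export
logFactorial <- function(n) {
    if (any(n < 0) || any(n != floor(n)))
        stop("'n' must contain non-negative integers")
    out <- numeric(length(n))
    small <- n < 64
    out[small] <- .LOGFACT_SMALL[n[small] + 1L]
    if (any(!small)) {
        x <- n[!small]
        out[!small] <- x * log(x) - x + 0.5 * log(2 * pi * x) +
            1 / (12 * x) - 1 / (360 * x^3) + 1 / (1260 * x^5)
    }
    out
}

#' Log binomial probability mass
#'
#' \eqn{\log \Pr(X = k) = \log\binom{n}{k} + k\log p + (n-k)\log(1-p)} with
#' the binomial coefficient evaluated through \code{\link{logFactorial}}.
#' The limits \eqn{p = 0} and \eqn{p = 1} are handled as point masses at
#' \eqn{k = 0} and \eqn{k = n}.
#'
#' @param n Number of trials (total mutations in the tested universe).
#' @param k Number of successes (mutations in the region); vectorised.
#' @param p Success probability, the region's length fraction \eqn{l/L}.
#' @return Log-probabilities, one per element of \code{k}.
#' @export
logBinomialPmf <- function(n, k, p) {
    if (length(n) != 1L || length(p) != 1L)
        stop("'n' and 'p' must be scalars")
    if (any(k < 0) || any(k > n))
        stop("'k' must lie in [0, n]")
    if (p < 0 || p > 1)
        stop("'p' must lie in [0, 1]")
    if (p == 0) return(ifelse(k == 0, 0, -Inf))
    if (p == 1) return(ifelse(k == n, 0, -Inf))
    if (length(k) > 1L && all(diff(k) == 1)) {
        # contiguous k: telescope from the first term,
        # pmf(j+1)/pmf(j) = (n-j)/(j+1) * p/(1-p); avoids re-deriving
        # large log-factorial differences at every j
        base <- .logPmfScalar(n, k[1], p)
        j <- k[-length(k)]
        inc <- log(n - j) - log(j + 1) + log(p) - log1p(-p)
        return(base + c(0, cumsum(inc)))
    }
    vapply(k, .logPmfScalar, numeric(1), n = n, p = p)
}

# log C(n,k): the falling-factorial ratio n!/(n-k)! is accumulated as an
# exact log-sum (no cancellation between O(n log n) Stirling terms), with
# the remaining k! from logFactorial
.logChoose <- function(n, k) {
    kk <- min(k, n - k)
    if (kk == 0) return(0)
    if (kk <= 1e6)
        sum(log(seq(n - kk + 1, n))) - logFactorial(kk)
    else
        logFactorial(n) - logFactorial(k) - logFactorial(n - k)
}

.logPmfScalar <- function(n, k, p) {
    .logChoose(n, k) + k * log(p) + (n - k) * log1p(-p)
}

# numerically stable log(sum(exp(x)))
.logSumExp <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
}

#' Lower-tail binomial probability P(X < k)
#'
#' The strictly-less tail \eqn{P(X < k) = \sum_{j=0}^{k-1} \Pr(X = j)},
#' accumulated in log-space. By convention \code{k = 0} gives 0 (empty sum)
#' and \code{k = n + 1} gives 1 (total mass).
#'
#' @inheritParams logBinomialPmf
#' @param k Upper limit (exclusive) of the summation, in \code{0..n+1}.
#' @return A probability.
#' @export
lowerTail <- function(n, k, p) {
    if (k < 0 || k > n + 1) stop("'k' must lie in [0, n + 1]")
    if (k == 0) return(0)
    if (k == n + 1) return(1)
    exp(.logSumExp(logBinomialPmf(n, seq.int(0L, k - 1L), p)))
}

#' Upper-tail binomial probability P(X >= k)
#'
#' Computed by direct log-sum-exp over \eqn{j = k, \dots, j_{max}} rather
#' than as \code{1 - lowerTail(...)}: in the deep upper tail — the regime
#' where candidate regions live — the complement loses all precision. The
#' summation is truncated at \eqn{j_{max} = \max(k, np) + 60\,\mathrm{sd}},
#' beyond which terms are below \eqn{e^{-40}} of the largest retained term.
#' When \eqn{k \le np} the mass is dominated by the bulk and the complement
#' of the lower tail is both accurate and cheaper, so it is used there.
#'
#' @inheritParams logBinomialPmf
#' @return A probability.
#' @export
upperTail <- function(n, k, p) {
    if (k < 0 || k > n + 1) stop("'k' must lie in [0, n + 1]")
    if (k == 0) return(1)
    if (k == n + 1) return(0)
    if (p == 0) return(if (k <= 0) 1 else 0)
    if (p == 1) return(1)  # k <= n here
    mu <- n * p
    if (k <= mu) return(min(1, max(0, 1 - lowerTail(n, k, p))))
    sd <- sqrt(max(n * p * (1 - p), 1))
    jmax <- min(n, ceiling(k + 60 * sd + 60))
    exp(.logSumExp(logBinomialPmf(n, seq.int(k, jmax), p)))
}

#' Bonferroni-corrected per-test level
#'
#' For a family of \code{m} hypotheses tested at family-wise level
#' \code{alpha}, each hypothesis is evaluated at \code{alpha / m}.
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param m Number of hypotheses in the family (>= 1).
#' @return \code{alpha / m}.
#' @examples
#' bonferroniLevel(0.05, 37 * 30)
#' @export
bonferroniLevel <- function(alpha, m) {
    if (any(m < 1)) stop("'m' must be >= 1")
    if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
    alpha / m
}

#' Test regions for mutation counts exceeding the binomial background
#'
#' Under a uniform-mutation null, a region of length \code{l} inside a
#' universe of total length \code{L} receives each of \code{n} mutations
#' independently with probability \eqn{p = l/L}. A region is a candidate
#' when its upper-tail probability \eqn{P(X \ge k)} falls below the
#' Bonferroni-corrected level \eqn{\alpha/m}.
#'
#' Vectorised over regions: \code{regionId}, \code{l} and \code{k} may be
#' parallel vectors sharing scalar \code{L}, \code{n}, \code{m}, \code{alpha}.
#'
#' @param regionId Region labels (domain or gene identifiers).
#' @param l Region lengths, residues.
#' @param L Total universe length, residues.
#' @param n Total mutations in the tested universe.
#' @param k Mutation counts per region.
#' @param m Bonferroni family size.
#' @param alpha Family-wise level, default 0.05.
#' @return A \code{data.frame} with columns \code{region_id}, \code{l},
#'   \code{L}, \code{n}, \code{k}, \code{p}, \code{p_upper}, \code{m},
#'   \code{alpha}, \code{candidate}.
#' @examples
#' testRegion("dom1", l = 100, L = 1e5, n = 5000, k = 50, m = 100)
#' @export
testRegion <- function(regionId, l, L, n, k, m, alpha = 0.05) {
    if (any(l <= 0) || any(l > L)) stop("require 0 < l <= L")
    if (any(k < 0) || any(k > n)) stop("require 0 <= k <= n")
    if (any(m < 1)) stop("'m' must be >= 1")
    nr <- length(regionId)
    stopifnot(length(l) == nr, length(k) == nr)
    p <- l / L
    pUpper <- vapply(seq_len(nr),
                     function(i) upperTail(n, k[i], p[i]),
                     numeric(1))
    thr <- bonferroniLevel(alpha, m)
    data.frame(region_id = as.character(regionId),
               l = l, L = L, n = n, k = k, p = p,
               p_upper = pUpper, m = m, alpha = alpha,
               candidate = pUpper < thr,
               stringsAsFactors = FALSE)
}
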