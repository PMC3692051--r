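# The minimum-hypergeometric (mHG) statistical engine. Given a binary label
# vector over a ranked list, the mHG score is the best hypergeometric tail
# over all top/rest partitions; its multiplicity over cutoffs is corrected
# by an exact p-value computed with a lattice dynamic program.

.stirling_lfact <- function(n) {
  # Stirling's series for log n!, with a downward shift so the series is
  # only evaluated at arguments >= 10 (keeps truncation error ~1e-8).
  stir <- function(x)
    x * log(x) - x + 0.5 * log(2 * pi * x) +
      1 / (12 * x) - 1 / (360 * x^3) + 1 / (1260 * x^5)
  small <- numeric(10L)  # log k! for k = 0..9 via lf(k) = lf(k+1) - log(k+1)
  acc <- stir(10)
  for (k in 9:0) {
    small[k + 1L] <- acc - log(k + 1)
    acc <- small[k + 1L]
  }
  out <- numeric(length(n))
  big <- n >= 10
  out[big] <- stir(n[big])
  out[!big] <- small[n[!big] + 1L]
  out
}

#' Table of log binomial coefficients
#'
#' Returns `log(choose(N, k))` for `k = 0..N`, either from exact cumulative
#' log-factorials or from Stirling's series. The two modes agree to within
#' a relative tolerance of 1e-6 on the log scale for N up to 10000.
#'
#' @param N Non-negative integer.
#' @param mode `"exact"` (cumulative log-factorials) or `"stirling"`.
#' @return Numeric vector of length `N + 1`.
#' @export
log_binomials <- function(N, mode = c("exact", "stirling")) {
  mode <- match.arg(mode)
  N <- as.integer(N)
  if (N < 0L) stop("N must be >= 0")
  lf <- switch(mode,
    exact = c(0, cumsum(log(seq_len(N)))),
    stirling = .stirling_lfact(0:N)
  )
  k <- 0:N
  lf[N + 1L] - lf[k + 1L] - lf[N - k + 1L]
}

.lfact <- function(N, mode = "exact") {
  if (mode == "exact") c(0, cumsum(log(seq_len(N)))) else .stirling_lfact(0:N)
}

#' Hypergeometric tail probability
#'
#' `P(X >= b)` for `X ~ Hypergeometric(N, B, n)`: the chance that at least
#' `b` of the `n` top-list sequences carry the property when `B` of all `N`
#' do. Computed in log space from log-factorials; `binomials = "stirling"`
#' uses Stirling's series for the binomial coefficients instead of exact
#' cumulative log-factorials.
#'
#' @param b Number of successes in the drawn set (`0 <= b <= min(n, B)`).
#' @param N Population size.
#' @param B Number of successes in the population.
#' @param n Number drawn.
#' @param log.p Return the log probability.
#' @param binomials `"exact"` or `"stirling"`.
#' @return Probability (or its log).
#' @examples
#' hgt(2, 4, 2, 2)  # 1/6
#' hgt(1, 4, 2, 2)  # 5/6
#' @export
hgt <- function(b, N, B, n, log.p = FALSE,
                binomials = c("exact", "stirling")) {
  binomials <- match.arg(binomials)
  b <- as.integer(b); N <- as.integer(N)
  B <- as.integer(B); n <- as.integer(n)
  if (N < 1L || B < 0L || B > N || n < 0L || n > N)
    stop("need 0 <= B <= N and 0 <= n <= N")
  if (b < 0L || b > min(n, B))
    stop("need 0 <= b <= min(n, B)")
  lo <- max(0L, n - (N - B))
  hi <- min(n, B)
  if (b <= lo) return(if (log.p) 0 else 1)
  lf <- .lfact(N, binomials)
  lch <- function(nn, kk) lf[nn + 1L] - lf[kk + 1L] - lf[nn - kk + 1L]
  i <- b:hi
  lterms <- lch(B, i) + lch(N - B, n - i) - lch(N, n)
  m <- max(lterms)
  lres <- min(0, m + log(sum(exp(lterms - m))))
  if (log.p) lres else exp(lres)
}

#' mHG score of a binary label vector
#'
#' Scans every cutoff `n` in `1..N-1`, computes the hypergeometric tail of
#' seeing `b_n` ones among the top `n`, and returns the minimum: the optimal
#' tail probability over all partitions induced by the ranking. The smallest
#' cutoff attaining the minimum is reported. Degenerate vectors (all zeros
#' or all ones) score 1 at `n_star = 1`.
#'
#' @param labels Binary (0/1 or logical) vector; position 1 is the top rank.
#' @return An object of class `mhg_result`: `score`, `log_score`, `n_star`,
#'   `b_star`, `N`, `B`.
#' @examples
#' mhg_score(c(1, 1, 0, 0))  # score 1/6 at n_star = 2
#' @export
mhg_score <- function(labels) {
  labels <- as.integer(as.logical(labels))
  if (anyNA(labels)) stop("labels must be binary without NA")
  N <- length(labels)
  if (N < 1L) stop("need at least one label")
  ones <- which(labels == 1L)
  res <- .mhg_score_cpp(ones, N)
  structure(
    list(score = res$score, log_score = res$log_score,
         n_star = res$n_star, b_star = res$b_star,
         N = N, B = length(ones)),
    class = "mhg_result"
  )
}

#' @export
print.mhg_result <- function(x, ...) {
  cat(sprintf("mHG: score %.4g at n* = %d (b* = %d), N = %d, B = %d",
              x$score, x$n_star, x$b_star, x$N, x$B))
  if (!is.null(x$pvalue)) cat(sprintf(", exact p = %.4g", x$pvalue))
  cat("\n")
  invisible(x)
}

#' Exact mHG p-value
#'
#' Probability of observing an mHG score at most `score` when all
#' `choose(N, B)` placements of the `B` ones are equally likely. Computed
#' by a dynamic program over the `(n, b)` lattice: monotone paths from
#' `(0, 0)` to `(N, B)` are counted in log space, zeroing every cell whose
#' hypergeometric tail is at most the score (for cutoffs `n <= N - 1`);
#' the p-value is one minus the surviving fraction of paths.
#'
#' @param score mHG score in `(0, 1]`.
#' @param N,B Universe size and number of ones.
#' @param log.score Optional log of `score`, for scores that underflow a
#'   double; when supplied, `score` is ignored.
#' @return Exact p-value.
#' @examples
#' mhg_pvalue(1 / 6, 4, 2)  # 1/6
#' @export
mhg_pvalue <- function(score, N, B, log.score = NULL) {
  N <- as.integer(N); B <- as.integer(B)
  if (B < 0L || B > N) stop("need 0 <= B <= N")
  if (is.null(log.score)) {
    if (!is.numeric(score) || score <= 0 || score > 1)
      stop("score must lie in (0, 1]")
    log.score <- log(score)
  }
  .mhg_pvalue_cpp(log.score, N, B)
}

#' Fixed-cutoff hypergeometric p-value
#'
#' Hypergeometric tail at one predetermined cutoff, with no minimization
#' over partitions — used in the target/background mode where the target
#' block defines the cutoff.
#'
#' @param labels Binary label vector.
#' @param n_fixed Cutoff, `1 <= n_fixed <= length(labels)`.
#' @return `hgt(b, N, B, n_fixed)` with `b` the ones among the top
#'   `n_fixed`.
#' @export
fixed_cutoff_pvalue <- function(labels, n_fixed) {
  labels <- as.integer(as.logical(labels))
  N <- length(labels)
  n_fixed <- as.integer(n_fixed)
  if (n_fixed < 1L || n_fixed > N) stop("need 1 <= n_fixed <= N")
  B <- sum(labels)
  b <- sum(labels[seq_len(n_fixed)])
  hgt(b, N, B, n_fixed)
}
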