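test_that("hypergeometric tail matches hand-computed values", {
  expect_equal(hgt(2, 4, 2, 2), 1 / 6, tolerance = 1e-12)
  expect_equal(hgt(1, 4, 2, 2), 5 / 6, tolerance = 1e-12)
  # tail from zero is certain for any valid parameters
  for (p in list(c(10, 3, 4), c(50, 0, 10), c(7, 7, 2)))
    expect_equal(hgt(0, p[1], p[2], p[3]), 1)
  expect_error(hgt(3, 4, 2, 2), "min")
  expect_error(hgt(1, 4, 5, 2))
})

test_that("hgt matches the survival function to 1e-9 relative error", {
  set.seed(11)
  for (i in 1:300) {
    N <- sample(2:1000, 1)
    B <- sample(0:N, 1)
    n <- sample(0:N, 1)
    lo <- max(0, n - (N - B))
    b <- sample(lo:min(n, B), 1)
    ours <- hgt(b, N, B, n)
    ref <- stats::phyper(b - 1, B, N - B, n, lower.tail = FALSE)
    expect_equal(ours, ref, tolerance = 1e-9)
  }
  # the C++ tail used inside the scan agrees with the R implementation
  expect_equal(rankmotif:::.hgt_cpp(7L, 100L, 20L, 25L), hgt(7, 100, 20, 25),
               tolerance = 1e-12)
})

test_that("exact and Stirling log-binomials agree on the log scale", {
  for (N in c(0, 1, 2, 17, 1000)) {
    ex <- log_binomials(N, "exact")
    st <- log_binomials(N, "stirling")
    expect_equal(ex[1], 0)          # log C(N, 0) = 0
    expect_equal(st[1], 0, tolerance = 1e-8)
    expect_equal(st, ex, tolerance = 1e-6)
  }
  expect_equal(log_binomials(4)[3], log(6), tolerance = 1e-12)
})

test_that("mHG score minimizes the tail over cutoffs", {
  r <- mhg_score(c(1, 1, 0, 0))
  expect_equal(r$score, 1 / 6, tolerance = 1e-12)
  expect_equal(r$n_star, 2L)
  expect_equal(r$b_star, 2L)

  expect_equal(mhg_score(rep(0, 6))$score, 1)
  expect_equal(mhg_score(rep(1, 6))$score, 1)
  # single one at the bottom: every usable cutoff has b = 0, score 1
  r2 <- mhg_score(c(0, 0, 0, 0, 1))
  expect_equal(r2$score, 1)
  expect_equal(r2$n_star, 1L)
  expect_equal(r2$b_star, 0L)
})

test_that("mHG score equals the brute-force minimum on random vectors", {
  set.seed(21)
  for (i in 1:300) {
    N <- sample(1:30, 1)
    labels <- rbinom(N, 1, runif(1, 0.1, 0.9))
    r <- mhg_score(labels)
    expect_equal(r$score, bf_mhg_score(labels), tolerance = 1e-12)
    # internal consistency of the reported optimum
    expect_equal(r$b_star, sum(labels[seq_len(r$n_star)]))
    if (r$B > 0 && r$B < N)
      expect_equal(r$score, hgt(r$b_star, N, r$B, r$n_star),
                   tolerance = 1e-12)
    # minimization property: never above any single fixed cutoff
    n1 <- sample(N, 1)
    expect_lte(r$score, fixed_cutoff_pvalue(labels, n1) * (1 + 1e-12))
  }
})

test_that("exact p-value equals the exhaustive fraction on small universes", {
  expect_equal(mhg_pvalue(1, 10, 4), 1)
  expect_equal(mhg_pvalue(1 / 6, 4, 2), 1 / 6, tolerance = 1e-12)
  for (N in c(5L, 8L)) {
    for (B in 0:N) {
      m <- all_label_vectors(N, B)
      scores <- apply(m, 2L, bf_mhg_score)
      for (s in unique(scores)) {
        expect_equal(mhg_pvalue(s, N, B), mean(scores <= s * (1 + 1e-10)),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("p-value bounds and monotonicity hold", {
  set.seed(31)
  for (i in 1:50) {
    N <- sample(5:40, 1)
    B <- sample(1:(N - 1), 1)
    labels <- integer(N)
    labels[sample(N, B)] <- 1L
    r <- mhg_score(labels)
    p <- mhg_pvalue(r$score, N, B, log.score = r$log_score)
    expect_lte(p, min(1, N * r$score) * (1 + 1e-9))  # union bound
    if (r$score < 1)
      expect_gte(p * (1 + 1e-9), 1 / choose(N, B))   # observed config counted
    expect_gte(p * (1 + 1e-9), r$score)              # p >= score
  }
  # non-decreasing in the score for fixed (N, B)
  ss <- sort(runif(20, 1e-6, 1))
  ps <- vapply(ss, mhg_pvalue, numeric(1), N = 25, B = 8)
  expect_true(all(diff(ps) >= -1e-12))
})

test_that("very small scores keep full relative precision", {
  # one candidate with all B ones on top of a long list
  N <- 500L
  B <- 30L
  labels <- c(rep(1L, B), rep(0L, N - B))
  r <- mhg_score(labels)
  p <- mhg_pvalue(r$score, N, B, log.score = r$log_score)
  expect_gt(p, 0)
  expect_lt(p, 1e-30)
  expect_gte(p * (1 + 1e-9), r$score)
})

test_that("fixed-cutoff p-value is a plain hypergeometric tail", {
  expect_equal(fixed_cutoff_pvalue(c(1, 1, 0, 0), 2), 1 / 6,
               tolerance = 1e-12)
  labels <- c(1, 0, 1, 0, 0, 1)
  expect_equal(fixed_cutoff_pvalue(labels, 6), 1)      # whole list
  expect_equal(fixed_cutoff_pvalue(c(0, 0, 1, 1), 2), 1)  # b = 0 at cutoff
})
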