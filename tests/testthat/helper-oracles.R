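# Independent oracles used across the suite.

# Brute-force mHG score: literal minimum of the hypergeometric tail over
# every cutoff n in 1..N-1 (hgt itself is validated against phyper
# separately, so using it as the shared tail primitive keeps the
# minimization paths independent without confounding float noise).
bf_mhg_score <- function(labels) {
  labels <- as.integer(labels)
  N <- length(labels)
  B <- sum(labels)
  if (N == 1L || B == 0L || B == N) return(1)
  cum <- cumsum(labels)
  min(vapply(1:(N - 1L), function(n) hgt(cum[n], N, B, n), numeric(1)))
}

# All binary vectors of length N with B ones, one per column
all_label_vectors <- function(N, B) {
  if (B == 0L) return(matrix(0L, nrow = N, ncol = 1L))
  cols <- combn(N, B)
  apply(cols, 2L, function(ix) {
    l <- integer(N)
    l[ix] <- 1L
    l
  })
}

# Exhaustive mHG p-value: fraction of all C(N, B) label vectors whose
# brute-force score is at most s (with the same relative tie tolerance the
# DP uses).
bf_mhg_pvalue <- function(s, N, B) {
  m <- all_label_vectors(N, B)
  scores <- apply(m, 2L, bf_mhg_score)
  mean(scores <= s * (1 + 1e-10))
}

# Canonical form of a kmer_set for equality comparison
normalize_kmer_set <- function(ks) {
  o <- order(ks$k, ks$word, method = "radix")
  list(
    word = ks$word[o], k = ks$k[o],
    occ = lapply(ks$occ[o], function(m) {
      m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
      dimnames(m) <- NULL
      m
    }),
    hits = lapply(ks$hits[o], as.integer)
  )
}

random_dna <- function(n, len, ambig_prob = 0) {
  letters <- c("A", "C", "G", "T", "N")
  pr <- c(rep((1 - ambig_prob) / 4, 4), ambig_prob)
  vapply(seq_len(n), function(i)
    paste(sample(letters, len, replace = TRUE, prob = pr), collapse = ""),
    character(1))
}

write_temp_fasta <- function(ids, seqs, width = 60L) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  con <- file(path, "w")
  for (i in seq_along(ids)) {
    writeLines(paste0(">", ids[i]), con)
    s <- seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  close(con)
  path
}
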