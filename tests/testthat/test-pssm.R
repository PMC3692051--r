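test_that("Hamming neighborhoods have the right size and symmetry", {
  nb <- hamming_neighbors("AA")
  expect_length(nb, 6L)
  expect_setequal(nb, c("CA", "GA", "TA", "AC", "AG", "AT"))
  expect_length(hamming_neighbors("ACDEF", "PROTEIN"), 5L * 19L)
  # symmetry: w' in Nb(w) <=> w in Nb(w')
  set.seed(13)
  for (i in 1:20) {
    w <- paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE),
               collapse = "")
    for (v in sample(hamming_neighbors(w), 3))
      expect_true(w %in% hamming_neighbors(v))
  }
})

test_that("seed selection keeps the best records, one slot per canonical pair", {
  fix <- generate_planted(plant_spec(seed = 41))
  sc <- scan_motifs(fix$seqs, k_min = 8, k_max = 8)
  expect_identical(select_seeds(sc, 50L), head(sc$records, 50L))
  expect_lte(nrow(select_seeds(sc, 2L)), 2L)
})

test_that("a seed with no present neighbors yields a point-mass PSSM", {
  # top sequences carry the motif; every Hamming neighbor is absent because
  # the rest of each sequence avoids the motif's letters
  seqs <- c(rep("TGACGTCAAAAAAAAA", 6), rep("CCCCCCCCCCCCCCCC", 24))
  # break up the homopolymer background so the planted word stays unique
  x <- ranked_seqs(seqs)
  sc <- scan_motifs(x, k_min = 8, k_max = 8, alpha = 1e-2,
                    correction = "none")
  expect_true("TGACGTCA" %in% sc$records$kmer)
  p <- extend_pssm("TGACGTCA", sc, pseudocount = 0.01)
  expect_equal(p$members, "TGACGTCA")
  # closed form: one-hot columns smoothed by the pseudocount
  w <- p$weights[[1]]
  expect_equal(max(p$prob[, 1]), (w + 0.01) / (w + 0.04), tolerance = 1e-12)
  expect_equal(min(p$prob[, 1]), 0.01 / (w + 0.04), tolerance = 1e-12)
  expect_equal(consensus(p), "TGACGTCA")
  expect_true(all(abs(colSums(p$prob) - 1) < 1e-9))
})

test_that("extension adopts a one-mismatch variant and mixes the column", {
  fix <- generate_planted(plant_spec(motifs = c("TGACGTCA", "TGACTTCA"),
                                     seed = 42))
  sc <- scan_motifs(fix$seqs, k_min = 8, k_max = 8)
  p <- extend_pssm(sc$records$kmer[1], sc)
  expect_true(all(c("TGACGTCA", "TGACTTCA") %in% p$members))
  # position 5 carries the planted G/T mixture
  expect_gt(p$prob["G", 5], 0.2)
  expect_gt(p$prob["T", 5], 0.2)
  # joint p-value beats the seed alone, and the trace strictly decreases
  expect_lt(p$stats$pvalue, sc$records$pvalue[1])
  expect_true(all(diff(p$trace) < 0))
  expect_true(p$seed %in% p$members)
})

test_that("a neighbor only present at the bottom of the list is rejected", {
  set.seed(55)
  top <- random_dna(10, 60)
  substr(top, 20, 27) <- "TGACGTCA"
  bottom <- random_dna(90, 60)
  substr(bottom, 20, 27) <- "TGACTTCA"  # variant lives only at the bottom
  x <- ranked_seqs(c(top, bottom))
  sc <- scan_motifs(x, k_min = 8, k_max = 8, alpha = 1e-2)
  expect_true("TGACGTCA" %in% sc$records$kmer)
  p <- extend_pssm("TGACGTCA", sc)
  expect_false("TGACTTCA" %in% p$members)
})

test_that("near-duplicate PSSMs collapse to one representative", {
  fix <- generate_planted(plant_spec(motifs = c("TGACGTCA", "TGACTTCA"),
                                     seed = 43))
  sc <- scan_motifs(fix$seqs, k_min = 8, k_max = 8)
  pssms <- extend_motifs(sc, limit = 10L)
  expect_gte(length(pssms), 1L)
  # both planted variants extend to the same member set; only one survives
  sets <- lapply(pssms, function(p) sort(p$members))
  expect_equal(anyDuplicated(sets), 0L)
  for (i in seq_along(pssms))
    for (j in seq_len(i - 1L)) {
      shared <- length(intersect(pssms[[i]]$members, pssms[[j]]$members))
      expect_lt(shared, 0.5 * min(lengths(sets)[c(i, j)]))
    }
})

test_that("PSSM files round-trip their probabilities", {
  fix <- generate_planted(plant_spec(seed = 44))
  sc <- scan_motifs(fix$seqs, k_min = 8, k_max = 8)
  p <- extend_pssm(sc$records$kmer[1], sc)
  f <- withr::local_tempfile(fileext = ".txt")
  write_pssm(p, f)
  lines <- readLines(f)
  expect_match(lines[1], "^# k=8\talphabet=DNA\tpvalue=")
  body <- read.table(text = lines[-(1:2)], sep = "\t")
  expect_equal(as.matrix(body), t(unname(p$prob)), tolerance = 1e-9,
               ignore_attr = TRUE)
  g <- withr::local_tempfile(fileext = ".tsv")
  write_logo_table(p, g)
  logo <- read.delim(g)
  expect_equal(nrow(logo), 4L * p$k)
  expect_equal(sum(logo$probability), p$k, tolerance = 1e-9)
})
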