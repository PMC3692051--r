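test_that("reverse complement follows Watson-Crick pairing", {
  expect_equal(reverse_complement("ACGT"), "ACGT")  # palindrome
  expect_equal(reverse_complement("AAGG"), "CCTT")
  expect_equal(reverse_complement("ACGU", "RNA"), "ACGU")
  expect_equal(reverse_complement(c("A", "TTT")), c("T", "AAA"))
  expect_equal(reverse_complement("ANR"), "YNT")  # IUPAC codes map too
  expect_error(reverse_complement("MKW", "PROTEIN"), "protein")
})

test_that("label vectors use presence semantics", {
  expect_equal(kmer_label_vector(c(1L, 2L), 4L), c(1L, 1L, 0L, 0L))
  # five occurrences in one sequence still give B = 1
  x <- ranked_seqs(c("AAAAAA", "CCCCCC"))
  ks <- enumerate_kmers(build_suffix_tree(x), 2, 2)
  aa <- match("AA", ks$word)
  expect_equal(nrow(ks$occ[[aa]]), 5L)
  expect_equal(ks$hits[[aa]], 1L)
})

test_that("planted 8-mer is recovered as the top-ranked record", {
  fix <- generate_planted(plant_spec(seed = 20260901))
  sc <- scan_motifs(fix$seqs, k_min = 8, k_max = 8)
  expect_gt(nrow(sc$records), 0)
  top <- sc$records[1, ]
  expect_equal(top$kmer, "TGACGTCA")
  expect_equal(top$N, 200L)
  expect_gte(top$B, 30L)
  expect_lte(top$corrected_pvalue, 1e-6)
  # reported enrichment satisfies its defining identity exactly
  expect_identical(sc$records$enrichment,
                   (sc$records$b / sc$records$n) /
                     (sc$records$B / sc$records$N))
})

test_that("null lists report nothing and single sequences cannot score", {
  nl <- scan_motifs(generate_null(seed = 4), k_min = 8, k_max = 8)
  expect_equal(nrow(nl$records), 0L)

  one <- scan_motifs(ranked_seqs(paste(rep("ACGT", 10), collapse = "")),
                     k_min = 4, k_max = 4, alpha = 1e-2)
  expect_equal(nrow(one$records), 0L)
})

test_that("double-strand candidates are canonical word/revcomp pairs", {
  # plant on random strands; the canonical form must still be found
  fix <- generate_planted(plant_spec(orientation = "random",
                                     seed = 20260902))
  sc <- scan_motifs(fix$seqs, k_min = 8, k_max = 8, strand = "double")
  expect_true("TGACGTCA" %in% sc$records$kmer)  # its own reverse complement
  rec <- sc$records[sc$records$kmer == "TGACGTCA", ]
  expect_equal(rec$reverse_complement, "TGACGTCA")
  expect_gte(rec$B, 30L)
  # every reported kmer is lexicographically <= its reverse complement
  expect_true(all(sc$records$kmer <= sc$records$reverse_complement))
})

test_that("double-strand results are invariant under reverse-complementing input", {
  fix <- generate_planted(plant_spec(n_sequences = 80L, n_plant = 15L,
                                     orientation = "random", seed = 33))
  flipped <- ranked_seqs(reverse_complement(fix$seqs$seq), ids = fix$seqs$id)
  a <- scan_motifs(fix$seqs, k_min = 8, k_max = 8, strand = "double")
  b <- scan_motifs(flipped, k_min = 8, k_max = 8, strand = "double")
  expect_identical(a$records$kmer, b$records$kmer)
  expect_identical(a$records$pvalue, b$records$pvalue)
  expect_identical(a$records$B, b$records$B)
})

test_that("identical input and config give byte-identical records", {
  fix <- generate_planted(plant_spec(n_sequences = 60L, n_plant = 12L,
                                     seed = 9))
  a <- scan_motifs(fix$seqs, k_min = 8, k_max = 8)
  b <- scan_motifs(fix$seqs, k_min = 8, k_max = 8)
  expect_identical(a$records, b$records)
})

test_that("two-set mode uses the fixed-cutoff hypergeometric tail", {
  # word in all 5 targets, background alphabet cannot contain it
  set.seed(77)
  tgt <- random_dna(5, 40)
  substr(tgt, 10, 17) <- "TGACGTCA"
  bg <- vapply(1:15, function(i)
    paste(sample(c("A", "C", "G"), 40, replace = TRUE), collapse = ""),
    character(1))
  ts <- two_set_input(ranked_seqs(tgt, alphabet = "DNA"),
                      ranked_seqs(bg, alphabet = "DNA"))
  sc <- scan_two_sets(ts, k_min = 8, k_max = 8, alpha = 1e-2,
                      correction = "none")
  rec <- sc$records[sc$records$kmer == "TGACGTCA", ]
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$n, 5L)
  expect_equal(rec$b, 5L)
  expect_equal(rec$B, 5L)
  expect_equal(rec$pvalue, 1 / choose(20, 5), tolerance = 1e-12)

  # a word present everywhere is filtered out (p near 1)
  ubi <- c(paste(rep("ACGTACGTAC", 4), collapse = ""))
  ts2 <- two_set_input(ranked_seqs(rep(ubi, 3)), ranked_seqs(rep(ubi, 5)))
  sc2 <- scan_two_sets(ts2, k_min = 8, k_max = 8, alpha = 1e-2)
  expect_equal(nrow(sc2$records), 0L)
})

test_that("alpha and k bounds are enforced", {
  x <- ranked_seqs(random_dna(3, 30))
  expect_error(scan_motifs(x, alpha = 0.5), "alpha")
  expect_error(scan_motifs(x, alpha = 1e-20), "alpha")
  expect_error(scan_motifs(x, k_min = 2, k_max = 8), "k range")
  expect_error(scan_motifs(x, k_min = 5, k_max = 25), "k range")
  expect_error(scan_motifs(ranked_seqs("MKWVLLEF"), strand = "double",
                           k_min = 4, k_max = 4), "nucleic")
})
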