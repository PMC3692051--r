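test_that("k-mer table formats statistics as specified", {
  rec <- data.frame(
    kmer = "TGACGTCA", reverse_complement = NA_character_, k = 8L,
    N = 200L, B = 40L, n = 30L, b = 30L,
    enrichment = (30 / 30) / (40 / 200), pvalue = 2.5e-12,
    corrected_pvalue = 4.1e-8, rank = 1L, stringsAsFactors = FALSE
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  write_kmer_table(rec, f)
  tab <- read.delim(f)
  expect_equal(tab$enrichment, 5)
  expect_equal(tab$N, 200L)
  expect_match(readLines(f)[2], "e-12")  # scientific notation p-values

  # empty record set -> header-only file
  write_kmer_table(rec[0, ], f)
  expect_length(readLines(f), 1L)
})

test_that("occurrence reports use 1-based coordinates and cover all ranks", {
  seqs <- c("TGACGTCAGGGGG", "CCCCCTGACGTCA", "GGGGGGGGGGGGG")
  x <- ranked_seqs(seqs)
  sc <- scan_motifs(x, k_min = 8, k_max = 8, alpha = 1e-2,
                    correction = "none")
  af <- withr::local_tempfile(fileext = ".tsv")
  df <- withr::local_tempfile(fileext = ".tsv")
  occ <- write_occurrence_reports("TGACGTCA", sc, af, df)
  align <- read.delim(af)
  expect_equal(align$position[align$rank == 1], 1L)  # offset 0 prints as 1
  expect_equal(align$position[align$rank == 2], 6L)
  expect_true(all(align$matched_word == "TGACGTCA"))
  dist <- read.delim(df, colClasses = c("integer", "character", "character"))
  expect_equal(nrow(dist), 3L)            # absent rank keeps its row
  expect_equal(dist$positions[3], "")     # ... with an empty cell
})

test_that("palindromic double-strand occurrences are reported once, on plus", {
  x <- ranked_seqs(c("AATGACGTCATT", "AAAAATTTTTTT"))
  sc <- scan_motifs(x, k_min = 8, k_max = 8, strand = "double",
                    alpha = 1e-2, correction = "none")
  af <- withr::local_tempfile(fileext = ".tsv")
  df <- withr::local_tempfile(fileext = ".tsv")
  occ <- write_occurrence_reports("TGACGTCA", sc, af, df)
  expect_equal(nrow(occ), 1L)
  expect_equal(occ$strand, "+")
})

test_that("the end-to-end run writes a complete, reproducible output set", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  fix <- generate_planted(plant_spec(n_sequences = 80L, n_plant = 15L,
                                     seed = 70))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_ranked_fasta(fix$seqs, fa)
  cfg1 <- run_config(fasta = fa, k_min = 8L, k_max = 8L, out_dir = dir1)
  cfg2 <- run_config(fasta = fa, k_min = 8L, k_max = 8L, out_dir = dir2)
  s1 <- suppressMessages(run_motif_discovery(cfg1))
  s2 <- suppressMessages(run_motif_discovery(cfg2))
  expect_gte(s1$n_significant, 1L)
  expect_equal(s1$motifs[[1]]$consensus, "TGACGTCA")
  for (f in c("kmers.tsv", "summary.json", "motif_01.pssm.txt",
              "motif_01.logo.tsv", "motif_01.occurrences.tsv",
              "motif_01.distribution.tsv"))
    expect_true(file.exists(file.path(dir1, f)))
  # reruns are byte-identical (timings live only in the message log)
  for (f in list.files(dir1))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)),
                     label = f)
  # zero motifs is a valid outcome, not an error
  nullfa <- withr::local_tempfile(fileext = ".fa")
  write_ranked_fasta(generate_null(60L, 80L, seed = 71), nullfa)
  s0 <- suppressMessages(run_motif_discovery(
    run_config(fasta = nullfa, k_min = 8L, k_max = 8L,
               out_dir = withr::local_tempdir())))
  expect_equal(s0$n_significant, 0L)
  expect_length(s0$motifs, 0L)
})

test_that("malformed input fails with an actionable message", {
  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">ok", "ACGT", ">oops", "ACGT!!"), bad)
  cfg <- run_config(fasta = bad, out_dir = withr::local_tempdir())
  expect_error(run_motif_discovery(cfg), "oops")
})

test_that("run_config validates its mode and defaults", {
  expect_error(run_config(), "either")
  expect_error(run_config(fasta = "a.fa", target = "t.fa",
                          background = "b.fa"), "either")
  expect_error(run_config(target = "t.fa"), "both")
  cfg <- run_config(fasta = "a.fa")
  expect_equal(cfg$alpha, 1e-6)
  expect_equal(cfg$strand, "single")
  expect_equal(cfg$seed_limit, 50L)
})
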