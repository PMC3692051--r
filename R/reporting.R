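# Run configuration, the two-phase driver (k-mer scan, then PSSM
# extension), and the output surface: k-mer table, PSSM files, occurrence
# alignment and distribution reports, and a JSON summary. Human-readable
# coordinates are 1-based inclusive; internal coordinates are 0-based
# half-open, converted in one audited helper.

.to_one_based <- function(pos0) as.integer(pos0) + 1L

#' Configuration for a motif-discovery run
#'
#' Defaults mirror the published service: single-strand word lengths 5-10
#' (10 in double-strand mode), significance threshold 1e-6, word lengths
#' bounded to 4-20, at most 40000 sequences and 4e6 characters.
#'
#' @param fasta Path to a ranked multi-FASTA file (ranked mode), or `NULL`.
#' @param target,background Paths to the two FASTA files (two-set mode), or
#'   `NULL`. Exactly one input mode must be given.
#' @param strand `"single"` or `"double"`.
#' @param k_min,k_max Word length range (`NULL` = mode default).
#' @param alpha Significance threshold.
#' @param seed_limit Number of seeds extended to PSSMs.
#' @param correction `"bonferroni"` or `"none"`.
#' @param threshold_on `"corrected"` or `"raw"`.
#' @param out_dir Output directory.
#' @param alphabet Optional alphabet hint for the readers.
#' @param max_sequences,max_chars Input size limits.
#' @return An object of class `run_config`.
#' @export
run_config <- function(fasta = NULL, target = NULL, background = NULL,
                       strand = c("single", "double"), k_min = NULL,
                       k_max = NULL, alpha = 1e-6, seed_limit = 50L,
                       correction = c("bonferroni", "none"),
                       threshold_on = c("corrected", "raw"),
                       out_dir = ".", alphabet = NULL,
                       max_sequences = 40000L, max_chars = 4000000L) {
  strand <- match.arg(strand)
  correction <- match.arg(correction)
  threshold_on <- match.arg(threshold_on)
  ranked <- !is.null(fasta)
  two_set <- !is.null(target) || !is.null(background)
  if (ranked == two_set)
    stop("give either `fasta` (ranked mode) or both `target` and ",
         "`background` (two-set mode)")
  if (two_set && (is.null(target) || is.null(background)))
    stop("two-set mode needs both `target` and `background`")
  .check_alpha(alpha)
  structure(
    list(mode = if (ranked) "ranked" else "two_set", fasta = fasta,
         target = target, background = background, strand = strand,
         k_min = k_min, k_max = k_max, alpha = alpha,
         seed_limit = as.integer(seed_limit), correction = correction,
         threshold_on = threshold_on, out_dir = out_dir,
         alphabet = alphabet, max_sequences = max_sequences,
         max_chars = max_chars),
    class = "run_config"
  )
}

#' Write the significant k-mer table
#'
#' One row per reported motif with the statistics `N`, `B`, `n`, `b`, the
#' enrichment `(b/n)/(B/N)` printed to 4 significant digits, and raw and
#' corrected p-values in scientific notation. An empty record set yields a
#' header-only file.
#'
#' @param records The `records` data frame of a scan.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_kmer_table <- function(records, path) {
  df <- data.frame(
    kmer = records$kmer,
    reverse_complement = records$reverse_complement,
    N = records$N, B = records$B, n = records$n, b = records$b,
    enrichment = signif(records$enrichment, 4L),
    raw_pvalue = format(records$pvalue, scientific = TRUE, digits = 6L),
    corrected_pvalue = format(records$corrected_pvalue, scientific = TRUE,
                              digits = 6L),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# All occurrences of a motif's member words, re-validated against the
# stored sequences. `members` are canonical words; in double-strand mode
# minus-strand occurrences are sites where the reverse complement of the
# canonical word lies in the sequence text.
.motif_occurrences <- function(members, scan) {
  seqs <- scan$seqs
  k <- nchar(members[1L])
  idx <- scan$index[[as.character(k)]]
  rows <- list()
  for (w in members) {
    m <- idx$occ[[match(w, idx$word)]]
    if (is.null(m)) next
    strand <- if ("strand" %in% colnames(m)) m[, "strand"] else
      rep.int(0L, nrow(m))
    for (r in seq_len(nrow(m))) {
      i <- m[r, "seq"]; p0 <- m[r, "pos"]
      found <- substr(seqs$seq[i], p0 + 1L, p0 + k)
      expect <- if (strand[r] == 1L)
        reverse_complement(w, seqs$alphabet) else w
      if (found != expect)
        stop("internal error: occurrence of '", w, "' fails revalidation")
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = seqs$id[i], rank = i, position = .to_one_based(p0),
        strand = if (strand[r] == 1L) "-" else "+",
        matched_word = found, member = w, stringsAsFactors = FALSE
      )
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq_id = character(0), rank = integer(0),
               position = integer(0), strand = character(0),
               matched_word = character(0), member = character(0),
               stringsAsFactors = FALSE)
  df[order(df$rank, df$position), , drop = FALSE]
}

.flank <- function(seqs, rank, pos1, k, width = 10L) {
  s <- seqs$seq[rank]
  lo <- max(1L, pos1 - width)
  hi <- min(nchar(s), pos1 + k - 1L + width)
  paste0(substr(s, lo, pos1 - 1L), "[", substr(s, pos1, pos1 + k - 1L),
         "]", substr(s, pos1 + k, hi))
}

#' Write occurrence alignment and distribution reports for a motif
#'
#' The alignment file lists every occurrence (sequence id, rank, 1-based
#' position, strand, matched word, flanking context), sorted by rank then
#' position. The distribution file has one row per input rank with the
#' occurrence positions as a semicolon-separated list (empty cell when the
#' motif is absent from that rank).
#'
#' @param members Character vector of member words (canonical orientation).
#' @param scan The `motif_scan` the motif came from.
#' @param alignment_path,distribution_path Output TSV paths.
#' @return Invisibly, the occurrence data frame.
#' @export
write_occurrence_reports <- function(members, scan, alignment_path,
                                     distribution_path) {
  occ <- .motif_occurrences(members, scan)
  k <- nchar(members[1L])
  occ$context <- if (nrow(occ))
    mapply(.flank, rank = occ$rank, pos1 = occ$position,
           MoreArgs = list(seqs = scan$seqs, k = k)) else character(0)
  write.table(occ, alignment_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  N <- scan$seqs$N
  pos_by_rank <- vapply(seq_len(N), function(i)
    paste(occ$position[occ$rank == i], collapse = ";"), character(1))
  dist <- data.frame(rank = seq_len(N), seq_id = scan$seqs$id,
                     positions = pos_by_rank, stringsAsFactors = FALSE)
  write.table(dist, distribution_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(occ)
}

#' Run the full two-phase motif discovery
#'
#' Phase one scans all k-mers and keeps those passing the significance
#' threshold; phase two extends the best seeds into PSSMs. Writes
#' `kmers.tsv`, per-motif PSSM text and logo tables, occurrence alignment
#' and distribution reports, and a machine-readable `summary.json` into the
#' configured output directory. Phase timings are logged as messages only,
#' so outputs are byte-identical across reruns. Zero reported motifs is a
#' valid outcome.
#'
#' @param config A [run_config()].
#' @return The run summary (also written as JSON), invisibly.
#' @export
run_motif_discovery <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  if (config$mode == "ranked") {
    input <- read_ranked_fasta(config$fasta, alphabet = config$alphabet,
                               max_sequences = config$max_sequences,
                               max_chars = config$max_chars)
    message("read ", input$N, " ranked sequences (", input$total_chars,
            " chars, ", input$alphabet, ")")
    scan <- scan_motifs(input, k_min = config$k_min, k_max = config$k_max,
                        strand = config$strand, alpha = config$alpha,
                        correction = config$correction,
                        threshold_on = config$threshold_on)
  } else {
    input <- read_two_sets(config$target, config$background,
                           alphabet = config$alphabet,
                           max_sequences = config$max_sequences,
                           max_chars = config$max_chars)
    message("read ", input$target$N, " target + ", input$background$N,
            " background sequences (", input$target$alphabet, ")")
    scan <- scan_two_sets(input, k_min = config$k_min,
                          k_max = config$k_max, strand = config$strand,
                          alpha = config$alpha,
                          correction = config$correction,
                          threshold_on = config$threshold_on)
  }
  t1 <- Sys.time()
  message(sprintf("phase 1 (k-mer scan): %d candidate(s), %d significant [%.2fs]",
                  sum(scan$candidate_counts), nrow(scan$records),
                  as.numeric(difftime(t1, t0, units = "secs"))))
  pssms <- extend_motifs(scan, limit = config$seed_limit)
  t2 <- Sys.time()
  message(sprintf("phase 2 (PSSM extension): %d motif(s) [%.2fs]",
                  length(pssms),
                  as.numeric(difftime(t2, t1, units = "secs"))))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_kmer_table(scan$records, file.path(config$out_dir, "kmers.tsv"))
  motif_summaries <- vector("list", length(pssms))
  for (i in seq_along(pssms)) {
    p <- pssms[[i]]
    tag <- sprintf("motif_%02d", i)
    write_pssm(p, file.path(config$out_dir, paste0(tag, ".pssm.txt")))
    write_logo_table(p, file.path(config$out_dir, paste0(tag, ".logo.tsv")))
    write_occurrence_reports(
      p$members, scan,
      file.path(config$out_dir, paste0(tag, ".occurrences.tsv")),
      file.path(config$out_dir, paste0(tag, ".distribution.tsv"))
    )
    motif_summaries[[i]] <- list(
      consensus = consensus(p), seed = p$seed, members = p$members,
      stats = p$stats
    )
  }
  summary <- list(
    mode = scan$mode, strand = scan$strand,
    k_min = scan$k_min, k_max = scan$k_max, alpha = scan$alpha,
    correction = scan$correction, threshold_on = scan$threshold_on,
    n_sequences = scan$seqs$N, total_chars = scan$seqs$total_chars,
    alphabet = scan$seqs$alphabet,
    n_candidates = as.list(scan$candidate_counts),
    n_significant = nrow(scan$records),
    records = scan$records, motifs = motif_summaries
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
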