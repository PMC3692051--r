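# Greedy Hamming-neighbor extension of significant exact k-mers into PSSMs.
# Starting from a seed word, length-k neighbors of any current member are
# adopted one at a time (best first) as long as the member set's joint
# enrichment p-value strictly improves.

#' Hamming-1 neighbors of a word
#'
#' All words of the same length differing in exactly one position, over the
#' core letters of the alphabet; there are `k * (|alphabet| - 1)` of them.
#'
#' @param word A word over the core alphabet.
#' @param alphabet `"DNA"`, `"RNA"` or `"PROTEIN"`.
#' @return Sorted character vector of neighbors (the word itself excluded).
#' @examples
#' hamming_neighbors("AA")  # CA GA TA AC AG AT, sorted
#' @export
hamming_neighbors <- function(word, alphabet = c("DNA", "RNA", "PROTEIN")) {
  alphabet <- match.arg(alphabet)
  core <- alphabet_letters(alphabet, "core")
  ch <- strsplit(word, "", fixed = TRUE)[[1L]]
  if (!all(ch %in% core)) stop("word contains letters outside the alphabet")
  out <- character(0)
  for (i in seq_along(ch)) {
    for (a in setdiff(core, ch[i])) {
      w <- ch
      w[i] <- a
      out <- c(out, paste(w, collapse = ""))
    }
  }
  sort(unique(out), method = "radix")
}

#' Select seed motifs for extension
#'
#' The top records (default 50) of a scan, by corrected p-value; in
#' double-strand mode each record is already a canonical word/reverse
#' complement pair occupying one slot, and boundary ties were broken
#' lexicographically when the records were sorted.
#'
#' @param scan A [scan_motifs()] or [scan_two_sets()] result, or its
#'   `records` data frame.
#' @param limit Maximum number of seeds.
#' @return Data frame of seed records.
#' @export
select_seeds <- function(scan, limit = 50L) {
  records <- if (inherits(scan, "motif_scan")) scan$records else scan
  head(records, limit)
}

# joint raw enrichment p-value of a hit-rank set under the scan's mode
.joint_pvalue <- function(hits, scan) {
  N <- scan$seqs$N
  if (scan$mode == "two_set") {
    b <- sum(hits <= scan$n_fixed)
    p <- hgt(b, N, length(hits), scan$n_fixed)
    list(pvalue = p, n_star = scan$n_fixed, b_star = b,
         score = p, log_score = log(p))
  } else {
    sc <- .mhg_score_cpp(as.integer(hits), N)
    p <- .mhg_pvalue_cpp(sc$log_score, N, length(hits))
    list(pvalue = p, n_star = sc$n_star, b_star = sc$b_star,
         score = sc$score, log_score = sc$log_score)
  }
}

#' Extend a seed k-mer into a PSSM
#'
#' Greedy loop: at each step every Hamming-1 neighbor of any current member
#' that occurs in the input is evaluated by recomputing the member set's
#' joint label vector (a sequence counts if it contains any member, with
#' the scan's strand rules) and its enrichment p-value; the single neighbor
#' giving the lowest p-value is adopted if strictly lower than the current
#' one, otherwise the loop stops. Columns are letter frequencies over all
#' member occurrences within the top `n*` sequences, weighted by occurrence
#' count, with a pseudocount.
#'
#' @param seed A seed k-mer (character) or a one-row record from
#'   [select_seeds()].
#' @param scan The `motif_scan` object the seed came from.
#' @param pseudocount Added to every letter count in every column
#'   (default 0.01).
#' @return An object of class `pssm`: fields `k`, `alphabet`, `letters`,
#'   `prob` (letters x k column-stochastic matrix), `members`, `weights`,
#'   `seed`, `stats` (joint `N`, `B`, `n`, `b`, `enrichment`, `pvalue`) and
#'   `trace` (the strictly decreasing p-value sequence over accepted
#'   steps).
#' @export
extend_pssm <- function(seed, scan, pseudocount = 0.01) {
  stopifnot(inherits(scan, "motif_scan"))
  kmer <- if (is.character(seed)) seed else seed$kmer
  stopifnot(is.character(kmer), length(kmer) == 1L)
  k <- nchar(kmer)
  idx <- scan$index[[as.character(k)]]
  if (is.null(idx) || !(kmer %in% idx$word))
    stop("seed '", kmer, "' is not a candidate of this scan")
  alphabet <- scan$seqs$alphabet
  double <- scan$strand == "double"
  canon <- function(w) {
    r <- reverse_complement(w, alphabet)
    ifelse(w <= r, w, r)
  }
  members <- kmer
  hits <- idx$hits[[match(kmer, idx$word)]]
  cur <- .joint_pvalue(hits, scan)
  trace <- cur$pvalue
  repeat {
    nbs <- unique(unlist(lapply(members, hamming_neighbors, alphabet),
                         use.names = FALSE))
    if (double) nbs <- unique(canon(nbs))
    nbs <- setdiff(sort(nbs, method = "radix"), members)
    mi <- match(nbs, idx$word)
    nbs <- nbs[!is.na(mi)]
    mi <- mi[!is.na(mi)]
    if (!length(nbs)) break
    best_p <- cur$pvalue
    best_j <- NA_integer_
    best_res <- NULL
    best_hits <- NULL
    for (j in seq_along(nbs)) {
      h2 <- sort(unique(c(hits, idx$hits[[mi[j]]])))
      res <- .joint_pvalue(h2, scan)
      if (res$pvalue < best_p) {  # strict improvement; first (lexicographic
        best_p <- res$pvalue      # order) wins ties among equals
        best_j <- j
        best_res <- res
        best_hits <- h2
      }
    }
    if (is.na(best_j)) break
    members <- c(members, nbs[best_j])
    hits <- best_hits
    cur <- best_res
    trace <- c(trace, cur$pvalue)
  }
  members <- sort(members, method = "radix")
  n_star <- cur$n_star
  weights <- vapply(members, function(w) {
    m <- idx$occ[[match(w, idx$word)]]
    sum(m[, "seq"] <= n_star)
  }, numeric(1))
  core <- alphabet_letters(alphabet, "core")
  prob <- matrix(pseudocount, nrow = length(core), ncol = k,
                 dimnames = list(core, NULL))
  for (i in seq_along(members)) {
    if (weights[i] == 0) next
    ch <- strsplit(members[i], "", fixed = TRUE)[[1L]]
    ij <- cbind(match(ch, core), seq_len(k))
    prob[ij] <- prob[ij] + weights[i]
  }
  prob <- sweep(prob, 2L, colSums(prob), "/")
  N <- scan$seqs$N
  B <- length(hits)
  stats <- list(N = N, B = B, n = n_star, b = cur$b_star,
                enrichment = (cur$b_star / n_star) / (B / N),
                pvalue = cur$pvalue, score = cur$score)
  structure(
    list(k = k, alphabet = alphabet, letters = core, prob = prob,
         members = members, weights = weights, seed = kmer,
         stats = stats, trace = trace),
    class = "pssm"
  )
}

#' Consensus word of a PSSM
#'
#' @param x A `pssm` object.
#' @return The word formed by each column's most probable letter.
#' @export
consensus <- function(x) {
  stopifnot(inherits(x, "pssm"))
  paste(x$letters[apply(x$prob, 2L, which.max)], collapse = "")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM (k = %d, %s): consensus %s, %d member(s), p = %.4g\n",
              x$k, x$alphabet, consensus(x), length(x$members),
              x$stats$pvalue))
  print(round(x$prob, 3))
  invisible(x)
}

# PSSMs whose member sets share at least half of the smaller set are
# near-duplicates; the more significant one is kept.
.dedup_pssms <- function(pssms) {
  if (length(pssms) <= 1L) return(pssms)
  o <- order(vapply(pssms, function(p) p$stats$pvalue, numeric(1)),
             vapply(pssms, function(p) p$seed, character(1)),
             method = "radix")
  kept <- list()
  for (i in o) {
    p <- pssms[[i]]
    dup <- any(vapply(kept, function(q) {
      shared <- length(intersect(p$members, q$members))
      shared >= 0.5 * min(length(p$members), length(q$members))
    }, logical(1)))
    if (!dup) kept[[length(kept) + 1L]] <- p
  }
  kept
}

#' Extend the best motifs of a scan into deduplicated PSSMs
#'
#' Runs [extend_pssm()] on the top seeds ([select_seeds()]) and collapses
#' near-duplicate results (member sets sharing at least half of the smaller
#' set), keeping the most significant representative of each group.
#'
#' @param scan A `motif_scan` object.
#' @param limit Seed budget (default 50).
#' @param pseudocount Passed to [extend_pssm()].
#' @return List of `pssm` objects ordered by joint p-value.
#' @export
extend_motifs <- function(scan, limit = 50L, pseudocount = 0.01) {
  seeds <- select_seeds(scan, limit)
  if (!nrow(seeds)) return(list())
  pssms <- lapply(seeds$kmer, extend_pssm, scan = scan,
                  pseudocount = pseudocount)
  .dedup_pssms(pssms)
}

#' Write a PSSM as a text file
#'
#' One header line (`k`, alphabet, p-value, consensus, members), a comment
#' line naming the letter columns, then `k` tab-separated rows of per-letter
#' probabilities in fixed alphabet order.
#'
#' @param x A `pssm` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(x, path) {
  stopifnot(inherits(x, "pssm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# k=%d\talphabet=%s\tpvalue=%s\tconsensus=%s\tmembers=%s",
                     x$k, x$alphabet, format(x$stats$pvalue, digits = 15),
                     consensus(x), paste(x$members, collapse = ",")), con)
  writeLines(paste0("# columns: ", paste(x$letters, collapse = "\t")), con)
  for (j in seq_len(x$k))
    writeLines(paste(format(x$prob[, j], digits = 10, scientific = FALSE),
                     collapse = "\t"), con)
  invisible(path)
}

#' Write a machine-readable logo table
#'
#' Long-format TSV with columns `position`, `letter`, `probability`; the
#' text equivalent of a sequence logo.
#'
#' @param x A `pssm` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_logo_table <- function(x, path) {
  stopifnot(inherits(x, "pssm"))
  df <- data.frame(
    position = rep(seq_len(x$k), each = length(x$letters)),
    letter = rep(x$letters, x$k),
    probability = as.vector(x$prob),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
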