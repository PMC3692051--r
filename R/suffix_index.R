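# Generalized suffix tree index and k-mer enumeration. The tree is built in
# C++ with Ukkonen's algorithm over the integer-encoded concatenation of the
# sequences, one unique terminator per sequence.

.encode_sequences <- function(x) {
  letters <- alphabet_letters(x$alphabet, "all")
  n_core <- length(alphabet_letters(x$alphabet, "core"))
  n_letters <- length(letters)
  chars <- strsplit(x$seq, "", fixed = TRUE)
  lens <- nchar(x$seq)
  starts <- c(0L, cumsum(lens + 1L))[seq_len(x$N)]  # 0-based global starts
  text <- integer(x$total_chars + x$N)
  off <- 1L
  for (i in seq_len(x$N)) {
    code <- match(chars[[i]], letters) - 1L
    text[off:(off + lens[i] - 1L)] <- code
    text[off + lens[i]] <- n_letters + i - 1L  # terminator, unique per sequence
    off <- off + lens[i] + 1L
  }
  list(text = text, letters = letters, n_core = n_core,
       n_letters = n_letters, starts = starts, lens = lens)
}

#' Build a generalized suffix tree over a ranked sequence list
#'
#' Every suffix of every sequence corresponds to exactly one root-to-leaf
#' path; leaves carry (sequence, offset) occurrence information. Construction
#' is Ukkonen's online algorithm, linear in the total indexed length M
#' (sequence characters plus one terminator per sequence).
#'
#' @param x A [ranked_seqs()] object.
#' @return An object of class `suffix_tree`. Its `stats` field reports the
#'   indexed length `M`, node and leaf counts, and the construction `work`
#'   (inner-loop steps), which supports empirical linearity checks.
#' @export
build_suffix_tree <- function(x) {
  stopifnot(inherits(x, "ranked_seqs"))
  enc <- .encode_sequences(x)
  ptr <- .gst_build_cpp(enc$text, enc$n_core, enc$n_letters,
                        enc$starts, enc$lens)
  structure(
    list(ptr = ptr, seqs = x, letters = enc$letters, n_core = enc$n_core,
         starts = enc$starts, stats = .gst_stats_cpp(ptr)),
    class = "suffix_tree"
  )
}

#' @export
print.suffix_tree <- function(x, ...) {
  s <- x$stats
  cat("generalized suffix tree: M =", s$M, "symbols,",
      s$n_nodes, "nodes,", s$n_leaves, "leaves\n")
  invisible(x)
}

.empty_kmer_set <- function() {
  structure(list(word = character(0), k = integer(0),
                 occ = list(), hits = list()),
            class = "kmer_set")
}

#' Enumerate distinct k-mers from a suffix tree
#'
#' Yields every distinct word of each length in `[k_min, k_max]` that occurs
#' in at least one sequence, exactly once per length, with its complete
#' occurrence list. Words containing ambiguity letters, or windows that
#' would cross a sequence boundary, are never produced.
#'
#' @param tree A [build_suffix_tree()] result.
#' @param k_min,k_max Word length range. Lengths exceeding every sequence
#'   simply yield nothing.
#' @return An object of class `kmer_set`: parallel fields `word` (character),
#'   `k` (integer), `occ` (list of two-column integer matrices `seq`, `pos`,
#'   with 1-based sequence ranks and 0-based offsets) and `hits` (list of
#'   sorted unique sequence ranks containing the word).
#' @export
enumerate_kmers <- function(tree, k_min, k_max = k_min) {
  stopifnot(inherits(tree, "suffix_tree"))
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (k_min < 1L || k_max < k_min)
    stop("need 1 <= k_min <= k_max")
  words <- character(0); ks <- integer(0)
  occ <- list(); hits <- list()
  for (k in k_min:k_max) {
    res <- .gst_enumerate_cpp(tree$ptr, k, tree$letters)
    if (length(res$word) == 0L) next
    grp <- rep.int(seq_along(res$word), res$n_occ)
    seq_split <- split(res$occ_seq, grp)
    pos_split <- split(res$occ_pos, grp)
    occ_k <- mapply(function(s, p) {
      o <- order(s, p)
      cbind(seq = s[o], pos = p[o])
    }, seq_split, pos_split, SIMPLIFY = FALSE, USE.NAMES = FALSE)
    hits_k <- lapply(occ_k, function(m) unique(m[, 1L]))
    words <- c(words, res$word)
    ks <- c(ks, rep.int(k, length(res$word)))
    occ <- c(occ, occ_k)
    hits <- c(hits, hits_k)
  }
  structure(list(word = words, k = ks, occ = occ, hits = hits),
            class = "kmer_set")
}

#' Naive sliding-window k-mer enumeration
#'
#' Reference enumeration by direct window extraction, O(N * L * k). Produces
#' the same `kmer_set` structure as [enumerate_kmers()]; used as the
#' correctness-first fallback and as the comparison path for the suffix
#' tree.
#'
#' @param x A [ranked_seqs()] object.
#' @param k_min,k_max Word length range.
#' @return A `kmer_set`; see [enumerate_kmers()].
#' @export
sliding_window_kmers <- function(x, k_min, k_max = k_min) {
  stopifnot(inherits(x, "ranked_seqs"))
  core <- alphabet_letters(x$alphabet, "core")
  word_re <- paste0("^[", paste(core, collapse = ""), "]+$")
  words <- character(0); ks <- integer(0)
  occ <- list(); hits <- list()
  for (k in k_min:k_max) {
    ws <- character(0); ss <- integer(0); ps <- integer(0)
    for (i in seq_len(x$N)) {
      L <- nchar(x$seq[i])
      if (L < k) next
      st <- seq_len(L - k + 1L)
      w <- substring(x$seq[i], st, st + k - 1L)
      keep <- grepl(word_re, w)
      ws <- c(ws, w[keep])
      ss <- c(ss, rep.int(i, sum(keep)))
      ps <- c(ps, st[keep] - 1L)
    }
    if (!length(ws)) next
    o <- order(ws, ss, ps, method = "radix")
    ws <- ws[o]; ss <- ss[o]; ps <- ps[o]
    grp <- match(ws, unique(ws))
    uw <- unique(ws)
    occ_k <- lapply(split(seq_along(ws), grp), function(ix)
      cbind(seq = ss[ix], pos = ps[ix]))
    names(occ_k) <- NULL
    words <- c(words, uw)
    ks <- c(ks, rep.int(k, length(uw)))
    occ <- c(occ, occ_k)
    hits <- c(hits, lapply(occ_k, function(m) unique(m[, 1L])))
  }
  structure(list(word = words, k = ks, occ = occ, hits = hits),
            class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat("kmer_set:", length(x$word), "distinct words",
      if (length(x$k)) paste0("(k in ", min(x$k), "..", max(x$k), ")"),
      "\n")
  invisible(x)
}
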