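# Candidate scanning: label vectors from k-mer occurrences, double-strand
# canonicalization, per-candidate mHG scoring and exact p-values, and the
# significance filter across candidates.

.rc_maps <- list(
  DNA = c(from = "ACGTNRYSWKMBDHV", to = "TGCANYRSWMKVHDB"),
  RNA = c(from = "ACGUNRYSWKMBDHV", to = "UGCANYRSWMKVHDB")
)

#' Reverse complement
#'
#' Watson-Crick reverse complement for DNA or RNA words (RNA pairs U with
#' A). IUPAC ambiguity codes are complemented accordingly. Calling this on
#' the protein alphabet is an error.
#'
#' @param words Character vector of words.
#' @param alphabet `"DNA"` or `"RNA"`.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("AAGG")  # "CCTT"
#' reverse_complement("ACGU", "RNA")  # "ACGU" (palindrome)
#' @export
reverse_complement <- function(words, alphabet = c("DNA", "RNA")) {
  if (identical(alphabet, "PROTEIN") || identical(alphabet, "protein"))
    stop("reverse complement is undefined for the protein alphabet")
  alphabet <- match.arg(alphabet)
  mp <- .rc_maps[[alphabet]]
  comp <- chartr(mp[["from"]], mp[["to"]], toupper(words))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Binary label vector for a set of hit ranks
#'
#' Presence semantics: position `i` is one iff the rank-`i` sequence
#' contains at least one occurrence (occurrence multiplicity does not
#' matter).
#'
#' @param hit_ranks Integer ranks of the sequences containing the word.
#' @param N Total number of sequences.
#' @return Integer 0/1 vector of length `N`.
#' @export
kmer_label_vector <- function(hit_ranks, N) {
  v <- integer(N)
  v[hit_ranks] <- 1L
  v
}

# Merge a kmer_set of one k into canonical double-strand candidates: a word
# and its reverse complement form one candidate keyed by the
# lexicographically smaller of the pair; palindromes stand alone. Occurrence
# matrices gain a strand column (0 = canonical orientation, 1 = reverse).
.canonicalize_kmers <- function(ks, alphabet) {
  if (!length(ks$word))
    return(list(word = character(0), rc = character(0),
                occ = list(), hits = list()))
  rcw <- reverse_complement(ks$word, alphabet)
  # uppercase single-case letters order identically across locales
  canon <- ifelse(ks$word <= rcw, ks$word, rcw)
  uc <- sort(unique(canon), method = "radix")
  idx <- split(seq_along(canon), factor(canon, levels = uc))
  occ <- vector("list", length(uc))
  hits <- vector("list", length(uc))
  for (j in seq_along(uc)) {
    parts <- lapply(idx[[j]], function(i) {
      strand <- if (ks$word[i] == uc[j]) 0L else 1L
      cbind(ks$occ[[i]], strand = rep.int(strand, nrow(ks$occ[[i]])))
    })
    m <- do.call(rbind, parts)
    m <- m[order(m[, "seq"], m[, "pos"], m[, "strand"]), , drop = FALSE]
    # palindromes appear once on the forward strand
    if (length(idx[[j]]) == 1L && ks$word[idx[[j]]] == rcw[idx[[j]]])
      m[, "strand"] <- 0L
    occ[[j]] <- m
    hits[[j]] <- sort(unique(m[, "seq"]))
  }
  list(word = uc, rc = reverse_complement(uc, alphabet),
       occ = occ, hits = hits)
}

.check_alpha <- function(alpha, bounds = c(1e-15, 1e-2)) {
  if (!is.numeric(alpha) || length(alpha) != 1L ||
      alpha < bounds[1L] || alpha > bounds[2L])
    stop("alpha must lie in [", bounds[1L], ", ", bounds[2L], "]")
  alpha
}

.check_k_range <- function(k_min, k_max, bounds = c(4L, 20L)) {
  if (k_min < bounds[1L] || k_max > bounds[2L] || k_min > k_max)
    stop("k range must satisfy ", bounds[1L], " <= k_min <= k_max <= ",
         bounds[2L])
  c(as.integer(k_min), as.integer(k_max))
}

.empty_records <- function() {
  data.frame(kmer = character(0), reverse_complement = character(0),
             k = integer(0), N = integer(0), B = integer(0),
             n = integer(0), b = integer(0), enrichment = numeric(0),
             pvalue = numeric(0), corrected_pvalue = numeric(0),
             rank = integer(0), stringsAsFactors = FALSE)
}

# Shared significance filtering given per-candidate raw p-values. Bonferroni
# multiplies by the number of distinct candidates evaluated at that k.
.filter_records <- function(df, alpha, correction, threshold_on) {
  if (!nrow(df)) return(df)
  df$corrected_pvalue <- if (correction == "bonferroni")
    pmin(1, df$pvalue * df$m_k) else df$pvalue
  crit <- if (threshold_on == "corrected") df$corrected_pvalue else df$pvalue
  df <- df[crit <= alpha, , drop = FALSE]
  df
}

.sort_records <- function(df) {
  if (!nrow(df)) {
    df$rank <- integer(0)
    return(df)
  }
  o <- order(df$corrected_pvalue, df$pvalue, df$kmer, method = "radix")
  df <- df[o, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Scan a ranked list for rank-imbalanced k-mers
#'
#' Enumerates every k-mer present in the input (via the suffix tree), builds
#' its presence label vector over the ranking, scores it with the mHG
#' statistic, computes the exact mHG p-value, applies a Bonferroni
#' correction across the candidates evaluated at each word length, and
#' returns the records passing the significance threshold. In double-strand
#' mode a word and its reverse complement are one candidate, keyed by the
#' lexicographically smaller of the pair.
#'
#' Defaults mirror the published web service: word lengths 5-10 in
#' single-strand mode, 10 in double-strand mode, threshold `1e-6`
#' (adjustable within `[1e-15, 1e-2]`), lengths bounded to `[4, 20]`.
#'
#' @param x A [ranked_seqs()] object.
#' @param k_min,k_max Word length range; `NULL` selects the mode default.
#' @param strand `"single"` or `"double"` (double requires DNA or RNA).
#' @param alpha Significance threshold applied to the (by default
#'   corrected) p-value.
#' @param correction `"bonferroni"` (over candidates per length) or
#'   `"none"`.
#' @param threshold_on Apply `alpha` to the `"corrected"` or `"raw"`
#'   p-value.
#' @return An object of class `motif_scan`; its `records` field is a
#'   data frame with one row per reported motif (columns `kmer`,
#'   `reverse_complement`, `k`, `N`, `B`, `n`, `b`, `enrichment`, `pvalue`,
#'   `corrected_pvalue`, `rank`), sorted by corrected p-value then word.
#' @export
scan_motifs <- function(x, k_min = NULL, k_max = NULL,
                        strand = c("single", "double"), alpha = 1e-6,
                        correction = c("bonferroni", "none"),
                        threshold_on = c("corrected", "raw")) {
  stopifnot(inherits(x, "ranked_seqs"))
  strand <- match.arg(strand)
  correction <- match.arg(correction)
  threshold_on <- match.arg(threshold_on)
  .check_alpha(alpha)
  if (is.null(k_min)) k_min <- if (strand == "double") 10L else 5L
  if (is.null(k_max)) k_max <- if (strand == "double") 10L else 10L
  kr <- .check_k_range(k_min, k_max)
  if (strand == "double" && x$alphabet == "PROTEIN")
    stop("double-strand mode requires a nucleic-acid alphabet")
  tree <- build_suffix_tree(x)
  N <- x$N
  rows <- list()
  index <- list()
  counts <- integer(0)
  for (k in kr[1L]:kr[2L]) {
    ks <- enumerate_kmers(tree, k, k)
    cand <- if (strand == "double") {
      .canonicalize_kmers(ks, x$alphabet)
    } else {
      list(word = ks$word, rc = rep(NA_character_, length(ks$word)),
           occ = ks$occ, hits = ks$hits)
    }
    m_k <- length(cand$word)
    index[[as.character(k)]] <- cand
    counts[as.character(k)] <- m_k
    if (m_k == 0L) next
    sc <- .mhg_score_batch_cpp(cand$hits, N)
    # p >= score, so candidates whose (corrected) score already exceeds
    # alpha cannot pass; skip their p-value DP
    bound <- if (correction == "bonferroni" && threshold_on == "corrected")
      sc[, "log_score"] + log(m_k) else sc[, "log_score"]
    sel <- which(bound <= log(alpha))
    if (!length(sel)) next
    pv <- vapply(sel, function(i)
      .mhg_pvalue_cpp(sc[i, "log_score"], N, length(cand$hits[[i]])),
      numeric(1))
    B <- lengths(cand$hits)[sel]
    n <- as.integer(sc[sel, "n_star"])
    b <- as.integer(sc[sel, "b_star"])
    df <- data.frame(
      kmer = cand$word[sel], reverse_complement = cand$rc[sel],
      k = rep.int(k, length(sel)), N = rep.int(N, length(sel)),
      B = as.integer(B), n = n, b = b,
      enrichment = (b / n) / (B / N),
      pvalue = pv, m_k = rep.int(m_k, length(sel)),
      stringsAsFactors = FALSE
    )
    rows[[as.character(k)]] <- .filter_records(df, alpha, correction,
                                               threshold_on)
  }
  df <- if (length(rows)) do.call(rbind, rows) else .empty_records()
  df$m_k <- NULL
  df <- .sort_records(df)
  structure(
    list(records = df, seqs = x, strand = strand, alpha = alpha,
         k_min = kr[1L], k_max = kr[2L], correction = correction,
         threshold_on = threshold_on, mode = "ranked",
         n_fixed = NA_integer_, candidate_counts = counts, index = index),
    class = "motif_scan"
  )
}

#' Scan a target set against a background set
#'
#' Two-set mode: the statistical universe is the target block followed by
#' the background block and the cutoff is fixed at the target size, so each
#' candidate is tested with a plain hypergeometric tail (no minimization
#' over partitions). Correction and filtering are as in [scan_motifs()].
#'
#' @param x A [two_set_input()] object.
#' @inheritParams scan_motifs
#' @return A `motif_scan` object (`mode = "two_set"`).
#' @export
scan_two_sets <- function(x, k_min = NULL, k_max = NULL,
                          strand = c("single", "double"), alpha = 1e-6,
                          correction = c("bonferroni", "none"),
                          threshold_on = c("corrected", "raw")) {
  stopifnot(inherits(x, "two_set_input"))
  strand <- match.arg(strand)
  correction <- match.arg(correction)
  threshold_on <- match.arg(threshold_on)
  .check_alpha(alpha)
  combined <- .combine_two_sets(x)
  n_fixed <- x$target$N
  if (is.null(k_min)) k_min <- if (strand == "double") 10L else 5L
  if (is.null(k_max)) k_max <- if (strand == "double") 10L else 10L
  kr <- .check_k_range(k_min, k_max)
  if (strand == "double" && combined$alphabet == "PROTEIN")
    stop("double-strand mode requires a nucleic-acid alphabet")
  tree <- build_suffix_tree(combined)
  N <- combined$N
  rows <- list()
  index <- list()
  counts <- integer(0)
  for (k in kr[1L]:kr[2L]) {
    ks <- enumerate_kmers(tree, k, k)
    cand <- if (strand == "double") {
      .canonicalize_kmers(ks, combined$alphabet)
    } else {
      list(word = ks$word, rc = rep(NA_character_, length(ks$word)),
           occ = ks$occ, hits = ks$hits)
    }
    m_k <- length(cand$word)
    index[[as.character(k)]] <- cand
    counts[as.character(k)] <- m_k
    if (m_k == 0L) next
    B <- lengths(cand$hits)
    b <- vapply(cand$hits, function(h) sum(h <= n_fixed), integer(1))
    pv <- .hgt_fixed_batch_cpp(b, B, N, n_fixed)
    df <- data.frame(
      kmer = cand$word, reverse_complement = cand$rc,
      k = rep.int(k, m_k), N = rep.int(N, m_k),
      B = as.integer(B), n = rep.int(n_fixed, m_k), b = as.integer(b),
      enrichment = (b / n_fixed) / (B / N),
      pvalue = pv, m_k = rep.int(m_k, m_k),
      stringsAsFactors = FALSE
    )
    rows[[as.character(k)]] <- .filter_records(df, alpha, correction,
                                               threshold_on)
  }
  df <- if (length(rows)) do.call(rbind, rows) else .empty_records()
  df$m_k <- NULL
  df <- .sort_records(df)
  structure(
    list(records = df, seqs = combined, strand = strand, alpha = alpha,
         k_min = kr[1L], k_max = kr[2L], correction = correction,
         threshold_on = threshold_on, mode = "two_set",
         n_fixed = n_fixed, candidate_counts = counts, index = index),
    class = "motif_scan"
  )
}

#' @export
print.motif_scan <- function(x, ...) {
  cat("motif_scan (", x$mode, ", ", x$strand, "-strand, k ", x$k_min, "..",
      x$k_max, ", alpha ", format(x$alpha), "): ",
      nrow(x$records), " significant motif(s) among ",
      sum(x$candidate_counts), " candidates\n", sep = "")
  if (nrow(x$records)) print(head(x$records, 10L))
  invisible(x)
}
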