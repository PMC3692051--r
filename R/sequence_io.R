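# Ranked-list and target/background FASTA input. The record order of the
# file is the ranking: record 1 is the most interesting sequence.

.alphabets <- list(
  DNA = list(
    core  = c("A", "C", "G", "T"),
    ambig = c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
  ),
  RNA = list(
    core  = c("A", "C", "G", "U"),
    ambig = c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
  ),
  PROTEIN = list(
    core  = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
    ambig = c("X", "B", "Z", "J")
  )
)

#' Letters of a sequence alphabet
#'
#' @param alphabet One of `"DNA"`, `"RNA"`, `"PROTEIN"`.
#' @param what `"core"` for the unambiguous letters, `"ambig"` for the
#'   accepted ambiguity codes, `"all"` for both.
#' @return Character vector of single letters.
#' @export
alphabet_letters <- function(alphabet = c("DNA", "RNA", "PROTEIN"),
                             what = c("all", "core", "ambig")) {
  alphabet <- match.arg(alphabet)
  what <- match.arg(what)
  a <- .alphabets[[alphabet]]
  switch(what, core = a$core, ambig = a$ambig, all = c(a$core, a$ambig))
}

# Deterministic, order-independent inference over the set of letters used.
# Only N is treated as an ambiguity code at inference time: the other IUPAC
# nucleotide codes are all valid amino-acid letters, so a sequence using them
# is classified as protein unless the caller supplies an explicit alphabet.
.infer_alphabet <- function(letters_used) {
  u <- sort(unique(letters_used))
  if (all(u %in% c("A", "C", "G", "T", "N"))) return("DNA")
  if (all(u %in% c("A", "C", "G", "U", "N")) && "U" %in% u) return("RNA")
  "PROTEIN"
}

#' Construct a ranked sequence list
#'
#' The workhorse container of the package: an ordered set of sequences whose
#' index is the rank (element 1 = rank 1 = top of the list). Sequences are
#' uppercased and validated against the (inferred or declared) alphabet plus
#' its ambiguity codes.
#'
#' @param sequences Character vector of sequences, in rank order.
#' @param ids Optional character vector of identifiers; duplicates are made
#'   unique with a warning.
#' @param alphabet Optional alphabet; inferred from the letters used when
#'   `NULL`. Inference calls a set DNA when it only uses ACGT plus N, RNA
#'   when it uses U (and no T), and protein otherwise.
#' @param max_sequences,max_chars Size limits (defaults 40000 sequences and
#'   4e6 residues); exceeding either is an error naming the limit.
#' @return An object of class `ranked_seqs` with fields `id`, `seq`,
#'   `alphabet`, `N` and `total_chars`.
#' @export
ranked_seqs <- function(sequences, ids = NULL, alphabet = NULL,
                        max_sequences = 40000L, max_chars = 4000000L) {
  if (!is.character(sequences) || length(sequences) == 0L)
    stop("`sequences` must be a non-empty character vector")
  if (is.null(ids)) ids <- sprintf("seq_%d", seq_along(sequences))
  ids <- as.character(ids)
  if (length(ids) != length(sequences))
    stop("`ids` and `sequences` lengths differ")
  if (anyDuplicated(ids)) {
    warning("duplicate sequence ids; making them unique")
    ids <- make.unique(ids, sep = "_dup")
  }
  seqs <- toupper(sequences)
  nc <- nchar(seqs)
  if (any(nc == 0L))
    stop("empty sequence at rank ", which(nc == 0L)[1L],
         " (id '", ids[which(nc == 0L)[1L]], "')")
  N <- length(seqs)
  if (N > max_sequences)
    stop("too many sequences: ", N, " exceeds the limit of ",
         max_sequences, " sequences")
  total <- sum(nc)
  if (total > max_chars)
    stop("input too large: ", total, " characters exceed the limit of ",
         max_chars, " characters")
  letters_used <- unique(unlist(strsplit(seqs, "", fixed = TRUE),
                                use.names = FALSE))
  if (is.null(alphabet)) {
    alphabet <- .infer_alphabet(letters_used)
  } else {
    alphabet <- match.arg(alphabet, c("DNA", "RNA", "PROTEIN"))
  }
  allowed <- alphabet_letters(alphabet, "all")
  bad <- setdiff(letters_used, allowed)
  if (length(bad)) {
    hit <- which(vapply(
      strsplit(seqs, "", fixed = TRUE),
      function(ch) any(ch %in% bad), logical(1)
    ))[1L]
    stop("sequence '", ids[hit], "' (rank ", hit, ") contains letters ",
         "outside the ", alphabet, " alphabet: ",
         paste(sort(bad), collapse = ", "))
  }
  structure(
    list(id = ids, seq = unname(seqs), alphabet = alphabet,
         N = N, total_chars = total),
    class = "ranked_seqs"
  )
}

#' @export
print.ranked_seqs <- function(x, ...) {
  cat("ranked_seqs: ", x$N, " ", x$alphabet, " sequence(s), ",
      x$total_chars, " residues\n", sep = "")
  show <- head(seq_len(x$N), 3L)
  for (i in show)
    cat(sprintf("  [rank %d] %s (%d nt/aa)\n", i, x$id[i], nchar(x$seq[i])))
  if (x$N > 3L) cat("  ...\n")
  invisible(x)
}

#' Read a ranked multi-FASTA file
#'
#' File order is the rank order (first record = rank 1). Headers are
#' truncated at the first whitespace to form ids.
#'
#' @param path Path to a multi-FASTA file.
#' @param alphabet Optional alphabet hint; see [ranked_seqs()].
#' @inheritParams ranked_seqs
#' @return A [ranked_seqs()] object.
#' @export
read_ranked_fasta <- function(path, alphabet = NULL,
                              max_sequences = 40000L, max_chars = 4000000L) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path)
  x <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("cannot parse FASTA file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(x) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(x))
  ranked_seqs(as.character(x), ids = ids, alphabet = alphabet,
              max_sequences = max_sequences, max_chars = max_chars)
}

#' Write a ranked sequence list to FASTA
#'
#' Round-trips exactly with [read_ranked_fasta()]: ids, order and sequences
#' are preserved.
#'
#' @param x A `ranked_seqs` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ranked_fasta <- function(x, path) {
  stopifnot(inherits(x, "ranked_seqs"))
  set <- Biostrings::BStringSet(setNames(x$seq, x$id))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read target and background FASTA files
#'
#' For the two-set mode: motifs are sought in the target set against the
#' background set. The combined universe for statistics is the target block
#' followed by the background block.
#'
#' @param target_path,background_path Paths to the two multi-FASTA files.
#' @param alphabet Optional alphabet hint applied to both files.
#' @inheritParams ranked_seqs
#' @return An object of class `two_set_input` with fields `target` and
#'   `background` (both `ranked_seqs` of one shared alphabet).
#' @export
read_two_sets <- function(target_path, background_path, alphabet = NULL,
                          max_sequences = 40000L, max_chars = 4000000L) {
  tgt <- read_ranked_fasta(target_path, alphabet = alphabet,
                           max_sequences = max_sequences,
                           max_chars = max_chars)
  bg <- read_ranked_fasta(background_path, alphabet = alphabet,
                          max_sequences = max_sequences,
                          max_chars = max_chars)
  two_set_input(tgt, bg)
}

#' Pair a target and a background sequence set
#'
#' @param target,background `ranked_seqs` objects over one alphabet.
#' @return A `two_set_input` object.
#' @export
two_set_input <- function(target, background) {
  stopifnot(inherits(target, "ranked_seqs"),
            inherits(background, "ranked_seqs"))
  if (target$alphabet != background$alphabet)
    stop("alphabet mismatch: target is ", target$alphabet,
         " but background is ", background$alphabet)
  structure(list(target = target, background = background),
            class = "two_set_input")
}

#' @export
print.two_set_input <- function(x, ...) {
  cat("two_set_input (", x$target$alphabet, "): ",
      x$target$N, " target + ", x$background$N, " background sequences\n",
      sep = "")
  invisible(x)
}

# Combined universe: target block on top, ids namespaced by set so that
# overlapping ids across the two files stay distinct.
.combine_two_sets <- function(x) {
  stopifnot(inherits(x, "two_set_input"))
  combined <- ranked_seqs(
    c(x$target$seq, x$background$seq),
    ids = c(paste0("target|", x$target$id),
            paste0("background|", x$background$id)),
    alphabet = x$target$alphabet
  )
  attr(combined, "n_target") <- x$target$N
  combined
}
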