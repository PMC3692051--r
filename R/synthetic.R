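# Synthetic inputs with known ground truth: planted-motif ranked lists and
# pure-null lists. These define the study conditions for the recovery and
# type-I-error tests.

# run code under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.random_seqs <- function(n, len, letters, prob) {
  vapply(seq_len(n), function(i)
    paste(sample(letters, len, replace = TRUE, prob = prob), collapse = ""),
    character(1))
}

#' Specification for a planted-motif fixture
#'
#' Describes a ranked list of iid background sequences in which each
#' sequence of the top block independently receives one planted copy of a
#' motif word (position uniform, optional per-letter mutation, optional
#' reverse-complement orientation). Defaults are the package's reference
#' study conditions: one 8-mer planted intact in the top 30 of 200 uniform
#' DNA sequences of length 100.
#'
#' @param motifs Word(s) to plant; when several, each planted copy picks
#'   one uniformly at random.
#' @param n_sequences,length List size and per-sequence length.
#' @param n_plant Top-block size receiving plants.
#' @param plant_prob Per-sequence planting probability within the top
#'   block.
#' @param mutation_rate Per-letter probability of mutating a planted copy
#'   to a different letter.
#' @param background Named letter probabilities (default uniform over the
#'   core alphabet).
#' @param orientation `"forward"` plants the word as given; `"random"`
#'   flips a fair coin between the word and its reverse complement (nucleic
#'   alphabets only).
#' @param alphabet Sequence alphabet.
#' @param seed Integer seed; fixing it makes the fixture byte-identical
#'   across runs.
#' @return An object of class `plant_spec`.
#' @export
plant_spec <- function(motifs = "TGACGTCA", n_sequences = 200L,
                       length = 100L, n_plant = 30L, plant_prob = 1,
                       mutation_rate = 0, background = NULL,
                       orientation = c("forward", "random"),
                       alphabet = "DNA", seed = NULL) {
  orientation <- match.arg(orientation)
  alphabet <- match.arg(alphabet, c("DNA", "RNA", "PROTEIN"))
  core <- alphabet_letters(alphabet, "core")
  if (is.null(background))
    background <- setNames(rep(1 / length(core), length(core)), core)
  if (!setequal(names(background), core))
    stop("background must name every core letter of the alphabet")
  if (abs(sum(background) - 1) > 1e-8)
    stop("background probabilities must sum to 1")
  motifs <- toupper(motifs)
  if (any(!vapply(strsplit(motifs, "", fixed = TRUE),
                  function(ch) all(ch %in% core), logical(1))))
    stop("motif words must use only core alphabet letters")
  if (max(nchar(motifs)) > length)
    stop("motif longer than the sequences")
  if (n_plant > n_sequences) stop("n_plant must be <= n_sequences")
  if (plant_prob < 0 || plant_prob > 1 || mutation_rate < 0 ||
      mutation_rate > 1)
    stop("plant_prob and mutation_rate must lie in [0, 1]")
  if (orientation == "random" && alphabet == "PROTEIN")
    stop("random orientation needs a nucleic-acid alphabet")
  structure(
    list(motifs = motifs, n_sequences = as.integer(n_sequences),
         length = as.integer(length), n_plant = as.integer(n_plant),
         plant_prob = plant_prob, mutation_rate = mutation_rate,
         background = background[core], orientation = orientation,
         alphabet = alphabet, seed = seed),
    class = "plant_spec"
  )
}

#' Generate a planted-motif ranked list
#'
#' @param spec A [plant_spec()].
#' @return A list of class `planted_fixture`: `seqs` (a [ranked_seqs()]
#'   object) and `truth`, a data frame of planted occurrences (`seq` rank,
#'   0-based `pos`, source `word`, actually `planted` string after mutation
#'   and orientation, `strand`).
#' @export
generate_planted <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  core <- alphabet_letters(spec$alphabet, "core")
  .with_seed(spec$seed, {
    seqs <- .random_seqs(spec$n_sequences, spec$length, core,
                         spec$background)
    truth <- list()
    for (i in seq_len(spec$n_plant)) {
      if (runif(1) >= spec$plant_prob) next
      w <- if (length(spec$motifs) > 1L)
        spec$motifs[sample.int(length(spec$motifs), 1L)] else spec$motifs
      ch <- strsplit(w, "", fixed = TRUE)[[1L]]
      if (spec$mutation_rate > 0) {
        mut <- runif(length(ch)) < spec$mutation_rate
        for (j in which(mut))
          ch[j] <- sample(setdiff(core, ch[j]), 1L)
      }
      planted <- paste(ch, collapse = "")
      strand <- "+"
      if (spec$orientation == "random" && runif(1) < 0.5) {
        planted <- reverse_complement(planted, spec$alphabet)
        strand <- "-"
      }
      kw <- nchar(planted)
      pos0 <- sample.int(spec$length - kw + 1L, 1L) - 1L
      substr(seqs[i], pos0 + 1L, pos0 + kw) <- planted
      truth[[length(truth) + 1L]] <-
        data.frame(seq = i, pos = pos0, word = w, planted = planted,
                   strand = strand, stringsAsFactors = FALSE)
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(seq = integer(0), pos = integer(0), word = character(0),
                 planted = character(0), strand = character(0),
                 stringsAsFactors = FALSE)
    structure(
      list(seqs = ranked_seqs(seqs,
                              ids = sprintf("seq_%04d",
                                            seq_len(spec$n_sequences)),
                              alphabet = spec$alphabet),
           truth = truth, spec = spec),
      class = "planted_fixture"
    )
  })
}

#' Generate a null (motif-free) ranked list
#'
#' iid sequences with no planted signal; the negative control for
#' type-I-error checks of the scan.
#'
#' @param n_sequences,length List size and per-sequence length.
#' @param alphabet Sequence alphabet.
#' @param seed Integer seed.
#' @param background Optional named letter probabilities (default uniform).
#' @return A [ranked_seqs()] object.
#' @export
generate_null <- function(n_sequences = 200L, length = 100L,
                          alphabet = "DNA", seed = NULL,
                          background = NULL) {
  n_sequences <- as.integer(n_sequences)
  if (n_sequences < 1L) stop("need at least one sequence")
  alphabet <- match.arg(alphabet, c("DNA", "RNA", "PROTEIN"))
  core <- alphabet_letters(alphabet, "core")
  if (is.null(background))
    background <- setNames(rep(1 / length(core), length(core)), core)
  .with_seed(seed, {
    seqs <- .random_seqs(n_sequences, length, core, background[core])
    ranked_seqs(seqs, ids = sprintf("null_%04d", seq_len(n_sequences)),
                alphabet = alphabet)
  })
}

#' Generate a first-order Markov background list
#'
#' Sequences whose letters follow a first-order Markov chain, for
#' robustness tests against compositional structure that iid backgrounds
#' lack.
#'
#' @param n_sequences,length List size and per-sequence length.
#' @param transition Square stochastic matrix (rows sum to 1) over the core
#'   alphabet, rows/columns in alphabet order.
#' @param alphabet Sequence alphabet.
#' @param seed Integer seed.
#' @return A [ranked_seqs()] object.
#' @export
generate_markov <- function(n_sequences = 200L, length = 100L,
                            transition, alphabet = "DNA", seed = NULL) {
  alphabet <- match.arg(alphabet, c("DNA", "RNA", "PROTEIN"))
  core <- alphabet_letters(alphabet, "core")
  stopifnot(is.matrix(transition),
            nrow(transition) == length(core),
            ncol(transition) == length(core),
            all(abs(rowSums(transition) - 1) < 1e-8))
  .with_seed(seed, {
    seqs <- vapply(seq_len(n_sequences), function(i) {
      s <- integer(length)
      s[1L] <- sample.int(length(core), 1L)
      for (j in seq_len(length - 1L))
        s[j + 1L] <- sample.int(length(core), 1L,
                                prob = transition[s[j], ])
      paste(core[s], collapse = "")
    }, character(1))
    ranked_seqs(seqs, ids = sprintf("mkv_%04d", seq_len(n_sequences)),
                alphabet = alphabet)
  })
}

#' Write a fixture to disk
#'
#' FASTA for the sequences plus a JSON truth file listing the planted
#' occurrences (empty array for null fixtures).
#'
#' @param x A `planted_fixture` or `ranked_seqs` object.
#' @param dir Output directory (created if needed).
#' @param name Basename for `<name>.fa` and `<name>.truth.json`.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_fixture <- function(x, dir, name = "fixture") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, paste0(name, ".fa"))
  js <- file.path(dir, paste0(name, ".truth.json"))
  if (inherits(x, "planted_fixture")) {
    write_ranked_fasta(x$seqs, fa)
    jsonlite::write_json(x$truth, js, dataframe = "rows")
  } else {
    write_ranked_fasta(x, fa)
    jsonlite::write_json(list(), js)
  }
  invisible(c(fasta = fa, truth = js))
}
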