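---
title: "Rank-imbalanced motif discovery: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-imbalanced motif discovery: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(rankmotif)
```

## The problem

High-throughput binding assays (ChIP-seq for protein–DNA, CLIP variants for
protein–RNA, proteomic screens for protein–protein recognition) do not
produce a clean "bound" set: they produce a *ranked list* of sequences,
ordered by binding strength or measurement confidence. A motif that drives
the measured recognition should concentrate near the top of that list, but
the right place to cut "top" from "rest" is unknown in advance — it differs
between factors, antibodies and experiments. `rankmotif` searches for
*rank-imbalanced* words: exact k-mers whose presence concentrates at the top
of the ranking more strongly than any fixed-cutoff analysis would assume,
with the cutoff chosen by the data.

## The mHG statistic

For a candidate word, label sequence `i` with
`λ_i = 1` if it contains at least one occurrence of the word (presence, not
counts), giving a binary vector `λ` over the `N` ranked sequences with
`B = Σλ_i` ones. For a prefix of size `n` containing `b_n` ones, the
hypergeometric tail

    HGT(b; N, B, n) = P(X ≥ b),  X ~ Hypergeometric(N, B, n)

is the chance of seeing that many motif-bearing sequences in the top `n`
under random placement. The minimum hypergeometric (mHG) score is

    s = min over n in 1..N-1 of HGT(b_n; N, B, n)

— the best tail over every top/rest partition induced by the ranking. The
cutoff `n*` attaining the minimum (smallest such `n` on ties) is reported
together with `b* = b_{n*}`, and the enrichment `(b*/n*)/(B/N)` compares
the motif's abundance above the chosen cutoff with its abundance overall.

Minimizing over cutoffs is itself a multiple test, so `s` is not a p-value.
The exact p-value is the probability, under the null that all
`choose(N, B)` placements of the ones are equally likely, of seeing an mHG
score at most `s`. It is computed exactly by a dynamic program over the
`(n, b)` lattice: monotone paths from `(0, 0)` to `(N, B)` are in bijection
with label vectors; every cell whose tail is at most `s` (for `n ≤ N-1`) is
an entry point into the rejection event, and the p-value is the total
weight of paths first touching such a cell.

```{r}
mhg_score(c(1, 1, 0, 0))
mhg_pvalue(1 / 6, N = 4, B = 2)
```

### Numerical choices

* All tails and path weights are held in **log space**; binomial
  coefficients come from cumulative log-factorials. A Stirling-series mode
  (`log_binomials(N, "stirling")`, with the standard downward shift so the
  series is only evaluated at arguments ≥ 10) is provided and validated
  against the exact mode to 1e-6 on the log scale; the exact mode is the
  default because it is cheap at these problem sizes and removes an
  approximation from the statistical path.
* The DP accumulates the **killed path mass** (the event probability)
  directly rather than `1 - surviving/total`. The two are mathematically
  identical — every path either survives or first hits exactly one zeroed
  cell — but the subtraction form loses all precision below ~1e-16, while
  the direct sum keeps full relative precision for the very small p-values
  (1e-30 and beyond) that strong motifs produce. Those tiny values are what
  rank competing motifs and what drives PSSM extension, so they must not
  collapse to zero.
* Cell classification `HGT ≤ s` uses a relative tie tolerance of 1e-10 so
  that the observed configuration's own cell (whose tail equals `s`
  mathematically) is always counted regardless of rounding. Distinct
  hypergeometric tails at the universe sizes involved differ by far more
  than this.
* The minimum over cutoffs is only evaluated at ranks where `λ = 1`:
  appending a zero can only increase the tail, so no minimum is missed.
  Degenerate vectors (`B = 0` or `B = N`) score 1 at `n* = 1`.
* The cutoff range is `1..N-1`: cutting at `N` is the degenerate whole-list
  partition and carries no ranking information.

## Candidate enumeration: the generalized suffix tree

All candidate words come from a generalized suffix tree over the input,
built with Ukkonen's online algorithm on the integer-encoded concatenation
of the sequences with one unique terminator symbol per sequence. Every
distinct word of length `k` is a depth-`k` locus in the tree; the leaves
below it are exactly its occurrences, so enumeration with full occurrence
lists is a single traversal per `k`. Construction is linear in the total
indexed length `M` (the tree object records an inner-loop work counter,
which the test suite uses for an empirical linearity check — about three
steps per character, flat in `M`). Words containing ambiguity letters
(`N` and friends for nucleic alphabets, `X/B/Z/J` for protein) are accepted
in the *input* but never become candidates: exact words are the unit of
testing, and ambiguity codes have no occurrence semantics here. A naive
sliding-window enumerator (`sliding_window_kmers()`) provides the same
interface as a correctness reference and fallback.

## Strand logic

In double-strand mode (DNA/RNA) a word and its reverse complement are one
biological entity: the candidate is keyed by the lexicographically smaller
of the pair, a sequence counts as a hit if it contains either orientation,
and palindromes are their own canonical form, counted and reported once on
the forward strand. Reverse-complementing every input sequence therefore
leaves the reported canonical motifs and their p-values exactly unchanged
— a symmetry the acceptance tests assert literally.

## The scan and multiple testing

`scan_motifs()` scores every enumerated candidate and keeps those passing
the significance threshold `alpha` (default 1e-6, accepted range 1e-15 to
1e-2). Across candidates we apply a **Bonferroni correction over the number
of distinct candidates actually evaluated at each word length** — a
conservative, deterministic choice that keeps the reported values
interpretable as familywise error bounds; raw mHG p-values are retained in
the output, and `threshold_on = "raw"` applies the threshold to them
instead. When a range of lengths is searched, all lengths compete in one
list ordered by corrected p-value (then raw p-value, then word), so the
most significant motif need not be the longest. Because the exact p-value
is never smaller than the score, candidates whose score already fails the
(corrected) threshold skip the DP entirely; this prunes almost the whole
null bulk and keeps a 200-sequence scan under a second.

In two-set mode (`scan_two_sets()`) the universe is the target block
followed by the background block and the cutoff is *fixed* at the target
size, so each candidate is tested with a plain hypergeometric tail — no
minimization, no mHG correction — matching the situation where the user
already has a meaningful target/background split.

## PSSM extension

The best seeds (default 50, by corrected p-value) are grown into PSSMs.
From a seed word, every Hamming-distance-1 neighbor *of any current member*
that occurs in the input is evaluated by recomputing the member set's joint
label vector (a sequence counts if it contains any member) and its
enrichment p-value; the single best neighbor is adopted if its joint
p-value is strictly lower, and the loop stops at the first step with no
strict improvement. Consequences of this design, where the procedure was
genuinely open:

* adoption is one-at-a-time best-first with deterministic tie-breaks
  (lowest p-value, then lexicographic order), so runs are reproducible;
* because neighbors of *members* are candidates, words at distance ≥ 2
  from the seed can enter, one accepted step at a time;
* the full mHG (including `n*`) is re-optimized for each member set rather
  than frozen at the seed's cutoff — the joint motif is a new hypothesis
  and deserves its own data-driven cutoff;
* termination is guaranteed: the neighbor universe is finite and each
  accepted step strictly decreases the p-value.

Columns are position-wise letter frequencies over all member occurrences
within the top-`n*` block (the enriched region — the logo should portray
the signal, not the background), weighted by occurrence count, with a
pseudocount of 0.01 per letter to avoid degenerate log-odds downstream.
After extension, PSSMs whose member sets share at least half of the
smaller set are near-duplicates (typically the same motif reached from
different seeds) and only the most significant representative is reported.

## Input handling

FASTA is the only input format; record order is the ranking. The alphabet
is inferred when not given: only `N` is treated as an ambiguity code at
inference time because the other IUPAC nucleotide codes are all valid
amino-acid letters — a sequence like `MKWVR` is protein, not a string of
nucleotide wildcards. An explicit `alphabet` argument overrides inference
and unlocks the full IUPAC ambiguity set for validation. Size limits
(40000 sequences, 4e6 characters) are configuration with conventional
defaults, not hard-coded constants. Rank ties are not modeled: file order
is authoritative.

## The synthetic generator and what passing tests mean

`generate_planted()` emulates the one feature the method is about — a word
concentrating at the top of a ranking — under fully controlled conditions:
iid background letters (uniform by default), one planted copy per top-block
sequence (position uniform, optional per-letter mutation, optional
reverse-complement orientation), and a recorded ground truth. The reference
conditions used throughout the tests are N = 200 sequences of length 100
with an intact 8-mer planted in the top 30; the recovery and false-positive
rates are computed over 100 seeded replicates of those conditions, and the
suffix-tree linearity check uses inputs up to ~80000 indexed characters.
These sizes exercise every code path at full statistical fidelity while
keeping the whole suite fast.

Real regulatory sequences are not iid: they have composition bias, repeats
and positional structure (a first-order Markov generator,
`generate_markov()`, is included for robustness checks). Passing the
planted-recovery and null-control tests therefore shows the *statistics and
machinery* are correct under their own null model — it does not certify
performance on genomic backgrounds, where enrichment of low-complexity
words against an inappropriate null is the classic failure mode of all
motif finders. The ranking itself is also taken as given; noisy rankings
degrade power in ways the generator does not model.

## Known limitations

* Exact words only: gapped or IUPAC-degenerate candidates are out of scope
  (the PSSM stage recovers point-mutation degeneracy, not spacers).
* No background Markov correction in the statistics; the null is uniform
  placement of presence labels.
* The Bonferroni correction across candidates is conservative; with very
  large candidate sets weakly enriched motifs will be missed at the
  default threshold.
* Double-strand mode assumes Watson–Crick complementarity; it is refused
  for protein input.

## A worked run

```{r}
fix <- generate_planted(plant_spec(seed = 42))
scan <- scan_motifs(fix$seqs, k_min = 8, k_max = 8)
scan$records[1, c("kmer", "N", "B", "n", "b", "enrichment",
                  "corrected_pvalue")]
pssm <- extend_pssm(scan$records$kmer[1], scan)
consensus(pssm)
```
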