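---
title: "Searching unaligned orthologs for conserved complementary regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searching unaligned orthologs for conserved complementarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccfind)
library(data.table)
```

## The problem

Long-range RNA-RNA base-pairing — a helix bridging two introns 10 kb apart,
or a snoRNA bound to an intronic target — is hard to find with the standard
comparative toolkit. Thermodynamic folding ignores pseudoknots and is biased
toward local structure; "first-align-then-fold" methods need a multiple
sequence alignment, and the intronic sequence around a conserved helix is
typically too diverged to align at all. `ccfind` takes the opposite,
*first-fold-then-align* route: it never aligns. Conservation of a k-mer is
defined as *content*, not position — a word counts as conserved in a segment
when it occurs anywhere in the orthologous segment of enough species. Two
complementary words that are each conserved in the *same* species, in a
permitted pair of segments, are evidence of a conserved helix, wherever they
sit in each genome.

The input is a collection of unaligned orthologous segments `s_ij`, indexed
by species `i = 1..m` and segment `j = 1..n`, with the same `j` naming
orthologs across species (in genomic practice, segments are delimited by
exon boundaries and the orthology is carried over by synteny, never by
base-level alignment). Species carry weight factors `f_i` summing to one, so
that a word's conservation weight in segment `j` is the summed weight of the
species whose `s_ij` contain it.

## The search pipeline

1. **Index** (`build_index`). Every segment is decomposed into its k-mers
   (default `k = 8`; the practical range is 8–11). With `gamma > 0`, gapped
   seeds are added: windows of span `k + g`, `g = 1..gamma`, whose middle `g`
   letters are skipped. The key of a gapped seed is the concatenation of its
   two halves (`ceiling(k/2)` and `floor(k/2)` letters), so seeds differing
   only in gap size — including `g = 0` — share one key. That is what lets a
   gap absorb either a short internal loop or a mutation inside an otherwise
   conserved word. Occurrence lists are kept sorted by (segment, position).

2. **Trim** (`trim_index`). For each key and segment, the conservation
   weight is the sum of `f_i` over species containing the key anywhere in
   that segment (each species counted once). Entries below the threshold
   `t0` are deleted. Trimming is the step that makes the Cartesian product
   feasible: it removes a priori non-conserved words *before* any pairing,
   so the quadratic blow-up only ever sees conserved keys. It is idempotent
   and antitone in `t0`, and both properties are tested.

3. **Pair** (`pair_and_trim`). For a key ω, the partner set ω\* is not one
   word but the collection of words that pair with ω antiparallel with at
   most `G` G·T wobbles and at least `h` G–C pairs (`wobble_complements`).
   A species supports the segment pair `(j, j′)` when ω occurs in `s_ij`
   and *some* member of ω\* occurs in `s_ij′`; the pair is reported when the
   summed weight of supporting species reaches `t ≥ t0` and `(j, j′)` is in
   the relation ℛ (same-gene pairs for intramolecular structure, a full
   product for target scans, or an explicit list). Fixing ω on the left and
   letting the partner vary inside ω\* avoids double counting; with
   `unique_flag`, only instances with `(j, p) < (j′, p′)` are reported, and
   a span never pairs with an overlapping copy of itself (non-overlapping
   self-complementarity — a hairpin — is legitimate and kept).

4. **Assemble** (`merge_clusters`). Overlapping complementary k-mers form
   longer helices: hits in one segment pair that overlap or abut on a common
   anti-diagonal (`p + p′` constant, up to a shift of `gamma` for gapped
   members) are merged; a cluster's matched length is the number of distinct
   paired positions it covers, and clusters shorter than `L` are discarded.
   `L`, not `k`, is the sensitivity/specificity dial: `k` only sets the hash
   resolution.

5. **Score and report** (`score_duplexes`, `naive_alignment`). See below.

All coordinates are 0-based half-open throughout, which keeps the
antiparallel span arithmetic free of fence-post cases.

## Parameters

| name | meaning | default | notes |
|------|---------|---------|-------|
| `k` | seed length (nt) | 8 | 4–15 accepted, 8–11 sensible |
| `t0` | trimming threshold (weight fraction) | 0.5 | `t0 ≤ t` enforced |
| `t` | intersection threshold (weight fraction) | 0.8 | comparisons use ≥ |
| `G` | max G·T wobbles per k-mer duplex | 1 | |
| `h` | min G–C pairs per k-mer duplex | 0 | a GC-content proxy for stability |
| `L` | min complementary nt per cluster | 12 | the main specificity filter |
| `gamma` | max central gap (nt) | 0 | gapped seeds off by default |
| `delta` | max positional divergence (nt) | Inf | unaligned input cannot be compared by position |
| `M` | segment length cap (nt, even) | 10000 | keeps first/last `M/2` nt |

Threshold comparisons use `≥` everywhere: a rule of "strictly greater" would
make `t = 1` unsatisfiable even for perfectly conserved words, while `≥`
keeps every stated threshold attainable. `h` defaults to 0 because the
planted-seed benchmark assumes uniformly random seeds are all detectable,
which only holds when no G–C floor is imposed.

The two-threshold scheme exists for operational reasons: trimming is the
expensive pass, so tables trimmed once at an intermediate `t0` can be stored
as meta-data (`write_index`/`read_index`) and re-trimmed in memory at any
`t ≥ t0` per analysis.

## Species weights

With no tree, weights are uniform. Given a tree, `compute_species_weights`
applies the Gerstein–Sonnhammer–Chothia apportionment — each leaf starts
with its terminal branch length, every internal branch is split among the
leaves below it in proportion to their accumulated weights — normalized to
sum to one. This down-weights clusters of near-identical genomes so that,
say, a dozen close primates cannot fake broad conservation by themselves.
A zero-length tree degenerates to uniform weights.

## Significance scores

Each duplex gets a two-component score. `C1` asks how surprising the
conserved box is against its segment's background: with `rho_j` the fraction
of k-mer start positions in segment `j` whose conservation weight reaches
`t`, a box of length `l` contributes `C1 = -(l - k + 1) * log10(rho)` per
side (conserved starts treated as independent Bernoulli events; `rho` is
floored at `1/(starts + 1)` so a fully non-conserved background stays
finite). `C2` asks how specific the complement is among the segment's
relation partners: `C2 = -log10(occurrences / partners)`. The components are
`-log10`-scaled so they add; duplexes are ranked by the total. Both behave
as the limits dictate: a highly conserved flanking sequence drives `C1` to
zero, and a complement found in many partner segments drives `C2` to zero —
in those regimes the score correctly refuses to call the duplex surprising.
These formulas are this package's own concrete model of the two named
effects; they are deliberately simple and are validated by their limiting
behavior and internal consistency, not against any external catalog.

## Reporting and the naive alignment

Per segment pair exactly one duplex is displayed: the longest, ties broken
by first occurrence (`merge_clusters` keeps all clusters; the selection
happens in `naive_alignment`, and everything remains available
programmatically). The complementary boxes are used as alignment anchors:
boxes and flanking intervals are aligned separately across the supporting
species and concatenated. The internal aligner is a star alignment centered
on the reference species (match +1, mismatch −1, gap −2 per column, via
`Biostrings::pairwiseAlignment`), which is entirely presentational: nothing
in detection depends on it. Flanks beyond 150 nt are middle-trimmed first.
When one pair of segments carries several distinct conserved duplexes, the
one-per-pair rule can anchor the display on the "wrong" one; the full
cluster list is the authoritative output.

## The rewiring FDR

The null model asks: how many duplex-bearing segment pairs would be found if
segments were re-paired across genes while preserving each segment's
conservation level and GC content? `block_segments` bins segments on a
quantile grid of the two covariates (the conservation score of a segment is
the mean conservation weight over its k-mer starts, computed on the
reference species' copy; the default grid is 25 × 20 = 500 blocks, both
factors configurable and far coarser grids being appropriate for small
inputs). `rewire_relation` permutes right endpoints within blocks, re-draws
pairs that land on their left endpoint's gene (bounded retries, then a
reported drop), and preserves the per-block right-endpoint multiset and the
left multiset exactly. `estimate_fdr` runs the search once on the true
relation and on `repeats` (default 20) independent rewirings — indexing and
trimming are shared, since rewiring only changes ℛ — and reports
FDR = mean control count / reference count with its standard error and a
normal 95% interval over repeats. Counting uses unordered segment pairs with
the α<β dedup disabled, so a pair is credited whichever way the rewiring
happens to orient it. A zero reference count yields an explicitly undefined
FDR, not a number.

## The benchmark simulators

`seed_insertion_benchmark` generates the unalignable-input condition: `n`
i.i.d. uniform-nucleotide segments per species, drawn independently in every
species, with `n_seeds` random k-mers planted into the odd segments and
their reverse complements into the even segments at independent uniform
positions, each copy split by a central gap of uniform size `0..max_gap`
filled with random letters. The defaults (`n = 200`, 1000 nt, `m = 16`,
100 seeds, `k = 8`, gaps ≤ 2) are the study conditions this package is
checked against: at `t = 0.95` the full pipeline recovers all 100 planted
pairs at their recorded coordinates, trial after trial, even though no two
orthologous segments share any background sequence — precisely the regime
where alignment-based methods see nothing. What this simulation does *not*
emulate is real intronic sequence: composition bias, repeats, indel drift
and correlated evolution are all absent, so passing it demonstrates
sensitivity of the machinery, not genomic specificity.

`evolve_on_tree` generates the opposite, alignable condition: random
ancestors evolved down a balanced binary tree of depth `log2(m)` with a
per-branch, per-site substitution probability (default 0.03, each
substitution uniform over the three alternatives). "Binary tree with a 3%
rate" admits two readings — 3% per branch or 3% per root-to-leaf path; per
branch is implemented as the default and the rate is an explicit argument,
so the other reading is `rate = 0.03 / depth`. The choice matters: at 3%
per branch, leaves are ≈ 89% identical to the root and an 8-mer survives
intact in a given leaf only ≈ 38% of the time, so word-level conservation
in 12 of 16 species is rare; at 3% per path it is common. Comparisons that
hinge on absolute counts under this simulation are therefore sensitive to
an assumption the text leaves open (see Limitations).

`duplex_post_filter` implements the benchmark's acceptance filter for
external predictions: a pair survives when it has ≥ 8 consecutive
complementary positions containing a window with ≤ 1 G·T per 8 nt whose two
words are conserved (word-containment, as everywhere) in at least the
required number of species. The optional harness (`run_rnaplex`,
`tree_benchmark`) feeds RNAplex predictions for the reference species'
sequences through this filter and checks them against the internal search;
no test requires the external executables.

## Numerical and degenerate-input conventions

* `U` is silently mapped to `T`; segments containing `N` are kept, but any
  seed whose key letters would include `N` is skipped (an `N` inside the
  *gap* of a gapped seed is harmless, since gap content is forgotten).
* For odd `k`, half-wise pairing of gapped keys is ill-typed (the halves
  differ in length), so complementarity of gapped keys is defined as
  antiparallel pairing of the `k` concatenated letters with both gaps
  excised; for even `k` — including the default — this coincides with
  pairing each half against the partner's opposite half.
* The reference coordinate frame for positional output and clustering is the
  highest-weight supporting species, ties broken by species-table order.
  Under exactly uniform weights the frame is therefore order-dependent;
  weights that differ (e.g. GSC weights) make it canonical.
* Cluster merging uses union-find over hits sharing an anti-diagonal within
  `gamma`; "overlap or abut" is `p₂ ≤ p₁ + span₁` on both sides, so helices
  assembled from abutting seeds count their full contiguous length.
* The rewiring is deterministic given its seed, and package randomness never
  leaks into the caller's RNG state.

## Problem sizes used in the checks

The shipped tests run the planted-seed benchmark at its full stated scale
(16 × 200 × 1000 nt, five independent trials) and everything else on small
instances: oracle equivalence on 3-species collections of four ≤ 60-nt
segments at `k ∈ {4, 5}` against an exhaustive enumeration oracle, FDR
calibration on 3 × 60 × 150-nt instances with 8 rewirings (null FDR pooled
over five independent instances so the interval reflects reference-count
noise as well), and the tree benchmark at 30 groups for the containment
property plus one 100-group run for the published-scale comparison. These
sizes were chosen as the smallest at which each property is non-vacuous.

## Limitations

* Conservation is exact word content. A single substitution inside a k-mer
  (outside the gapped-seed rescue) removes that species' support; compensa-
  tory double substitutions that preserve pairing but change both words are
  invisible. This is a deliberate trade: in the target regime conserved
  helices are nearly invariant, and statistical power comes from the
  contrast with the diverged background, not from covariation.
* The C1/C2 score is a calibrated ranking device, not a p-value.
* The tree-simulation comparison against an external duplex predictor
  depends on unstated details (the MSA program, how the predictor is applied
  to alignments, the mutation-rate convention), and its absolute pair counts
  are not reproducible from the text alone; the containment of filtered
  external predictions in the hash-search output is the robust property and
  is the one asserted.
* Genome-scale analyses (hundreds of thousands of real intronic segments)
  are out of scope for the shipped checks; nothing in the code limits the
  input size, but memory for the index grows with total sequence.
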