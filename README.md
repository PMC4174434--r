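# ccfind — conserved complementary regions in unaligned orthologs

`ccfind` finds pairs of complementary k-mers that are *simultaneously*
conserved across orthologous, unaligned sequence segments in many species.
It is built for the comparative genomics of long-range RNA structure and
RNA–RNA interactions — intronic helices that loop out skipped exons, snoRNA
or lncRNA complementarity to pre-mRNA — in exactly the regime where the
usual tools fail: the sequences flanking a conserved helix are typically too
diverged to align, so any method that starts from a multiple sequence
alignment never sees the signal. `ccfind` follows the
*first-fold-then-align* principle instead: conservation of a word is defined
by its occurrence anywhere in the orthologous segment (content, not
position), and alignment happens only afterwards, anchored on the structure
it found.

## The method in brief

Orthologous segments `s_ij` (species `i = 1..m` with weights `f_i` summing
to 1, segments `j = 1..n`) are decomposed into k-mers, optionally with a
central gap of up to `gamma` nt (the gap content is forgotten, so a gapped
seed tolerates a short internal loop or a mutation). Per-species sorted hash
tables `H_i(ω)` map each key to its occurrence list. The search then:

1. **trims** each table: an occurrence of ω in segment `j` survives iff the
   summed weight of species whose `s_ij` contains ω anywhere is ≥ `t0`;
2. **pairs** each surviving ω against its wobble complement set ω\* (all
   words pairing antiparallel with ≤ `G` G·T wobbles and ≥ `h` G–C pairs):
   species `i` supports segment pair `(j, j′)` iff ω occurs in `s_ij` and
   some χ ∈ ω\* occurs in `s_ij′`; pairs in the relation ℛ with support
   weight ≥ `t` become hits;
3. **assembles** overlapping hits on common anti-diagonals into duplexes and
   keeps those with ≥ `L` paired nucleotides;
4. **scores** each duplex: `C1 = -(l-k+1)·log10(ρ)` per side (ρ = the
   segment's background rate of conserved k-mer starts) plus
   `C2 = -log10(complement occurrences / relation partners)`, and ranks by
   the total.

A rewiring null model estimates the FDR: segments are binned into blocks by
conservation score and GC content, the relation's right endpoints are
permuted within blocks (never landing back on the same gene), and FDR =
mean control count / reference count over repeated rewirings. Two
simulators generate benchmark instances with ground truth (planted
complementary seeds in unalignable backgrounds; tree-evolved orthologous
groups), and an optional harness compares against RNAplex when it is on the
`PATH`.

## Worked example

Plant three complementary 8-mer pairs (split by random central gaps of up to
2 nt) into otherwise independent random segments of three species, and
search for them:

```r
library(ccfind)

sim <- seed_insertion_benchmark(n = 6, length = 120, m = 3, n_seeds = 3,
                                k = 8, max_gap = 2, rng_seed = 7)
cfg <- search_config(k = 8, t0 = 0.9, t = 0.9, G = 1, h = 0, L = 8,
                     gamma = 2, M = 1000)
rel <- build_relation(sim$collection, sim$collection, "all-pairs")
res <- run_search(sim$collection, sim$collection, rel, cfg)
res
#> cc_result:
#>   18+18 segments, 3 species, 36 relation pairs
#>   occurrences 6048 -> 18 after trimming at t0=0.9
#>   3 hits, 3 duplexes in 3 segment pairs (t=0.9, L=8)
```

Trimming collapsed 6048 occurrences to the 18 that are conserved in all
three species (weight ≥ 0.9 forces all of them), and pairing found exactly
the three planted segment pairs:

```r
as.data.frame(res$duplexes)[, c("left_id", "right_id", "left_start",
                                "matched_length", "support_weight", "score")]
#>   left_id right_id left_start matched_length support_weight    score
#> 1   s0005    s0006         45              8              1 9.005771
#> 2   s0001    s0002         90              8              1 9.001944
#> 3   s0003    s0004        100              8              1 6.945039
```

Each duplex links segment `2q-1` to its partner `2q` at the planted
coordinates with support weight 1 (all species). The score is the summed
improbability of the two conserved boxes against their non-conserved
backgrounds (`C1` per side) plus the specificity of the complement among the
36 scanned partners (`C2`); ~9 means roughly "nine orders of magnitude more
conserved-and-specific than this background predicts". The per-species box
instances, the cluster members, and a structure-anchored display alignment
(`naive_alignment`) are all available from the result object.

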