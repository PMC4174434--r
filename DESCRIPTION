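Package: ccfind
Title: Alignment-Free Search for Conserved Complementary Regions in
    Unaligned Orthologous Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects pairs of complementary k-mers that are simultaneously
    conserved across orthologous, unaligned sequence segments in many
    species, following the first-fold-then-align principle. Builds sorted
    (optionally gapped) k-mer indexes per species, sparsifies them by
    weighted cross-species conservation (trimming), intersects them with
    wobble-tolerant reverse complements under a segment-pair relation,
    assembles overlapping hits into duplexes with significance scores, and
    estimates the false-discovery rate by a block-preserving rewiring null
    model. Ships the benchmark simulators (planted complementary seeds;
    tree-evolved orthologous groups) and an optional harness around an
    external aligner and RNAplex.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
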