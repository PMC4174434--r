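library(data.table)

# build a collection from a list of per-species named sequence vectors:
# seqs[[species]][segment_id] ; gene ids default to the segment id
make_collection <- function(seqs, genes = NULL, weights = NULL,
                            side = "A") {
  sp <- names(seqs)
  segs <- rbindlist(lapply(sp, function(s) {
    ids <- names(seqs[[s]])
    data.table(species = s, segment_id = ids,
               gene_id = if (is.null(genes)) ids else genes[ids],
               sequence = unname(seqs[[s]]))
  }))
  segment_collection(segs, species_table(sp, weights), side)
}

# m species x n segments of iid random sequence, genes pairing consecutive
# segments; built on a fixed seed so tests are reproducible
random_collection <- function(m, n, len, seed, pair_genes = TRUE) {
  ccfind:::with_seed(seed, {
    sp <- paste0("sp", seq_len(m))
    segs <- rbindlist(lapply(sp, function(s) data.table(
      species = s,
      segment_id = sprintf("s%02d", seq_len(n)),
      gene_id = if (pair_genes) sprintf("g%02d", ceiling(seq_len(n) / 2))
                else sprintf("g%02d", seq_len(n)),
      sequence = ccfind:::random_dna(rep(len, n)))))
    segment_collection(segs, species_table(sp))
  })
}

# relation pairing segment 2q-1 with 2q, one direction, no self pairs
odd_even_relation <- function(n, width = 2) {
  fmt <- paste0("s%0", width, "d")
  data.frame(left_id = sprintf(fmt, seq(1, n, 2)),
             right_id = sprintf(fmt, seq(2, n, 2)))
}

quiet_config <- function(...) suppressWarnings(search_config(...))

hit_pairs <- function(hits) {
  dt <- as.data.table(hits)
  if (nrow(dt) == 0L)
    return(setDT(list(key = character(), left_id = character(),
                      right_id = character(), support_weight = numeric())))
  unique(dt[, .(key, left_id, right_id,
                support_weight = round(support_weight, 9))])
}
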