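test_that("trimming keeps exactly the keys whose weight sum clears t0", {
  # omega present in segment s1 of species 1 and 2 only, uniform weights 1/3
  seqs <- list(sp1 = c(s1 = "AAGGGCAA"), sp2 = c(s1 = "TTGGGCTT"),
               sp3 = c(s1 = "TTTTTTTT"))
  coll <- make_collection(seqs)
  cfg <- quiet_config(k = 4, t0 = 0, t = 0.6, L = 4, M = 100)
  idx <- build_index(coll, cfg)
  w_of <- function(ix, key) nrow(ix$occ[ix$occ$key == key])
  tr6 <- trim_index(idx, 0.6)
  expect_equal(w_of(tr6, "GGGC"), 2L)               # 2/3 >= 0.6: kept
  tr7 <- trim_index(idx, 0.7)
  expect_equal(w_of(tr7, "GGGC"), 0L)               # 2/3 < 0.7: dropped
  # t0 = 0 keeps everything
  tr0 <- trim_index(idx, 0)
  expect_equal(nrow(tr0$occ), nrow(idx$occ))
  # the surviving table at a full-conservation threshold is empty here
  expect_equal(nrow(trim_index(idx, 1)$occ), 0L)
})

test_that("simultaneity across species is what trimming and pairing detect", {
  # "boxes" (GGGC/GCCC) sit in the same segment pair in all 3 species;
  # "circles" (AACCA/TGGTT at k=4: CCAT etc.) use distinct words present in
  # only 2 species simultaneously
  box <- "GGGC"; boxrc <- revcomp(box)
  circ <- "ATCG"; circrc <- revcomp(circ)
  seqs <- list(
    sp1 = c(s1 = paste0("TT", box, "TTTT"), s2 = paste0("AAA", boxrc, "ACT")),
    sp2 = c(s1 = paste0(box, "TTATTT"), s2 = paste0(boxrc, "AGACT")),
    sp3 = c(s1 = paste0("TTTT", box, circ), s2 = paste0("ATAT", boxrc, circrc)))
  # circles co-occur in the pair only in sp3 (and partially elsewhere)
  coll <- make_collection(seqs, genes = c(s1 = "g", s2 = "g"))
  cfg <- quiet_config(k = 4, t0 = 0, t = 1.0, G = 0, L = 4, M = 100)
  idx <- trim_index(build_index(coll, cfg), cfg$t0)
  hits <- pair_and_trim(idx, idx, data.frame(left_id = "s1", right_id = "s2"),
                        cfg)
  hp <- hit_pairs(hits)
  expect_true(box %in% hp$key)                      # boxes reported at t = 1
  expect_false(circ %in% hp$key)                    # circles are not
  expect_equal(hp[key == box, support_weight], 1)
})

test_that("a conserved complementary word pair is found at its weight", {
  # GGGC in s1 and GCCC in s2 for species 1 and 2 only
  seqs <- list(
    sp1 = c(s1 = "TTGGGCTT", s2 = "AAGCCCAA"),
    sp2 = c(s1 = "AGGGCAAT", s2 = "TTTGCCCT"),
    sp3 = c(s1 = "TTTTTTTT", s2 = "AAAAAAAA"))
  coll <- make_collection(seqs, genes = c(s1 = "g", s2 = "g"))
  cfg <- quiet_config(k = 4, t0 = 0.5, t = 0.6, G = 0, L = 4, M = 100)
  idx <- trim_index(build_index(coll, cfg), cfg$t0)
  rel <- data.frame(left_id = "s1", right_id = "s2")
  hp <- hit_pairs(pair_and_trim(idx, idx, rel, cfg))
  expect_equal(nrow(hp[key == "GGGC"]), 1L)
  expect_equal(hp[key == "GGGC", support_weight], round(2 / 3, 9))
  # empty relation: no output no matter the sequences
  empty_rel <- data.frame(left_id = character(), right_id = character())
  expect_equal(nrow(pair_and_trim(idx, idx, empty_rel, cfg)), 0L)
  # mismatched key spaces are rejected
  idx5 <- build_index(coll, quiet_config(k = 5, t0 = 0.5, t = 0.6, L = 5,
                                         M = 100))
  expect_error(pair_and_trim(idx, idx5, rel, cfg), "mismatch")
})

test_that("trimming is idempotent and antitone in the threshold", {
  coll <- random_collection(3, 4, 50, seed = 33)
  cfg <- quiet_config(k = 4, t0 = 0, t = 0.5, M = 100)
  idx <- build_index(coll, cfg)
  for (t0 in c(0.3, 0.6, 1.0)) {
    tr1 <- trim_index(idx, t0)
    tr2 <- trim_index(tr1, t0)
    expect_equal(as.data.frame(tr2$occ), as.data.frame(tr1$occ))
  }
  sizes <- vapply(c(0, 0.3, 0.6, 0.9, 1), function(t0)
    nrow(trim_index(idx, t0)$occ), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  # subset relation, not just shrinking counts
  lo <- trim_index(idx, 0.3)$occ
  hi <- trim_index(idx, 0.9)$occ
  expect_equal(nrow(fsetdiff(hi, lo)), 0L)
})

test_that("raising t shrinks the hit list and never leaks outside the relation", {
  coll <- random_collection(3, 6, 40, seed = 41)
  rel <- odd_even_relation(6)
  sizes <- vapply(c(0.3, 0.6, 1.0), function(t) {
    cfg <- quiet_config(k = 4, t0 = 0.3, t = t, M = 100)
    idx <- trim_index(build_index(coll, cfg), cfg$t0)
    nrow(hit_pairs(pair_and_trim(idx, idx, rel, cfg)))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  cfg <- quiet_config(k = 4, t0 = 0.3, t = 0.6, M = 100)
  idx <- trim_index(build_index(coll, cfg), cfg$t0)
  hits <- as.data.table(pair_and_trim(idx, idx, rel, cfg))
  if (nrow(hits)) {
    in_rel <- merge(hits[, .(left_id, right_id)], as.data.table(rel),
                    by = c("left_id", "right_id"))
    expect_equal(nrow(in_rel), nrow(hits))
  }
})

test_that("trim + pair equals the brute-force definition on random instances", {
  cases <- expand.grid(k = c(4, 5), G = c(0, 1), h = c(0, 2),
                       stringsAsFactors = FALSE)
  plant <- function(seq, word, pos) {        # overwrite at 0-based pos
    paste0(substr(seq, 1, pos), word,
           substring(seq, pos + nchar(word) + 1))
  }
  for (ci in seq_len(nrow(cases))) {
    k <- cases$k[ci]; G <- cases$G[ci]; h <- cases$h[ci]
    gamma <- ifelse(ci %% 2 == 0, 1, 0)
    coll <- random_collection(3, 4, 45, seed = 100 + ci)
    # plant structure so the comparison is never vacuous: an exact
    # complementary pair in all species (gapped in one species when gapped
    # seeds are on), a wobble-paired word pair in all species, and a pair
    # present in a single species as a negative control
    segs <- coll$segments
    ccfind:::with_seed(900 + ci, {
      w1 <- ccfind:::random_dna(k)
      w2 <- ccfind:::random_dna(k)
      w2wob <- sample(wobble_complements(w2, 1, 0), 1)
      w3 <- ccfind:::random_dna(k)
      lh <- ceiling(k / 2)
      w1gap <- paste0(substr(w1, 1, lh), "A", substring(w1, lh + 1))
      for (sp in paste0("sp", 1:3)) {
        put <- function(id, word, pos) {
          segs[species == sp & segment_id == id,
               sequence := plant(sequence, word, pos)]
        }
        put("s01", if (sp == "sp2" && gamma == 1) w1gap else w1, 5)
        put("s02", revcomp(w1), 12)
        put("s03", w2, 3)
        put("s04", w2wob, 20)
        if (sp == "sp1") { put("s03", w3, 30); put("s04", revcomp(w3), 2) }
      }
    })
    coll <- segment_collection(segs, coll$species_table)
    cfg <- quiet_config(k = k, t0 = 0.3, t = 0.6, G = G, h = h, L = k,
                        gamma = gamma, M = 100, unique_flag = FALSE)
    rel <- odd_even_relation(4)
    idx <- trim_index(build_index(coll, cfg), cfg$t0)
    got <- hit_pairs(pair_and_trim(idx, idx, rel, cfg))
    want <- oracle_search(coll, coll, rel, cfg)
    setkey(got, key, left_id, right_id)
    expect_gt(nrow(want) + nrow(got), 0)
    expect_equal(as.data.frame(got), as.data.frame(want),
                 ignore_attr = TRUE,
                 label = sprintf("case k=%d G=%d h=%d", k, G, h))
  }
})

test_that("without dedup, every hit reappears under the complementary key", {
  coll <- random_collection(2, 4, 40, seed = 55)
  cfg <- quiet_config(k = 4, t0 = 0.4, t = 0.5, G = 0, M = 100,
                      unique_flag = FALSE)
  # symmetric relation over distinct segments
  rel <- data.frame(left_id = c("s01", "s02", "s03", "s04"),
                    right_id = c("s02", "s01", "s04", "s03"))
  idx <- trim_index(build_index(coll, cfg), cfg$t0)
  hits <- as.data.table(pair_and_trim(idx, idx, rel, cfg))
  for (r in seq_len(min(nrow(hits), 25))) {
    expect_true(nrow(hits[key == revcomp(hits$key[r]) &
                          left_id == hits$right_id[r] &
                          right_id == hits$left_id[r]]) > 0)
  }
})

test_that("positional divergence bound restricts contributing species", {
  # same 4-mer at position 0 in sp1/sp2 but at position 20 in sp3
  mk <- function(p) paste0(strrep("A", p), "GGGC",
                           strrep("A", 24 - p - 4))
  seqs <- list(sp1 = c(s1 = mk(0), s2 = "AAGCCCAA"),
               sp2 = c(s1 = mk(1), s2 = "TGCCCTTA"),
               sp3 = c(s1 = mk(20), s2 = "TAGCCCTT"))
  coll <- make_collection(seqs)
  cfg <- quiet_config(k = 4, t0 = 0, t = 0.5, M = 100)
  idx <- build_index(coll, cfg)
  # unlimited delta: all three species carry GGGC in s1
  expect_equal(length(unique(trim_index(idx, 0.9)$occ[key == "GGGC", species])), 3L)
  # delta = 5: sp3's occurrence is 20 nt away from the reference's
  tr <- trim_index(idx, 0.6, delta = 5)
  expect_setequal(unique(tr$occ[key == "GGGC", species]), c("sp1", "sp2"))
})
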