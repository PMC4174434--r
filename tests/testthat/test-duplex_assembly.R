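# hand-built hit tables for geometry tests
mk_hits <- function(p, p2, gap = 0L, gap2 = 0L, key = "ACGTACGT",
                    left = "s1", right = "s2", w = 1) {
  n <- length(p)
  setDT(list(key = rep(key, n), left_id = rep(left, n), pos = as.integer(p),
             gap = rep(as.integer(gap), n), chi = rep(revcomp(key), n),
             right_id = rep(right, n), pos2 = as.integer(p2),
             gap2 = rep(as.integer(gap2), n),
             support_weight = rep(w, n), n_support = rep(2L, n),
             support_species = rep("sp1,sp2", n),
             ref_species = rep("sp1", n)))
}

test_that("overlapping hits on one anti-diagonal merge into a single duplex", {
  cfg <- quiet_config(k = 8, L = 8, M = 100)
  dup <- merge_clusters(mk_hits(c(10, 11), c(50, 49)), cfg, min_length = 8)
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$left_start, 10L)
  expect_equal(dup$left_end, 19L)
  expect_equal(dup$right_start, 49L)
  expect_equal(dup$right_end, 58L)
  expect_equal(dup$matched_length, 9L)          # p + p2 = 60 for both
  # the length filter is a hard threshold
  expect_equal(nrow(merge_clusters(mk_hits(c(10, 11), c(50, 49)), cfg,
                                   min_length = 12)), 0L)
  expect_equal(nrow(merge_clusters(mk_hits(c(10, 11), c(50, 49)), cfg,
                                   min_length = 9)), 1L)
})

test_that("hits on a common anti-diagonal but with disjoint spans stay apart", {
  cfg <- quiet_config(k = 8, L = 8, M = 100)
  dup <- merge_clusters(mk_hits(c(0, 20), c(60, 40)), cfg, min_length = 8)
  expect_equal(nrow(dup), 2L)
  # abutting spans on the same anti-diagonal do merge
  dup2 <- merge_clusters(mk_hits(c(0, 8), c(60, 52)), cfg, min_length = 8)
  expect_equal(nrow(dup2), 1L)
  expect_equal(dup2$matched_length, 16L)
  # different anti-diagonals never merge without gapped members
  dup3 <- merge_clusters(mk_hits(c(0, 4), c(60, 58)), cfg, min_length = 8)
  expect_equal(nrow(dup3), 2L)
})

test_that("clustering partitions the hits and is antitone in L", {
  coll <- random_collection(3, 6, 60, seed = 77)
  cfg <- quiet_config(k = 4, t0 = 0.3, t = 0.6, M = 100)
  idx <- trim_index(build_index(coll, cfg), cfg$t0)
  hits <- pair_and_trim(idx, idx, odd_even_relation(6), cfg)
  dup <- merge_clusters(hits, cfg, min_length = cfg$k)
  # every hit instance belongs to exactly one cluster before the L filter
  expect_equal(sum(dup$n_members), nrow(hits))
  members <- rbindlist(dup$members)
  setkey(members, pos, pos2)
  hh <- as.data.table(hits)[, .(key, pos, gap, chi, pos2, gap2,
                                support_weight)]
  expect_equal(nrow(members), nrow(unique(rbind(
    members, hh[, names(members), with = FALSE]))))
  counts <- vapply(c(4, 6, 8, 12), function(L)
    nrow(merge_clusters(hits, cfg, min_length = L)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("reported duplex spans re-verify under the pairing rules", {
  sim <- seed_insertion_benchmark(n = 8, length = 120, m = 3, n_seeds = 4,
                                  k = 8, max_gap = 2, rng_seed = 13)
  cfg <- quiet_config(k = 8, t0 = 0.9, t = 0.9, G = 1, h = 0, L = 8,
                      gamma = 2, M = 1000)
  coll <- sim$collection
  idx <- trim_index(build_index(coll, cfg), cfg$t0)
  rel <- build_relation(coll, coll, "all-pairs")
  hits <- pair_and_trim(idx, idx, rel, cfg)
  dup <- merge_clusters(hits, cfg)
  expect_gt(nrow(dup), 0)
  segs <- coll$segments
  for (i in seq_len(nrow(dup))) {
    d <- dup[i]
    ls <- segs[species == d$ref_species & segment_id == d$left_id, sequence]
    rs <- segs[species == d$ref_species & segment_id == d$right_id, sequence]
    for (r in seq_len(nrow(d$members[[1]]))) {
      mrow <- d$members[[1]][r]
      lword <- paste0(substr(ls, mrow$pos + 1, mrow$pos + 4),
                      substr(ls, mrow$pos + 5 + mrow$gap,
                             mrow$pos + 8 + mrow$gap))
      rword <- paste0(substr(rs, mrow$pos2 + 1, mrow$pos2 + 4),
                      substr(rs, mrow$pos2 + 5 + mrow$gap2,
                             mrow$pos2 + 8 + mrow$gap2))
      # independent wobble check: the two words must pair with <= G wobbles
      # and >= h G-C pairs
      expect_true(rword %in% oracle_wobble(lword, 1, 0),
                  label = sprintf("duplex %d member %d pairs", i, r))
    }
  }
})

test_that("significance scores follow the Bernoulli-start and specificity model", {
  # planted box in a background of otherwise unconserved sequence
  sim <- seed_insertion_benchmark(n = 10, length = 200, m = 3, n_seeds = 5,
                                  k = 12, max_gap = 0, rng_seed = 19)
  cfg <- quiet_config(k = 6, t0 = 0.9, t = 0.9, G = 0, h = 0, L = 6,
                      gamma = 0, M = 1000)
  coll <- sim$collection
  idxU <- build_index(coll, cfg)
  idx <- trim_index(idxU, cfg$t0)
  rel <- build_relation(coll, coll, "all-pairs")
  hits <- pair_and_trim(idx, idx, rel, cfg)
  dup <- merge_clusters(hits, cfg)
  sc <- score_duplexes(dup, hits, idxU, idxU, rel, cfg)
  expect_true(all(c("C1_left", "C1_right", "C2", "score") %in% names(sc)))
  expect_equal(sc$score, sc$C1_left + sc$C1_right + sc$C2)
  expect_true(all(sc$score >= 0))
  expect_equal(sc$score, sort(sc$score, decreasing = TRUE))
  # C1 agrees with a by-hand evaluation of the formula on the top duplex
  d <- sc[1]
  rates <- ccfind:::conservation_rates(idxU, cfg$t)
  r <- rates[species == d$ref_species & segment_id == d$left_id]
  rho <- max(r$rho, 1 / (r$n_starts + 1))
  expect_equal(d$C1_left,
               -(d$left_end - d$left_start - cfg$k + 1) * log10(rho))
  # C2: a complement unique among its partners scores log10(#partners)
  pc <- nrow(as.data.table(rel)[left_id == d$left_id])
  co <- uniqueN(as.data.table(hits)[left_id == d$left_id &
                                    key %in% d$members[[1]]$key, right_id])
  expect_equal(d$C2, -log10(co / pc))
  # scores are invariant under a consistent relabeling of species (names
  # permuted in both the segments and the weight table, weights distinct so
  # the reference frame follows the permutation)
  st_w <- species_table(sprintf("sp%02d", 1:3), c(0.5, 0.3, 0.2))
  collw <- segment_collection(coll$segments, st_w)
  idxW <- build_index(collw, cfg)
  hitsw <- pair_and_trim(trim_index(idxW, cfg$t0), trim_index(idxW, cfg$t0),
                         rel, cfg)
  scw <- score_duplexes(merge_clusters(hitsw, cfg), hitsw, idxW, idxW,
                        rel, cfg)
  segs2 <- copy(coll$segments)[, species := chartr("123", "231", species)]
  st2 <- species_table(chartr("123", "231", st_w$species), st_w$weight)
  coll2 <- segment_collection(segs2, st2)
  idxU2 <- build_index(coll2, cfg)
  hits2 <- pair_and_trim(trim_index(idxU2, cfg$t0), trim_index(idxU2, cfg$t0),
                         rel, cfg)
  sc2 <- score_duplexes(merge_clusters(hits2, cfg), hits2, idxU2, idxU2,
                        rel, cfg)
  expect_equal(sort(round(sc2$score, 9)), sort(round(scw$score, 9)))
})

test_that("the naive alignment reports one duplex per pair, longest first", {
  # two planted boxes of different lengths in the same segment pair
  long_box <- "ACGTACGTACGTAC"    # 14 nt
  short_box <- "GGATCCGGATCC"     # 12 nt
  bg <- function(seed, len) ccfind:::with_seed(seed, ccfind:::random_dna(len))
  seqs <- lapply(1:3, function(i) {
    s1 <- paste0(bg(i, 10), long_box, bg(i + 10, 30), short_box, bg(i + 20, 10))
    s2 <- paste0(bg(i + 30, 15), revcomp(short_box), bg(i + 40, 25),
                 revcomp(long_box), bg(i + 50, 15))
    c(s1 = s1, s2 = s2)
  })
  names(seqs) <- paste0("sp", 1:3)
  coll <- make_collection(seqs, genes = c(s1 = "g", s2 = "g"))
  cfg <- quiet_config(k = 8, t0 = 1, t = 1, G = 0, L = 12, M = 1000)
  idxU <- build_index(coll, cfg)
  idx <- trim_index(idxU, cfg$t0)
  rel <- data.frame(left_id = "s1", right_id = "s2")
  hits <- pair_and_trim(idx, idx, rel, cfg)
  dup <- merge_clusters(hits, cfg)
  expect_equal(sort(dup$matched_length), c(12L, 14L))
  al <- naive_alignment(dup, coll, coll, idx, idx, cfg)
  expect_length(al, 1L)
  expect_equal(al[[1]]$duplex$matched_length, 14L)   # longest selected
  A <- al[[1]]$left_alignment
  expect_equal(rownames(A), paste0("sp", 1:3))
  expect_gt(length(al[[1]]$left_box_cols), 0)
  # the reference row of the left box, read off the alignment, is the box
  refrow <- paste(A["sp1", al[[1]]$left_box_cols], collapse = "")
  expect_equal(gsub("-", "", refrow), long_box)
  txt <- format_alignment(al[[1]])
  expect_true(any(grepl("\\*", txt)))
})

test_that("equal-length duplexes resolve to the first occurring one", {
  boxA <- "ACGTACGTACGT"; boxB <- "GGATCCGGATCC"
  bg <- function(seed, len) ccfind:::with_seed(seed, ccfind:::random_dna(len))
  seqs <- lapply(1:2, function(i) {
    c(s1 = paste0(bg(i, 5), boxA, bg(i + 9, 20), boxB, bg(i + 17, 5)),
      s2 = paste0(bg(i + 33, 5), revcomp(boxA), bg(i + 41, 20),
                  revcomp(boxB), bg(i + 49, 5)))
  })
  names(seqs) <- paste0("sp", 1:2)
  coll <- make_collection(seqs, genes = c(s1 = "g", s2 = "g"))
  cfg <- quiet_config(k = 8, t0 = 1, t = 1, G = 0, L = 12, M = 1000)
  idx <- trim_index(build_index(coll, cfg), cfg$t0)
  rel <- data.frame(left_id = "s1", right_id = "s2")
  dup <- merge_clusters(pair_and_trim(idx, idx, rel, cfg), cfg)
  expect_equal(nrow(dup), 2L)
  al <- naive_alignment(dup, coll, coll, idx, idx, cfg)
  expect_equal(al[[1]]$duplex$left_start, min(dup$left_start))
})

test_that("flanks longer than 150 nt are middle-trimmed before alignment", {
  box <- "ACGTACGTACGTACGT"
  seqs <- lapply(1:2, function(i) {
    bg <- ccfind:::with_seed(i, ccfind:::random_dna(400))
    c(s1 = paste0(bg, box),
      s2 = paste0(revcomp(box), ccfind:::with_seed(i + 5,
                                                   ccfind:::random_dna(400))))
  })
  names(seqs) <- paste0("sp", 1:2)
  coll <- make_collection(seqs, genes = c(s1 = "g", s2 = "g"))
  cfg <- quiet_config(k = 8, t0 = 1, t = 1, G = 0, L = 16, M = 1000)
  idx <- trim_index(build_index(coll, cfg), cfg$t0)
  dup <- merge_clusters(pair_and_trim(idx, idx,
    data.frame(left_id = "s1", right_id = "s2"), cfg), cfg)
  al <- naive_alignment(dup, coll, coll, idx, idx, cfg)
  # 400-nt flank capped at 150 alignment columns plus the 16-nt box
  expect_lte(ncol(al[[1]]$left_alignment), 150 + 16 + 10)
})
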