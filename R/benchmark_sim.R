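#' Seed-insertion benchmark: planted complementary k-mers
#'
#' Generates `n` i.i.d. uniform-nucleotide segments of the given length in
#' each of `m` simulated species (segments are independent across species, so
#' no group of orthologs is alignable), draws `n_seeds` random k-mer seeds,
#' and plants seed q into segment 2q-1 of every species at an independent
#' uniform position, with its reverse complement planted into segment 2q.
#' Each inserted copy is split by a central gap of size drawn uniformly from
#' 0..`max_gap`, filled with random nucleotides. Insertion overwrites the
#' background (segment lengths are unchanged). The intended complementary
#' pairs are segments (2q-1, 2q).
#'
#' @param n number of segments per species (even).
#' @param length segment length (nt).
#' @param m number of species.
#' @param n_seeds number of planted seed pairs (<= n/2).
#' @param k seed length (nt).
#' @param max_gap maximum central gap size (nt).
#' @param rng_seed integer seed; same seed, same output.
#' @return a list with `collection` (a [segment_collection()]; gene ids group
#'   each planted pair, species weights uniform) and `truth` (a data.table:
#'   `pair`, `seed`, `species`, `segment_id`, `pos`, `gap`, `side`).
#' @export
seed_insertion_benchmark <- function(n = 200L, length = 1000L, m = 16L,
                                     n_seeds = 100L, k = 8L, max_gap = 2L,
                                     rng_seed = 1L) {
  n <- as.integer(n); m <- as.integer(m); n_seeds <- as.integer(n_seeds)
  if (n %% 2 != 0) stop("n must be even")
  if (n_seeds > n / 2) stop("n_seeds must be <= n/2")
  if (length < k + max_gap) stop("segment too short for insertion")
  with_seed(rng_seed, {
    species <- sprintf("sp%02d", seq_len(m))
    seeds <- random_dna(rep(k, n_seeds))
    lh <- as.integer(ceiling(k / 2))
    seg_rows <- vector("list", m)
    truth_rows <- vector("list", m)
    for (i in seq_len(m)) {
      seqs <- random_dna(rep(length, n))
      tr <- vector("list", n_seeds)
      for (q in seq_len(n_seeds)) {
        for (side in 1:2) {
          j <- 2L * q - 2L + side
          word <- if (side == 1L) seeds[q] else revcomp(seeds[q])
          g <- sample.int(max_gap + 1L, 1L) - 1L
          ins <- paste0(substr(word, 1L, lh),
                        if (g > 0) random_dna(g) else "",
                        substring(word, lh + 1L))
          span <- k + g
          p <- sample.int(length - span + 1L, 1L) - 1L   # 0-based
          seqs[j] <- paste0(substr(seqs[j], 1L, p), ins,
                            substring(seqs[j], p + span + 1L))
          tr[[q]] <- rbind(tr[[q]],
            data.table(pair = q, seed = seeds[q], species = species[i],
                       segment_id = sprintf("s%04d", j), pos = p, gap = g,
                       side = side))
        }
      }
      seg_rows[[i]] <- data.table(
        species = species[i],
        segment_id = sprintf("s%04d", seq_len(n)),
        gene_id = sprintf("g%04d", ceiling(seq_len(n) / 2)),
        sequence = seqs)
      truth_rows[[i]] <- rbindlist(tr)
    }
    coll <- segment_collection(rbindlist(seg_rows), species_table(species))
    list(collection = coll, truth = rbindlist(truth_rows))
  })
}

#' Count planted pairs recovered by a hit list
#'
#' A planted pair q is recovered when the hit list contains an instance of
#' seed q linking segments 2q-1 and 2q at exactly the planted positions in
#' the hits' reference species.
#'
#' @param hits a `cc_hits` table from [pair_and_trim()].
#' @param truth the truth table from [seed_insertion_benchmark()].
#' @return integer vector of recovered pair indices.
#' @export
recovered_pairs <- function(hits, truth) {
  dt <- as.data.table(hits)
  if (nrow(dt) == 0L) return(integer(0))
  tr <- dcast(truth, pair + seed + species ~ side,
              value.var = c("segment_id", "pos"))
  hit_match <- merge(
    dt[, .(key, left_id, pos, right_id, pos2, ref_species)],
    tr[, .(pair, seed, species, segment_id_1, pos_1, segment_id_2, pos_2)],
    by.x = c("key", "ref_species", "left_id", "right_id"),
    by.y = c("seed", "species", "segment_id_1", "segment_id_2"))
  sort(unique(hit_match[pos == pos_1 & pos2 == pos_2, pair]))
}

# per-branch substitution: each site mutates with probability `rate` to one
# of the three other nucleotides uniformly
mutate_branch <- function(seqs, rate) {
  vapply(seqs, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- runif(length(chars)) < rate
    if (any(hit)) {
      alt <- vapply(chars[hit], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      chars[hit] <- alt
    }
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Tree-evolved orthologous groups
#'
#' Generates `n_groups` random ancestral sequences (equal nucleotide
#' probabilities) and evolves each down a balanced binary tree of depth
#' log2(m) with the same per-branch, per-site substitution probability on
#' every branch. The leaves of each group become the m orthologous segments
#' with a common segment identifier, so that groups are alignable but
#' mutated.
#'
#' @param n_groups number of orthologous groups.
#' @param ancestor_length ancestral sequence length (nt).
#' @param m number of leaf species (a power of two).
#' @param rate per-branch per-site substitution probability.
#' @param rng_seed integer seed.
#' @return a list with `collection` (one segment per group per leaf; gene id
#'   equals segment id so that each group is its own gene) and `ancestors`
#'   (character vector of root sequences).
#' @export
evolve_on_tree <- function(n_groups = 100L, ancestor_length = 150L,
                           m = 16L, rate = 0.03, rng_seed = 1L) {
  depth <- log2(m)
  if (depth != round(depth)) stop("m must be a power of two")
  with_seed(rng_seed, {
    anc <- random_dna(rep(ancestor_length, n_groups))
    tips <- list(anc)
    for (d in seq_len(depth)) {
      tips <- unlist(lapply(tips, function(node)
        list(mutate_branch(node, rate), mutate_branch(node, rate))),
        recursive = FALSE)
    }
    species <- sprintf("sp%02d", seq_len(m))
    segs <- rbindlist(lapply(seq_len(m), function(i)
      data.table(species = species[i],
                 segment_id = sprintf("s%04d", seq_len(n_groups)),
                 gene_id = sprintf("s%04d", seq_len(n_groups)),
                 sequence = tips[[i]])))
    list(collection = segment_collection(segs, species_table(species)),
         ancestors = anc)
  })
}

#' Post-filter externally predicted duplexes
#'
#' Applies the benchmark filter to base-pair lists predicted by any external
#' tool: a segment pair is kept iff it has a run of at least `min_run`
#' consecutive complementary base pairs containing a window of `min_run`
#' pairs with at most `max_gt` G.T pairs, whose two words are conserved (by
#' the position-forgetting rule: each word occurs anywhere in the orthologous
#' segment) in at least `min_species` species.
#'
#' @param predictions a data.frame with columns `left_id`, `right_id`,
#'   `left_pos`, `right_pos`: one row per predicted base pair, 0-based
#'   positions in the reference species' segments; `left_pos` ascending pairs
#'   `right_pos` descending within a helix.
#' @param collection the [segment_collection()] the predictions refer to.
#' @param ref_species the species whose coordinates the predictions use.
#' @param min_run minimum consecutive complementary nucleotides (default 8).
#' @param max_gt maximum G.T pairs per window of `min_run` (default 1).
#' @param min_species minimum number of species conserving both words
#'   (default 12).
#' @return a data.table of kept (left_id, right_id) pairs.
#' @export
duplex_post_filter <- function(predictions, collection, ref_species,
                               min_run = 8L, max_gt = 1L, min_species = 12L) {
  pred <- as.data.table(predictions)
  need <- c("left_id", "right_id", "left_pos", "right_pos")
  if (!all(need %in% names(pred)))
    stop("malformed pairing list: need columns ",
         paste(need, collapse = ", "))
  segs <- collection$segments
  refseq <- function(id) segs[.(ref_species, id),
                              on = c("species", "segment_id"), sequence]
  species_seqs <- split(segs$sequence,
                        segs$species)[unique(segs$species)]
  kept <- pred[, {
    ok <- FALSE
    ls <- strsplit(refseq(left_id[1]), "")[[1]]
    rs <- strsplit(refseq(right_id[1]), "")[[1]]
    lj <- segs[segment_id == left_id[1]]
    rj <- segs[segment_id == right_id[1]]
    o <- order(left_pos)
    lp <- left_pos[o]; rp <- right_pos[o]
    lchr <- ls[lp + 1L]; rchr <- rs[rp + 1L]
    pairtype <- paste0(lchr, rchr)
    is_comp <- pairtype %in% c("AT", "TA", "CG", "GC", "GT", "TG")
    is_gt <- pairtype %in% c("GT", "TG")
    # non-complementary calls cannot belong to a helix: drop them, then
    # split what remains into runs of consecutive antiparallel pairs
    lp <- lp[is_comp]; rp <- rp[is_comp]
    lchr <- lchr[is_comp]; rchr <- rchr[is_comp]; is_gt <- is_gt[is_comp]
    if (length(lp) >= min_run) {
      brk <- cumsum(c(TRUE, diff(lp) != 1L | diff(rp) != -1L))
      for (run in split(seq_along(lp), brk)) {
        if (length(run) < min_run) next
        for (s in seq_len(length(run) - min_run + 1L)) {
          win <- run[s:(s + min_run - 1L)]
          if (sum(is_gt[win]) > max_gt) next
          lword <- paste(lchr[win], collapse = "")
          rword <- paste(rev(rchr[win]), collapse = "")
          consv <- sum(vapply(unique(segs$species), function(sp) {
            a <- lj[species == sp, sequence]
            b <- rj[species == sp, sequence]
            length(a) == 1L && length(b) == 1L &&
              grepl(lword, a, fixed = TRUE) && grepl(rword, b, fixed = TRUE)
          }, logical(1)))
          if (consv >= min_species) { ok <- TRUE; break }
        }
        if (ok) break
      }
    }
    .(kept = ok)
  }, by = .(left_id, right_id)]
  kept[kept == TRUE, .(left_id, right_id)]
}
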