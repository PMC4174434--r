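#' Assign segments to conservation x GC blocks
#'
#' Segments are binned on a quantile grid: `n_cons` quantile bins of the
#' segment conservation score (the mean, over the segment's k-mer start
#' positions, of the cross-species conservation weight) crossed with `n_gc`
#' quantile bins of GC fraction. Empty cells are allowed; degenerate
#' covariates collapse into fewer distinct bins. Covariates are computed on
#' the reference (highest-weight) species' copy of each segment.
#'
#' @param collection a [segment_collection()].
#' @param index the (untrimmed) `kmer_index` of the collection.
#' @param n_cons,n_gc numbers of quantile bins (defaults 25 x 20 = 500
#'   blocks).
#' @return an object of class `block_assignment`: a data.table with columns
#'   `segment_id`, `conservation`, `gc`, `block`.
#' @export
block_segments <- function(collection, index, n_cons = 25L, n_gc = 20L) {
  if (n_cons < 1 || n_gc < 1) stop("block factors must be >= 1")
  ref <- reference_species(collection$species_table)
  segs <- collection$segments[species == ref]
  if (nrow(segs) == 0L) stop("reference species has no segments")
  cw <- conservation_weights(index)
  occ_ref <- index$occ[species == ref & gap == 0L]
  occ_ref <- merge(occ_ref, cw, by = c("key", "segment_id"))
  cons <- occ_ref[, .(conservation = mean(wsum)), by = segment_id]
  gc <- segs[, .(segment_id,
                 gc = (nchar(gsub("[^GC]", "", sequence)) /
                       pmax(nchar(sequence), 1L)))]
  cov <- merge(gc, cons, by = "segment_id", all.x = TRUE)
  cov[is.na(conservation), conservation := 0]
  qbin <- function(x, q) {
    if (q == 1L || length(unique(x)) == 1L) return(rep(1L, length(x)))
    br <- unique(quantile(x, probs = seq(0, 1, length.out = q + 1L)))
    if (length(br) < 2L) return(rep(1L, length(x)))
    as.integer(cut(x, breaks = br, include.lowest = TRUE))
  }
  cov[, block := paste0("c", qbin(conservation, n_cons),
                        ".g", qbin(gc, n_gc))]
  setkey(cov, segment_id)
  structure(cov[, .(segment_id, conservation, gc, block)],
            class = c("block_assignment", "data.table", "data.frame"))
}

#' Rewire a relation preserving conservation/GC blocks
#'
#' Right endpoints of the relation are permuted uniformly at random within
#' their blocks, so the control relation pairs each left segment with a right
#' segment of matched conservation and GC content but (in general) from a
#' different gene — a null model for "no interaction in trans". Pairs that
#' land on the same gene as their left endpoint are re-drawn by swapping with
#' another random slot in the same block (up to `max_retry` attempts), then
#' dropped with a warning. The per-block multiset of right endpoints and the
#' left-endpoint multiset are preserved exactly (minus reported drops).
#'
#' @param relation a `cc_relation`.
#' @param blocks a [block_segments()] assignment covering all right
#'   endpoints.
#' @param gene_of named character vector mapping segment_id to gene_id (used
#'   for the same-gene exclusion); pairs with unknown genes are never
#'   excluded.
#' @param rng_seed integer seed; the rewiring is deterministic given it.
#' @param max_retry bounded retries per conflicting pair.
#' @return a rewired `cc_relation`.
#' @export
rewire_relation <- function(relation, blocks, gene_of, rng_seed,
                            max_retry = 100L) {
  rel <- as_relation(relation)
  bl <- as.data.table(blocks)
  missing_blk <- setdiff(rel$right_id, bl$segment_id)
  if (length(missing_blk))
    stop("right endpoint(s) not assigned to blocks: ",
         paste(head(missing_blk, 5), collapse = ", "))
  blk <- bl$block; names(blk) <- bl$segment_id
  with_seed(rng_seed, {
    out <- copy(rel)
    out[, blkid := blk[right_id]]
    out[, new_right := {
      idx <- sample.int(.N)
      right_id[idx]
    }, by = blkid]
    gene_l <- unname(gene_of[out$left_id])
    gene_r <- unname(gene_of[out$new_right])
    conflict <- which(!is.na(gene_l) & !is.na(gene_r) & gene_l == gene_r)
    nr <- out$new_right
    for (i in conflict) {
      if (!is.na(gene_of[out$left_id[i]]) &&
          !is.na(gene_of[nr[i]]) &&
          gene_of[out$left_id[i]] == gene_of[nr[i]]) {
        slots <- which(out$blkid == out$blkid[i])
        done <- FALSE
        for (r in seq_len(max_retry)) {
          j <- slots[sample.int(length(slots), 1L)]
          if (j == i) next
          gl_i <- gene_of[out$left_id[i]]; gr_j <- gene_of[nr[j]]
          gl_j <- gene_of[out$left_id[j]]; gr_i <- gene_of[nr[i]]
          ok_i <- is.na(gl_i) || is.na(gr_j) || gl_i != gr_j
          ok_j <- is.na(gl_j) || is.na(gr_i) || gl_j != gr_i
          if (ok_i && ok_j) {
            tmp <- nr[i]; nr[i] <- nr[j]; nr[j] <- tmp
            done <- TRUE
            break
          }
        }
        if (!done) nr[i] <- NA_character_
      }
    }
    dropped <- sum(is.na(nr))
    if (dropped > 0)
      warning(dropped, " pair(s) dropped: same-gene conflict unresolvable",
              call. = FALSE)
    res <- out[!is.na(nr)]
    res[, right_id := nr[!is.na(nr)]]
    as_relation(res[, .(left_id, right_id)])
  })
}

#' Estimate the false-discovery rate by relation rewiring
#'
#' Runs the full search once on the true relation (the reference set) and
#' `repeats` times on independently rewired relations (control sets), all at
#' the identical configuration, and reports FDR = mean control count /
#' reference count, where a count is the number of distinct segment pairs
#' carrying at least one duplex. Indexing and trimming are done once and
#' shared by all runs, since rewiring only changes the relation.
#'
#' @param collectionA,collectionB the two sides (pass the same object for
#'   intramolecular search).
#' @param relation the true `cc_relation`.
#' @param config a [search_config()].
#' @param repeats number of rewired controls (default 20).
#' @param rng_seed integer seed for the rewirings.
#' @param n_cons,n_gc blocking factors for [block_segments()].
#' @return an object of class `fdr_report`: list with `reference_count`,
#'   `control_counts`, `fdr_mean`, `fdr_se`, `ci95` (normal 95% interval),
#'   `repeats`. If the reference count is zero the FDR fields are `NA` and
#'   `undefined` is TRUE.
#' @export
estimate_fdr <- function(collectionA, collectionB, relation, config,
                         repeats = 20L, rng_seed = 1L,
                         n_cons = 25L, n_gc = 20L) {
  idxA <- build_index(collectionA, config)
  same <- identical(collectionA, collectionB)
  idxB <- if (same) idxA else build_index(collectionB, config)
  blocks <- block_segments(collectionB, idxB, n_cons = n_cons, n_gc = n_gc)
  trA <- trim_index(idxA, config$t0, config$delta)
  trB <- if (same) trA else trim_index(idxB, config$t0, config$delta)
  gene_map <- {
    gb <- unique(collectionB$segments[, .(segment_id, gene_id)])
    ga <- unique(collectionA$segments[, .(segment_id, gene_id)])
    gmap <- rbind(ga, gb)
    gmap <- unique(gmap)
    g <- gmap$gene_id; names(g) <- gmap$segment_id
    g
  }
  # count unordered segment pairs bearing a duplex; the alpha < beta dedup is
  # disabled so a pair is found whichever way round the rewiring orients it
  cfg_count <- config
  cfg_count$unique_flag <- FALSE
  count_pairs <- function(rel) {
    hits <- pair_and_trim(trA, trB, rel, cfg_count)
    dup <- merge_clusters(hits, cfg_count)
    if (nrow(dup) == 0L) return(0L)
    u <- unique(as.data.table(dup)[, .(left_id, right_id)])
    nrow(unique(u[, .(a = pmin(left_id, right_id),
                      b = pmax(left_id, right_id))]))
  }
  reference_count <- count_pairs(relation)
  seeds <- with_seed(rng_seed, sample.int(.Machine$integer.max, repeats))
  control_counts <- vapply(seeds, function(s) {
    ctrl <- rewire_relation(relation, blocks, gene_map, rng_seed = s)
    count_pairs(ctrl)
  }, integer(1))
  if (reference_count > 0L) {
    ratios <- control_counts / reference_count
    fdr_mean <- mean(ratios)
    fdr_se <- if (repeats > 1L) sd(ratios) / sqrt(repeats) else NA_real_
    ci95 <- if (is.na(fdr_se)) c(NA_real_, NA_real_)
            else fdr_mean + c(-1, 1) * qnorm(0.975) * fdr_se
    undefined <- FALSE
  } else {
    fdr_mean <- fdr_se <- NA_real_
    ci95 <- c(NA_real_, NA_real_)
    undefined <- TRUE
  }
  structure(list(reference_count = reference_count,
                 control_counts = control_counts,
                 fdr_mean = fdr_mean, fdr_se = fdr_se, ci95 = ci95,
                 repeats = repeats, undefined = undefined),
            class = "fdr_report")
}

#' @export
print.fdr_report <- function(x, ...) {
  cat("fdr_report:\n")
  cat("  reference segment pairs:", x$reference_count, "\n")
  cat("  control counts:", paste(x$control_counts, collapse = " "), "\n")
  if (x$undefined) {
    cat("  FDR: undefined (reference count is zero)\n")
  } else {
    cat(sprintf("  FDR = %.3f (SE %.3f, 95%% CI %.3f-%.3f, %d repeats)\n",
                x$fdr_mean, x$fdr_se, x$ci95[1], x$ci95[2], x$repeats))
  }
  invisible(x)
}
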