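# paired (non-gap) left positions of a seed instance at pos/gap
paired_positions <- function(pos, gap, k) {
  lh <- as.integer(ceiling(k / 2))
  c(pos + seq_len(lh) - 1L,
    if (k - lh > 0) pos + lh + gap + seq_len(k - lh) - 1L)
}

#' Merge overlapping conserved k-mer hits into duplexes
#'
#' Hits are grouped by segment pair; within a group, reference-species
#' quadruples are sorted by (p, p') and hits whose spans overlap or abut on a
#' common anti-diagonal (p + p' equal up to a shift of at most `gamma` for
#' gapped members) are merged into maximal clusters. The matched length of a
#' cluster is the number of distinct paired positions in the union of its
#' members; clusters shorter than `min_length` are discarded. The cluster
#' support weight is the minimum over members.
#'
#' @param hits a `cc_hits` table from [pair_and_trim()].
#' @param config a [search_config()].
#' @param min_length length filter; defaults to `config$L`. Pass `config$k`
#'   to keep every cluster.
#' @return a data.table of class `cc_duplexes`: one row per cluster with the
#'   two spans (0-based half-open), `matched_length`, `support_weight`,
#'   `n_members`, `anchor_key`, `support_species`, `ref_species`, and a
#'   `members` list-column holding the member hit rows.
#' @export
merge_clusters <- function(hits, config, min_length = config$L) {
  stopifnot(inherits(config, "search_config"))
  k <- config$k
  dt <- as.data.table(hits)
  empty <- data.table(left_id = character(), left_start = integer(),
                      left_end = integer(), right_id = character(),
                      right_start = integer(), right_end = integer(),
                      matched_length = integer(), support_weight = numeric(),
                      n_members = integer(), anchor_key = character(),
                      support_species = character(), ref_species = character(),
                      members = list())
  if (nrow(dt) == 0L)
    return(structure(empty, class = c("cc_duplexes", class(empty))))

  res <- dt[order(left_id, right_id, pos, pos2), {
    n <- .N
    p <- pos; g <- gap; p2 <- pos2; g2 <- gap2
    endl <- p + k + g; endr <- p2 + k + g2
    diag <- p + p2
    comp <- seq_len(n)                      # union-find over member hits
    find <- function(i) { while (comp[i] != i) i <- comp[i] <- comp[comp[i]]; i }
    for (i in seq_len(n)) for (jj in seq_len(n)) if (jj > i) {
      overlap_l <- p[jj] < endl[i] + 1L && p[i] < endl[jj] + 1L
      overlap_r <- p2[jj] < endr[i] + 1L && p2[i] < endr[jj] + 1L
      if (overlap_l && overlap_r && abs(diag[i] - diag[jj]) <= config$gamma) {
        ri <- find(i); rj <- find(jj)
        if (ri != rj) comp[rj] <- ri
      }
    }
    root <- vapply(seq_len(n), find, integer(1))
    cl <- split(seq_len(n), root)
    rbindlist(lapply(cl, function(idx) {
      lpos <- unique(unlist(lapply(idx, function(i)
        paired_positions(p[i], g[i], k))))
      data.table(
        left_start = min(p[idx]), left_end = max(endl[idx]),
        right_start = min(p2[idx]), right_end = max(endr[idx]),
        matched_length = length(lpos),
        support_weight = min(support_weight[idx]),
        n_members = length(idx),
        anchor_key = key[idx][which.min(p[idx])],
        support_species = paste(Reduce(intersect,
          strsplit(support_species[idx], ",", fixed = TRUE)), collapse = ","),
        ref_species = ref_species[1],
        members = list(setDT(list(key = key[idx], pos = p[idx], gap = g[idx],
                                  chi = chi[idx], pos2 = p2[idx],
                                  gap2 = g2[idx],
                                  support_weight = support_weight[idx])))
      )
    }))
  }, by = .(left_id, right_id)]
  res <- res[matched_length >= min_length]
  setcolorder(res, names(empty))
  setkey(res, left_id, right_id, left_start)
  structure(res, class = c("cc_duplexes", class(res)))
}

# per-(species, segment) background rate rho: fraction of ungapped k-mer
# start positions whose conservation weight is >= t
conservation_rates <- function(index, t) {
  cw <- conservation_weights(index)
  occ0 <- index$occ[gap == 0L]
  occ0 <- merge(occ0, cw, by = c("key", "segment_id"))
  cons <- occ0[, .(n_cons = sum(wsum >= t)), by = .(species, segment_id)]
  out <- merge(index$seg_lengths, cons, by = c("species", "segment_id"),
               all.x = TRUE)
  out[is.na(n_cons), n_cons := 0L]
  out[, n_starts := pmax(length - index$k + 1L, 0L)]
  out[, rho := ifelse(n_starts > 0, n_cons / n_starts, 0)]
  out[]
}

#' Attach significance scores to duplexes
#'
#' The score has two components. C1 measures how unlikely the duplex's flanks
#' of conserved k-mer starts are under the segment's background conservation
#' rate rho (conserved starts modeled as independent Bernoulli(rho) events
#' over the l - k + 1 starts of each side): C1_side =
#' -(l_side - k + 1) * log10(rho_side), with rho floored at
#' 1/(number of starts + 1). C2 measures the specificity of the complement
#' among relation partners: C2 = -log10(complement_occurrences /
#' partner_count). The total is their sum; duplexes are returned ranked by
#' decreasing total. A highly conserved segment (rho near 1) yields C1 near
#' 0, and a promiscuous complement yields a small C2.
#'
#' @param duplexes a `cc_duplexes` table.
#' @param hits the `cc_hits` the duplexes were merged from.
#' @param indexA,indexB the untrimmed indexes of the two sides.
#' @param relation the `cc_relation` used in the search.
#' @param config a [search_config()].
#' @return the duplexes with columns `C1_left`, `C1_right`, `C2`, `score`,
#'   ordered by decreasing score.
#' @export
score_duplexes <- function(duplexes, hits, indexA, indexB, relation, config) {
  dup <- as.data.table(duplexes)
  if (nrow(dup) == 0L) {
    dup[, `:=`(C1_left = numeric(), C1_right = numeric(), C2 = numeric(),
               score = numeric())]
    return(structure(dup, class = c("cc_duplexes", class(dup))))
  }
  rel <- as_relation(relation)
  partner_n <- rel[, .(partner_count = uniqueN(right_id)), by = left_id]
  if (any(!dup$left_id %in% partner_n$left_id))
    stop("duplex left segment with no relation partners")
  k <- config$k
  ratesA <- conservation_rates(indexA, config$t)
  ratesB <- conservation_rates(indexB, config$t)
  hitdt <- as.data.table(hits)

  c1 <- function(rates, species, seg, span_len) {
    # build the join table outside the i-expression: inside `rates[...]`,
    # bare `species` would resolve to the rates column, not the argument
    itab <- data.table(species = species, segment_id = seg)
    r <- rates[itab, on = c("species", "segment_id")]
    rho <- pmax(r$rho, 1 / (r$n_starts + 1))
    -(span_len - k + 1) * log10(rho)
  }
  dup[, C1_left := c1(ratesA, ref_species, left_id, left_end - left_start)]
  dup[, C1_right := c1(ratesB, ref_species, right_id, right_end - right_start)]
  dup[, C2 := {
    keys <- vapply(members, function(m) m$key[1], character(1))
    vapply(seq_len(.N), function(i) {
      mkeys <- members[[i]]$key
      co <- hitdt[left_id == dup$left_id[i] & key %in% mkeys,
                  uniqueN(right_id)]
      pc <- partner_n[.(dup$left_id[i]), on = "left_id", partner_count]
      -log10(max(co, 1L) / pc)
    }, numeric(1))
  }]
  dup[, score := C1_left + C1_right + C2]
  setorder(dup, -score)
  structure(dup, class = c("cc_duplexes", class(dup)))
}

#' Write duplexes as a BED-like TSV
#'
#' One line per duplex: both anchored intervals (0-based half-open), matched
#' length, support weight and the score components.
#'
#' @param duplexes a `cc_duplexes` table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_duplexes <- function(duplexes, path) {
  dt <- as.data.table(duplexes)
  cols <- intersect(c("left_id", "left_start", "left_end", "right_id",
                      "right_start", "right_end", "matched_length",
                      "support_weight", "n_members", "anchor_key",
                      "support_species", "ref_species",
                      "C1_left", "C1_right", "C2", "score"), names(dt))
  fwrite(dt[, ..cols], path, sep = "\t")
  invisible(path)
}

# star alignment: align every sequence pairwise to the center and merge on
# center coordinates (match +1, mismatch -1, gap -2 per gap column)
star_align <- function(seqs, center = 1L) {
  n <- length(seqs)
  if (n == 1L) return(matrix(strsplit(seqs, "")[[1]], nrow = 1))
  if (any(!nzchar(seqs))) seqs[!nzchar(seqs)] <- ""
  cseq <- seqs[center]
  if (!nzchar(cseq))
    return(matrix("", nrow = n, ncol = 0))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -1,
                                                     baseOnly = FALSE)
  clen <- nchar(cseq)
  # per species: aligned pattern/subject strings vs the center
  aln <- lapply(seq_len(n), function(i) {
    if (i == center) return(list(p = cseq, s = cseq))
    if (!nzchar(seqs[i]))
      return(list(p = strrep("-", clen), s = cseq))
    pa <- Biostrings::pairwiseAlignment(
      pattern = seqs[i], subject = cseq, type = "global",
      substitutionMatrix = submat, gapOpening = 0, gapExtension = 2)
    list(p = as.character(Biostrings::alignedPattern(pa)),
         s = as.character(Biostrings::alignedSubject(pa)))
  })
  # number of insertion columns after each center position (0 = before first)
  ins <- matrix(0L, nrow = n, ncol = clen + 1L)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- strsplit(aln[[i]]$s, "")[[1]]
    p <- strsplit(aln[[i]]$p, "")[[1]]
    cpos <- 0L
    run <- integer(clen + 1L)
    cells <- vector("list", clen + 1L)
    buf <- character(0)
    for (u in seq_along(s)) {
      if (s[u] == "-") buf <- c(buf, p[u])
      else {
        cells[[cpos + 1L]] <- buf
        run[cpos + 1L] <- length(buf)
        cpos <- cpos + 1L
        buf <- p[u]
      }
    }
    cells[[cpos + 1L]] <- buf
    run[cpos + 1L] <- length(buf)
    # cells[[v]] holds the insertion run before center position v plus (for
    # v > 1) the character at center position v-1 at its end — rearrange:
    rows[[i]] <- cells
    ins[i, ] <- pmax(run - c(0L, rep(1L, clen)), 0L)
  }
  width <- apply(ins, 2, max)
  out <- matrix("-", nrow = n, ncol = sum(width) + clen)
  for (i in seq_len(n)) {
    pos <- 0L
    for (v in seq_len(clen + 1L)) {
      cell <- rows[[i]][[v]]
      nins <- if (v == 1L) length(cell) else length(cell) - 1L
      base <- if (v == 1L) character(0) else cell[length(cell)]
      insrun <- if (v == 1L) cell else cell[-length(cell)]
      if (v > 1L) { out[i, pos + 1L] <- base; pos <- pos + 1L }
      if (nins > 0) out[i, pos + seq_len(nins)] <- insrun
      pos <- pos + width[v]
    }
  }
  rownames(out) <- names(seqs)
  out
}

# middle-trim a sequence to at most `cap` nt (first/last cap/2 kept)
middle_trim <- function(x, cap = 150L) {
  if (cap %% 2 == 1L) cap <- cap - 1L
  ifelse(nchar(x) <= cap, x, cap_segment(x, cap))
}

#' Naive structure-anchored alignment of a segment pair
#'
#' For each segment pair, exactly one duplex is selected: the one with the
#' longest matched length, ties broken by the smallest (p, p'). The
#' complementary boxes and the flanking intervals are each aligned separately
#' across the supporting species (star alignment centered on the reference
#' species) and concatenated into one display alignment per side. Flanks
#' longer than 150 nt are middle-trimmed before alignment. Box columns are
#' reported per side.
#'
#' @param duplexes a `cc_duplexes` table.
#' @param collectionA,collectionB the collections the search ran on.
#' @param indexA,indexB the (trimmed) indexes, used to locate per-species
#'   instances of the anchor k-mer.
#' @param config a [search_config()].
#' @param flank_cap maximum flank length before middle-trimming (nt).
#' @return a list of per-segment-pair alignments; each element has
#'   `left_id`, `right_id`, the selected duplex row, `left_alignment` and
#'   `right_alignment` (character matrices, species by columns) and
#'   `left_box_cols` / `right_box_cols` (column ranges of the boxes).
#' @export
naive_alignment <- function(duplexes, collectionA, collectionB,
                            indexA, indexB, config, flank_cap = 150L) {
  dup <- as.data.table(duplexes)
  if (nrow(dup) == 0L) return(list())
  # one duplex per segment pair: longest, then first occurring
  sel <- dup[order(-matched_length, left_start, right_start),
             .SD[1], by = .(left_id, right_id)]
  segsA <- collectionA$segments
  segsB <- collectionB$segments
  lapply(seq_len(nrow(sel)), function(i) {
    d <- sel[i]
    spp <- strsplit(d$support_species, ",", fixed = TRUE)[[1]]
    ref <- d$ref_species
    spp <- c(ref, setdiff(spp, ref))
    side <- function(index, segs, seg_id, anchor, box_len) {
      spans <- lapply(spp, function(s) {
        o <- index$occ[.(s, anchor, seg_id),
                       on = c("species", "key", "segment_id"),
                       nomatch = 0L]
        full <- segs[.(s, seg_id), on = c("species", "segment_id"), sequence]
        if (nrow(o) == 0L || is.na(full))
          return(list(seq = full, start = NA_integer_, end = NA_integer_))
        p <- o$pos[1]; g <- o$gap[1]
        list(seq = full, start = p,
             end = min(p + box_len + g, nchar(full)))
      })
      names(spans) <- spp
      spans
    }
    box_len_l <- d$left_end - d$left_start
    box_len_r <- d$right_end - d$right_start
    anchor_chi <- d$members[[1]]$chi[which.min(d$members[[1]]$pos2)]
    lsp <- side(indexA, segsA, d$left_id, d$anchor_key, box_len_l)
    rsp <- side(indexB, segsB, d$right_id, anchor_chi, box_len_r)
    build <- function(spans) {
      pre <- vapply(spans, function(z)
        if (is.na(z$start)) "" else substr(z$seq, 1, z$start), character(1))
      box <- vapply(spans, function(z)
        if (is.na(z$start)) "" else substr(z$seq, z$start + 1, z$end),
        character(1))
      post <- vapply(spans, function(z)
        if (is.na(z$start)) "" else substring(z$seq, z$end + 1), character(1))
      a_pre <- star_align(middle_trim(pre, flank_cap))
      a_box <- star_align(box)
      a_post <- star_align(middle_trim(post, flank_cap))
      mat <- cbind(a_pre, a_box, a_post)
      rownames(mat) <- names(spans)
      list(alignment = mat,
           box_cols = if (ncol(a_box)) ncol(a_pre) + seq_len(ncol(a_box))
                      else integer(0))
    }
    lb <- build(lsp); rb <- build(rsp)
    list(left_id = d$left_id, right_id = d$right_id, duplex = d,
         left_alignment = lb$alignment, left_box_cols = lb$box_cols,
         right_alignment = rb$alignment, right_box_cols = rb$box_cols)
  })
}

#' Render a naive alignment entry as plain text
#'
#' @param entry one element of the [naive_alignment()] result.
#' @return a character vector of report lines.
#' @export
format_alignment <- function(entry) {
  fmt <- function(mat, box_cols, tag) {
    if (ncol(mat) == 0L) return(character(0))
    marker <- rep(" ", ncol(mat))
    marker[box_cols] <- "*"
    c(sprintf("# %s", tag),
      paste0(formatC(rownames(mat), width = 12), " ",
             apply(mat, 1, paste, collapse = "")),
      paste0(strrep(" ", 13), paste(marker, collapse = "")))
  }
  c(sprintf("## %s -- %s", entry$left_id, entry$right_id),
    fmt(entry$left_alignment, entry$left_box_cols, entry$left_id),
    fmt(entry$right_alignment, entry$right_box_cols, entry$right_id))
}
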