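#' Trim a k-mer index by weighted cross-species conservation
#'
#' For each key omega and segment id j, the conservation weight w(omega, j)
#' is the sum of weights of the species whose segment s_ij contains omega
#' anywhere (each species counted once: the position-forgetting rule).
#' Occurrences are retained iff w(omega, j) >= t0. With a finite `delta`, a
#' non-reference species contributes only if one of its occurrences lies
#' within `delta` nt of an occurrence in the reference species (the
#' highest-weight species carrying the key in that segment).
#'
#' @param index a `kmer_index` (see [build_index()]).
#' @param t0 trimming threshold in `[0, 1]`.
#' @param delta positional divergence bound (nt) or `Inf` (default).
#' @return a `kmer_index` whose occurrence table is a subset of the input,
#'   still sorted.
#' @export
trim_index <- function(index, t0, delta = Inf) {
  stopifnot(inherits(index, "kmer_index"), t0 >= 0, t0 <= 1)
  occ <- index$occ
  if (nrow(occ) == 0L || t0 == 0 && is.infinite(delta)) {
    index$trimmed_at <- max(t0, index$trimmed_at %||% 0)
    return(index)
  }
  w <- weight_lookup(index$species_table)
  if (is.infinite(delta)) {
    pres <- unique(occ[, .(key, segment_id, species)])
  } else {
    pos <- unique(occ[, .(key, segment_id, species, pos)])
    sp_order <- index$species_table$species       # ties broken by table order
    pres <- pos[, {
      sp <- unique(species)
      ref <- sp[order(-w[sp], match(sp, sp_order))][1]
      refpos <- pos[species == ref]     # pos column within this group
      ok <- vapply(sp, function(s) {
        s == ref || min(abs(outer(pos[species == s], refpos, "-"))) < delta
      }, logical(1))
      .(species = sp[ok])
    }, by = .(key, segment_id)]
  }
  pres[, wgt := w[species]]
  grp <- pres[, .(wsum = sum(wgt)), by = .(key, segment_id)]
  keep_keys <- grp[wsum >= t0, .(key, segment_id)]
  if (is.finite(delta)) {
    keep <- occ[pres[keep_keys, on = c("key", "segment_id"),
                     .(key, segment_id, species)],
                on = c("key", "segment_id", "species"), nomatch = 0L]
  } else {
    keep <- occ[keep_keys, on = c("key", "segment_id"), nomatch = 0L]
  }
  setkey(keep, species, key, segment_id, pos)
  index$occ <- keep
  index$trimmed_at <- max(t0, index$trimmed_at %||% 0)
  index
}

# conservation weight per (key, segment_id) of an index
conservation_weights <- function(index) {
  w <- weight_lookup(index$species_table)
  pres <- unique(index$occ[, .(key, segment_id, species)])
  pres[, wgt := w[species]]
  pres[, .(wsum = sum(wgt)), by = .(key, segment_id)]
}

#' Pair trimmed indexes into conserved complementary k-mer hits
#'
#' For every key omega of the left index, a species i supports the segment
#' pair (j, j') iff omega occurs in s_ij and some chi in the wobble
#' complement set of omega occurs in s_ij'. A hit is emitted iff (j, j') is
#' in the relation and the summed weight of supporting species is >= t.
#' Positional instances are reported in the coordinates of the reference
#' species (the highest-weight supporting species); one row is emitted per
#' combination of reference-species occurrences.
#'
#' With `unique_flag`, only instances with (j, p) < (j', p') in lexicographic
#' order are reported, and same-segment instances with overlapping spans are
#' excluded (non-overlapping self-complementarity, a hairpin, is kept).
#'
#' @param indexA,indexB `kmer_index` objects already trimmed at t0 <= t.
#' @param relation a `cc_relation` from [build_relation()].
#' @param config a [search_config()].
#' @return a data.table of class `cc_hits`: columns `key`, `left_id`, `pos`,
#'   `gap`, `chi`, `right_id`, `pos2`, `gap2`, `support_weight`, `n_support`,
#'   `support_species`, `ref_species`.
#' @export
pair_and_trim <- function(indexA, indexB, relation, config) {
  stopifnot(inherits(indexA, "kmer_index"), inherits(indexB, "kmer_index"),
            inherits(config, "search_config"))
  if (indexA$k != indexB$k || indexA$gamma != indexB$gamma)
    stop("key-space mismatch: indexes differ in k or gamma")
  if (!is.null(indexA$trimmed_at) && indexA$trimmed_at > config$t)
    stop("t must be >= the threshold the index was trimmed at")
  rel <- as_relation(relation)
  empty <- setDT(list(key = character(), left_id = character(),
                      pos = integer(), gap = integer(), chi = character(),
                      right_id = character(), pos2 = integer(),
                      gap2 = integer(), support_weight = numeric(),
                      n_support = integer(), support_species = character(),
                      ref_species = character()))
  mk <- function(dt) {
    setattr(dt, "class", c("cc_hits", class(dt)))
    setattr(dt, "config", config)
    dt
  }
  occA <- indexA$occ; occB <- indexB$occ
  if (nrow(occA) == 0L || nrow(occB) == 0L || nrow(rel) == 0L)
    return(mk(empty))

  w <- weight_lookup(indexA$species_table)
  sp_order <- indexA$species_table$species
  LA <- unique(occA[, .(key, left_id = segment_id, species)])
  RB <- unique(occB[, .(chi = key, right_id = segment_id, species)])

  keys <- unique(LA$key)
  wmap <- rbindlist(lapply(keys, function(om) {
    ch <- wobble_complements(om, config$G, config$h)
    if (length(ch)) setDT(list(key = rep(om, length(ch)), chi = ch)) else NULL
  }))
  if (is.null(wmap) || nrow(wmap) == 0L) return(mk(empty))

  RBx <- merge(RB, wmap, by = "chi", allow.cartesian = TRUE)
  if (nrow(RBx) == 0L) return(mk(empty))
  RBseg <- unique(RBx[, .(key, right_id, species)])

  sup <- merge(LA, RBseg, by = c("key", "species"), allow.cartesian = TRUE)
  sup <- sup[rel, on = c("left_id", "right_id"), nomatch = 0L]
  if (nrow(sup) == 0L) return(mk(empty))
  sup[, wgt := w[species]]
  pairs <- sup[, .(support_weight = sum(wgt), n_support = .N,
                   support_species = paste(
                     species[order(match(species, sp_order))], collapse = ","),
                   ref_species = species[order(-wgt, match(species, sp_order))][1]),
               by = .(key, left_id, right_id)]
  pairs <- pairs[support_weight >= config$t]
  if (nrow(pairs) == 0L) return(mk(empty))

  # attach reference-species positional instances (Cartesian within pair)
  lp <- occA[, .(species, key, left_id = segment_id, pos, gap)]
  lsel <- lp[pairs[, .(key, left_id, right_id, species = ref_species)],
             on = c("key", "left_id", "species"), nomatch = 0L,
             allow.cartesian = TRUE]
  hits <- merge(pairs, lsel[, .(key, left_id, right_id, pos, gap)],
                by = c("key", "left_id", "right_id"))
  rp <- merge(occB[, .(species, chi = key, right_id = segment_id,
                       pos2 = pos, gap2 = gap)],
              unique(RBx[, .(key, chi, right_id)]),
              by = c("chi", "right_id"), allow.cartesian = TRUE)
  rsel <- rp[pairs[, .(key, right_id, left_id, species = ref_species)],
             on = c("key", "right_id", "species"), nomatch = 0L,
             allow.cartesian = TRUE]
  hits <- merge(hits,
                rsel[, .(key, left_id, right_id, chi, pos2, gap2)],
                by = c("key", "left_id", "right_id"),
                allow.cartesian = TRUE)

  # a span never pairs with itself: same-segment instances must not overlap
  k <- config$k
  hits <- hits[left_id != right_id |
               (pos + k + gap <= pos2) | (pos2 + k + gap2 <= pos)]
  if (config$unique_flag) {
    hits <- hits[left_id < right_id |
                 (left_id == right_id & pos < pos2)]
  }
  setcolorder(hits, c("key", "left_id", "pos", "gap", "chi", "right_id",
                      "pos2", "gap2", "support_weight", "n_support",
                      "support_species", "ref_species"))
  setkey(hits, left_id, right_id, pos, pos2)
  mk(hits)
}

#' Write hits as TSV
#'
#' @param hits a `cc_hits` table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_hits <- function(hits, path) {
  fwrite(as.data.table(hits), path, sep = "\t")
  invisible(path)
}
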