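# Brute-force oracle implementations, written directly from the definitions
# and independent of the package's index/trim/pair code path.

.oracle_env <- new.env()

# all 4^k words as a character matrix (rows = words, cols = positions)
all_words_matrix <- function(k) {
  keyname <- paste0("w", k)
  if (!is.null(.oracle_env[[keyname]])) return(.oracle_env[[keyname]])
  grid <- do.call(expand.grid,
                  c(rep(list(c("A", "C", "G", "T")), k),
                    stringsAsFactors = FALSE))
  m <- as.matrix(grid[, rev(seq_len(k)), drop = FALSE])
  .oracle_env[[keyname]] <- m
  m
}

# wobble complement set by exhaustive enumeration of all 4^k candidates
oracle_wobble <- function(omega, G, h) {
  chars <- strsplit(omega, "", fixed = TRUE)[[1]]
  k <- length(chars)
  W <- all_words_matrix(k)
  n_wc <- matrix(FALSE, nrow(W), k)
  n_wob <- matrix(FALSE, nrow(W), k)
  n_gc <- matrix(FALSE, nrow(W), k)
  for (u in seq_len(k)) {
    partner <- W[, k + 1L - u]           # chi position k-1-u pairs omega[u]
    pairstr <- paste0(chars[u], partner)
    n_wc[, u] <- pairstr %in% c("AT", "TA", "GC", "CG")
    n_wob[, u] <- pairstr %in% c("GT", "TG")
    n_gc[, u] <- pairstr %in% c("GC", "CG")
  }
  ok <- rowSums(n_wc | n_wob) == k &
    rowSums(n_wob) <= G &
    rowSums(n_gc) >= h
  apply(W[ok, , drop = FALSE], 1, paste, collapse = "")
}

# every (key, 0-based pos, gap) window of a sequence, by explicit loops
oracle_windows <- function(seq, k, gamma) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  lh <- ceiling(k / 2)
  out <- list()
  for (g in 0:gamma) {
    span <- k + g
    if (n < span) next
    for (p in 0:(n - span)) {
      idx <- c(p + seq_len(lh), p + lh + g + seq_len(k - lh))
      letters <- chars[idx]
      if (any(!letters %in% c("A", "C", "G", "T"))) next
      out[[length(out) + 1L]] <-
        data.frame(key = paste(letters, collapse = ""), pos = p, gap = g,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(key = character(), pos = integer(), gap = integer()))
  do.call(rbind, out)
}

# does `key` occur (as a possibly gapped seed) anywhere in `seq`?
# (window sets per sequence are cached; the windows themselves still come
# from the loop-based enumeration above)
oracle_contains <- function(seq, key, k, gamma) {
  id <- paste0("ks:", k, ":", gamma, ":", seq)
  ks <- .oracle_env[[id]]
  if (is.null(ks)) {
    ks <- unique(oracle_windows(seq, k, gamma)$key)
    .oracle_env[[id]] <- ks
  }
  key %in% ks
}

# definition-level search: trim both sides at t0 (position-forgetting
# conservation weight per key and segment), then for each relation pair and
# each key of side A count species carrying the key on the left and any
# wobble complement on the right; emit pairs with summed weight >= t.
# Returns unique (key, left_id, right_id, support_weight).
oracle_search <- function(collA, collB, relation, cfg) {
  w <- collA$species_table$weight
  names(w) <- collA$species_table$species
  segsA <- as.data.table(collA$segments)
  segsB <- as.data.table(collB$segments)
  segsA[, sequence := cap_segment(sequence, cfg$M)]
  segsB[, sequence := cap_segment(sequence, cfg$M)]
  sp <- collA$species_table$species
  contains <- function(segs, sp_id, seg_id, word) {
    s <- segs$sequence[segs$species == sp_id & segs$segment_id == seg_id]
    length(s) == 1L && oracle_contains(s, word, cfg$k, cfg$gamma)
  }
  # conservation weight of key in segment id over a side
  consw <- function(segs, id, key) {
    sum(w[vapply(sp, function(s) contains(segs, s, id, key), logical(1))])
  }
  rel <- unique(as.data.frame(relation))
  out <- list()
  keysA <- unique(unlist(lapply(segsA$sequence, function(s)
    oracle_windows(s, cfg$k, cfg$gamma)$key)))
  wobset <- lapply(keysA, oracle_wobble, G = cfg$G, h = cfg$h)
  names(wobset) <- keysA
  for (r in seq_len(nrow(rel))) {
    j <- rel$left_id[r]; j2 <- rel$right_id[r]
    for (key in keysA) {
      if (consw(segsA, j, key) < cfg$t0) next     # left side trimmed at t0
      chis <- wobset[[key]]
      chis <- chis[vapply(chis, function(ch)
        consw(segsB, j2, ch) >= cfg$t0, logical(1))]  # right side trimmed
      if (!length(chis)) next
      supp <- vapply(sp, function(s) {
        contains(segsA, s, j, key) &&
          any(vapply(chis, function(ch) contains(segsB, s, j2, ch),
                     logical(1)))
      }, logical(1))
      sw <- sum(w[supp])
      if (sw >= cfg$t) {
        out[[length(out) + 1L]] <- data.frame(
          key = key, left_id = j, right_id = j2,
          support_weight = round(sw, 9), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(setDT(list(key = character(), left_id = character(),
                      right_id = character(), support_weight = numeric())))
  setkey(unique(as.data.table(do.call(rbind, out))), key, left_id, right_id)[]
}
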