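#' Enumerate (optionally gapped) k-mer seeds of a sequence
#'
#' Emits every ungapped k-window and, for each gap size g in 1..gamma, every
#' window of span k+g whose middle g letters are skipped. The gap sits
#' strictly between the two halves of ceiling(k/2) and floor(k/2) letters; the
#' seed key is the concatenation of the halves, so seeds with different gap
#' sizes but identical halves share one key (the gap content is forgotten).
#' Windows overlapping an N are skipped.
#'
#' @param sequence DNA string.
#' @param k seed length (letters in the key).
#' @param gamma maximum central gap size.
#' @return a data.table with columns `key`, `pos` (0-based start of the
#'   window), `gap` (gap size; span is k+gap).
#' @export
enumerate_seeds <- function(sequence, k, gamma = 0L) {
  k <- as.integer(k); gamma <- as.integer(gamma)
  if (k < 4) stop("k must be >= 4")
  if (gamma < 0) stop("gamma must be >= 0")
  n <- nchar(sequence)
  lh <- as.integer(ceiling(k / 2))
  rh <- k - lh
  out <- vector("list", gamma + 1L)
  for (g in 0:gamma) {
    span <- k + g
    if (n < span) { out[[g + 1L]] <- NULL; next }
    starts <- seq_len(n - span + 1L)           # 1-based
    if (g == 0L) {
      keys <- substring(sequence, starts, starts + k - 1L)
    } else {
      keys <- paste0(substring(sequence, starts, starts + lh - 1L),
                     substring(sequence, starts + lh + g,
                               starts + lh + g + rh - 1L))
    }
    keep <- !grepl("N", keys, fixed = TRUE)
    # the skipped gap letters may be anything (including N): only the key
    # letters must be called bases
    if (any(keep))
      out[[g + 1L]] <- setDT(list(key = keys[keep],
                                  pos = starts[keep] - 1L,
                                  gap = rep(g, sum(keep))))
  }
  res <- rbindlist(out)
  if (nrow(res) == 0L)
    res <- setDT(list(key = character(), pos = integer(), gap = integer()))
  res[]
}

#' Wobble-tolerant complement set of a k-mer
#'
#' All words chi whose antiparallel pairing against omega (position u of
#' omega pairs position k-1-u of chi) consists of Watson-Crick pairs plus at
#' most G wobble G.T pairs, and contains at least h G-C pairs. For gapped
#' seeds the key letters pair as if the gaps were excised.
#'
#' @param omega k-mer key (no N).
#' @param G maximum number of G.T wobbles.
#' @param h minimum number of G-C pairs.
#' @return character vector of complement keys (possibly empty).
#' @export
wobble_complements <- function(omega, G = 0L, h = 0L) {
  chars <- strsplit(omega, "", fixed = TRUE)[[1]]
  k <- length(chars)
  if (any(!chars %in% c("A", "C", "G", "T")))
    stop("omega must be over {A,C,G,T}")
  # per position: the Watson-Crick partner, plus the wobble partner where
  # omega has G (partner T) or T (partner G)
  wc <- unname(.COMP[chars])
  wobblable <- which(chars %in% c("G", "T"))
  n_gc_wc <- sum(chars %in% c("G", "C"))
  res <- character(0)
  maxw <- min(G, length(wobblable))
  for (nw in 0:maxw) {
    combos <- if (nw == 0L) list(integer(0))
              else if (length(wobblable) == 1L) list(wobblable)
              else combn(wobblable, nw, simplify = FALSE)
    for (idx in combos) {
      # a wobbled G position loses its G-C pair; a wobbled T position never
      # had one
      n_gc <- n_gc_wc - sum(chars[idx] == "G")
      if (n_gc < h) next
      partner <- wc
      partner[idx] <- ifelse(chars[idx] == "G", "T", "G")
      # partner[u] pairs position u of omega, i.e. sits at k-1-u of chi
      res <- c(res, paste(rev(partner), collapse = ""))
    }
  }
  unique(res)
}

#' Build the per-species k-mer index of a collection
#'
#' The index H_i(omega) maps each seed key to its occurrences (segment j,
#' position p, gap g) per species, kept sorted lexicographically by
#' (segment_id, position). Segments are capped at M nucleotides first.
#'
#' @param collection a [segment_collection()].
#' @param config a [search_config()].
#' @param cap apply the M cap before indexing (default TRUE).
#' @return an object of class `kmer_index`: a list with the occurrence
#'   data.table (`occ`: species, key, segment_id, pos, gap), `k`, `gamma`,
#'   `side_label`, and per-segment `seg_lengths`.
#' @export
build_index <- function(collection, config, cap = TRUE) {
  stopifnot(inherits(collection, "segment_collection"),
            inherits(config, "search_config"))
  if (cap) collection <- cap_collection(collection, config$M)
  segs <- collection$segments
  occ_list <- vector("list", nrow(segs))
  for (r in seq_len(nrow(segs))) {
    s <- enumerate_seeds(segs$sequence[r], config$k, config$gamma)
    if (nrow(s)) {
      s[, species := segs$species[r]]
      s[, segment_id := segs$segment_id[r]]
    }
    occ_list[[r]] <- s
  }
  occ <- rbindlist(occ_list, use.names = TRUE, fill = TRUE)
  if (nrow(occ) == 0L)
    occ <- setDT(list(species = character(), key = character(),
                      segment_id = character(), pos = integer(),
                      gap = integer()))
  setcolorder(occ, c("species", "key", "segment_id", "pos", "gap"))
  setkey(occ, species, key, segment_id, pos)
  seg_lengths <- segs[, .(species, segment_id, length = nchar(sequence))]
  structure(list(occ = occ, k = config$k, gamma = config$gamma,
                 side_label = collection$side_label,
                 species_table = collection$species_table,
                 seg_lengths = seg_lengths),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index (side %s): k=%d gamma=%d, %d occurrences, %d keys, %d species\n",
              x$side_label, x$k, x$gamma, nrow(x$occ),
              length(unique(x$occ$key)), length(unique(x$occ$species))))
  invisible(x)
}

#' Write / read a trimmed index as sorted TSV meta-data
#'
#' The two-threshold workflow stores tables trimmed at an intermediate t0 and
#' reloads them for re-trimming at a higher t.
#'
#' @param index a `kmer_index`.
#' @param path file path.
#' @return `write_index` returns the path invisibly; `read_index` the index.
#' @export
write_index <- function(index, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#ccfind-index k=%d gamma=%d side=%s",
                     index$k, index$gamma, index$side_label), con)
  writeLines(paste0("#species\t",
                    paste(index$species_table$species, collapse = ","), "\t",
                    paste(format(index$species_table$weight, digits = 17),
                          collapse = ",")), con)
  sl <- index$seg_lengths
  writeLines(paste0("#seglen\t", sl$species, "\t", sl$segment_id, "\t",
                    sl$length), con)
  occ <- index$occ
  writeLines(paste(occ$species, occ$key, occ$segment_id, occ$pos, occ$gap,
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  m <- regmatches(hdr, regexec("k=(\\d+) gamma=(\\d+) side=(\\w+)", hdr))[[1]]
  if (length(m) != 4) stop("not a ccfind index file")
  sp_line <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  st <- species_table(strsplit(sp_line[2], ",")[[1]],
                      as.numeric(strsplit(sp_line[3], ",")[[1]]))
  seg_lines <- grep("^#seglen\t", lines, value = TRUE)
  slp <- tstrsplit(sub("^#seglen\t", "", seg_lines), "\t", fixed = TRUE)
  seg_lengths <- data.table(species = slp[[1]], segment_id = slp[[2]],
                            length = as.integer(slp[[3]]))
  body <- lines[!startsWith(lines, "#")]
  occ <- if (length(body)) {
    p <- tstrsplit(body, "\t", fixed = TRUE)
    setDT(list(species = p[[1]], key = p[[2]], segment_id = p[[3]],
               pos = as.integer(p[[4]]), gap = as.integer(p[[5]])))
  } else {
    setDT(list(species = character(), key = character(),
               segment_id = character(), pos = integer(), gap = integer()))
  }
  setkey(occ, species, key, segment_id, pos)
  structure(list(occ = occ, k = as.integer(m[2]), gamma = as.integer(m[3]),
                 side_label = m[4], species_table = st,
                 seg_lengths = seg_lengths),
            class = "kmer_index")
}
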