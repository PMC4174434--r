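#' Species table with weight factors
#'
#' The m species under comparison and their weight factors f_i, which must be
#' positive and sum to one. Weights express how much each species contributes
#' to the cross-species conservation weight of a k-mer.
#'
#' @param species_ids character vector of unique species identifiers.
#' @param weights numeric vector of per-species fractions; defaults to the
#'   uniform 1/m.
#' @return an object of class `species_table`: a data.frame with columns
#'   `species` and `weight`.
#' @export
species_table <- function(species_ids, weights = NULL) {
  species_ids <- as.character(species_ids)
  if (anyDuplicated(species_ids))
    stop("species ids must be unique")
  m <- length(species_ids)
  if (m == 0L) stop("at least one species required")
  if (is.null(weights)) weights <- rep(1 / m, m)
  if (length(weights) != m)
    stop("weights and species_ids differ in length")
  if (any(weights <= 0)) stop("every species weight must be > 0")
  if (abs(sum(weights) - 1) > 1e-9)
    stop("species weights must sum to 1 (within 1e-9)")
  structure(data.frame(species = species_ids, weight = weights,
                       stringsAsFactors = FALSE),
            class = c("species_table", "data.frame"))
}

weight_lookup <- function(st) {
  w <- st$weight
  names(w) <- st$species
  w
}

# the species used as coordinate frame: highest weight, ties by table order
reference_species <- function(st) st$species[which.max(st$weight)]

clean_sequence <- function(seq, where = "sequence") {
  seq <- toupper(seq)
  seq <- gsub("U", "T", seq, fixed = TRUE)
  if (!nzchar(seq)) stop("empty ", where)
  if (grepl("[^ACGTN]", seq))
    stop("characters outside {A,C,G,T,N} in ", where)
  seq
}

#' Build a collection of orthologous segments
#'
#' A collection holds the segments s_ij of one side of the search (the left
#' set A or the right set B): per species i, sequences indexed by a segment
#' identifier j that is shared across species for orthologous segments.
#'
#' @param segments data.frame with columns `species`, `segment_id`, `gene_id`,
#'   `sequence` and optionally `strand` ("+" or "-").
#' @param species_tab a [species_table()]; every segment must reference a
#'   species listed in it.
#' @param side_label "A" or "B".
#' @return an object of class `segment_collection`.
#' @export
segment_collection <- function(segments, species_tab, side_label = "A") {
  stopifnot(inherits(species_tab, "species_table"))
  side_label <- match.arg(side_label, c("A", "B"))
  dt <- as.data.table(segments)
  need <- c("species", "segment_id", "gene_id", "sequence")
  if (!all(need %in% names(dt)))
    stop("segments need columns: ", paste(need, collapse = ", "))
  if (!"strand" %in% names(dt)) dt[, strand := "+"]
  dt[, species := as.character(species)]
  dt[, segment_id := as.character(segment_id)]
  dt[, gene_id := as.character(gene_id)]
  dt[, sequence := vapply(sequence, clean_sequence, character(1),
                          USE.NAMES = FALSE)]
  unknown <- setdiff(dt$species, species_tab$species)
  if (length(unknown))
    stop("unknown species id(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(dt[, .(species, segment_id)]))
    stop("duplicate segment: (species, segment_id) must be unique")
  setkey(dt, species, segment_id)
  structure(list(segments = dt, species_table = species_tab,
                 side_label = side_label),
            class = "segment_collection")
}

#' @export
print.segment_collection <- function(x, ...) {
  cat(sprintf("segment_collection (side %s): %d segments, %d species, %d genes\n",
              x$side_label, nrow(x$segments),
              length(unique(x$segments$species)),
              length(unique(x$segments$gene_id))))
  invisible(x)
}

#' Load orthologous segments from a FASTA file
#'
#' FASTA headers follow the `species|gene|segment_id` dialect, so that the
#' same-gene relation can be built without annotation files. U is mapped to T
#' and sequences are upper-cased.
#'
#' @param fasta_path path to a FASTA file.
#' @param species_tab a [species_table()].
#' @param side_label "A" or "B".
#' @return a [segment_collection()].
#' @export
load_segments <- function(fasta_path, species_tab, side_label = "A") {
  if (!file.exists(fasta_path)) stop("no such file: ", fasta_path)
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0L) stop("empty FASTA: ", fasta_path)
  headers <- names(seqs)
  parts <- strsplit(sub("\\s.*$", "", headers), "|", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 3L
  if (any(bad))
    stop("malformed header (expect species|gene|segment_id): ",
         headers[which(bad)[1]])
  segs <- data.frame(
    species = vapply(parts, `[`, character(1), 1L),
    gene_id = vapply(parts, `[`, character(1), 2L),
    segment_id = vapply(parts, `[`, character(1), 3L),
    sequence = as.character(seqs),
    stringsAsFactors = FALSE
  )
  segment_collection(segs, species_tab, side_label)
}

#' Write a collection to FASTA with `species|gene|segment_id` headers
#'
#' @param collection a [segment_collection()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_segments <- function(collection, path) {
  dt <- collection$segments
  x <- Biostrings::DNAStringSet(dt$sequence)
  names(x) <- paste(dt$species, dt$gene_id, dt$segment_id, sep = "|")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Cap a segment to at most M nucleotides
#'
#' Long segments keep only their first M/2 and last M/2 nucleotides; the
#' middle is discarded. This bounds index memory against occasional very long
#' segments.
#'
#' @param sequence DNA string.
#' @param M even integer cap (nt).
#' @return the capped sequence, of length `min(nchar(sequence), M)`.
#' @export
cap_segment <- function(sequence, M) {
  if (length(M) != 1L || is.na(M) || M < 2 || M %% 2 != 0)
    stop("M must be even and >= 2")
  n <- nchar(sequence)
  ifelse(n <= M, sequence,
         paste0(substr(sequence, 1L, M / 2),
                substr(sequence, n - M / 2 + 1L, n)))
}

# apply the cap to every segment of a collection
cap_collection <- function(collection, M) {
  dt <- copy(collection$segments)
  dt[, sequence := cap_segment(sequence, M)]
  collection$segments <- dt
  collection
}

#' Opposite-strand control collection
#'
#' Replaces every sequence by its reverse complement and toggles the strand
#' flag. By construction the control has exactly the same per-segment length,
#' GC content and nucleotide conservation rate as the input, which makes it a
#' matched null for trans-interaction target scans.
#'
#' @param collection a [segment_collection()].
#' @return a [segment_collection()] on the opposite strand.
#' @export
opposite_strand_control <- function(collection) {
  dt <- copy(collection$segments)
  dt[, sequence := revcomp(sequence)]
  dt[, strand := ifelse(strand == "+", "-", "+")]
  collection$segments <- dt
  collection
}

#' Gerstein-Sonnhammer-Chothia species weights from a tree
#'
#' Computes GSC weights on a rooted tree: each leaf starts with its terminal
#' branch length; every internal branch length is then apportioned to the
#' leaves below it proportionally to their accumulated weights. The result is
#' normalized to sum to one. A tree with zero total branch length yields
#' uniform weights.
#'
#' @param tree an [ape::read.tree()] `phylo` object, or a newick string/file.
#' @return a [species_table()] over the leaf labels.
#' @export
compute_species_weights <- function(tree) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
  }
  if (is.null(tree) || !inherits(tree, "phylo")) stop("unparseable tree")
  tips <- tree$tip.label
  if (anyDuplicated(tips)) stop("duplicate leaf names in tree")
  m <- length(tips)
  if (is.null(tree$edge.length) || sum(tree$edge.length) <= 0)
    return(species_table(tips))
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  ntot <- m + tree$Nnode
  # leaves under each node
  kids <- vector("list", ntot)
  for (e in seq_len(nrow(tree$edge))) {
    kids[[tree$edge[e, 1]]] <- c(kids[[tree$edge[e, 1]]], tree$edge[e, 2])
  }
  leaves_below <- function(node) {
    if (node <= m) return(node)
    unlist(lapply(kids[[node]], leaves_below))
  }
  w <- numeric(m)
  # terminal branches first
  edge_to <- tree$edge[, 2]
  for (e in seq_len(nrow(tree$edge)))
    if (edge_to[e] <= m) w[edge_to[e]] <- tree$edge.length[e]
  # internal branches, from shallow clades up: apportion by current weights.
  # Process in order of increasing clade size so that weights below are final.
  internal <- which(edge_to > m)
  clade <- lapply(internal, function(e) leaves_below(edge_to[e]))
  for (idx in order(vapply(clade, length, integer(1)))) {
    e <- internal[idx]
    lv <- clade[[idx]]
    cw <- w[lv]
    share <- if (sum(cw) > 0) cw / sum(cw) else rep(1 / length(lv), length(lv))
    w[lv] <- w[lv] + tree$edge.length[e] * share
  }
  species_table(tips, w / sum(w))
}

#' Build the relation between two segment collections
#'
#' The relation lists which (left segment, right segment) combinations are
#' searched. `same-gene` pairs segments sharing a gene identifier (the
#' intramolecular structure setting); `all-pairs` is the full Cartesian
#' product (the target-scan setting); `from-file` reads a two-column TSV of
#' segment id pairs.
#'
#' @param collectionA,collectionB [segment_collection()]s.
#' @param mode one of "same-gene", "all-pairs", "from-file".
#' @param path TSV path for `from-file` (columns: left_id, right_id).
#' @return an object of class `cc_relation`: a data.table with columns
#'   `left_id`, `right_id`.
#' @export
build_relation <- function(collectionA, collectionB,
                           mode = c("same-gene", "all-pairs", "from-file"),
                           path = NULL) {
  mode <- match.arg(mode)
  la <- unique(collectionA$segments[, .(segment_id, gene_id)])
  lb <- unique(collectionB$segments[, .(segment_id, gene_id)])
  pairs <- switch(mode,
    "same-gene" = {
      merge(la[, .(left_id = segment_id, gene_id)],
            lb[, .(right_id = segment_id, gene_id)],
            by = "gene_id", allow.cartesian = TRUE)[, .(left_id, right_id)]
    },
    "all-pairs" = CJ(left_id = la$segment_id, right_id = lb$segment_id),
    "from-file" = {
      if (is.null(path) || !file.exists(path)) stop("relation file not found")
      tb <- fread(path, header = FALSE, sep = "\t",
                  colClasses = "character")
      if (ncol(tb) < 2) stop("relation file needs two columns")
      setnames(tb[, 1:2], c("left_id", "right_id"))
    }
  )
  pairs <- unique(pairs)
  bad_l <- setdiff(pairs$left_id, la$segment_id)
  bad_r <- setdiff(pairs$right_id, lb$segment_id)
  if (length(bad_l) || length(bad_r))
    stop("relation references unknown segment id(s): ",
         paste(head(c(bad_l, bad_r), 5), collapse = ", "))
  setkey(pairs, left_id, right_id)
  structure(pairs, class = c("cc_relation", class(pairs)))
}

as_relation <- function(pairs) {
  dt <- as.data.table(pairs)
  setnames(dt, 1:2, c("left_id", "right_id"))
  dt[, left_id := as.character(left_id)]
  dt[, right_id := as.character(right_id)]
  setkey(dt, left_id, right_id)
  structure(dt, class = c("cc_relation", class(dt)))
}
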