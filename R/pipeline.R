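#' Run the full conserved-complementarity search
#'
#' Orchestrates index construction, t0-trimming, relation-restricted pairing
#' at t, duplex assembly with the L filter, and scoring. The search path is
#' fully deterministic: identical inputs and configuration yield identical
#' reports.
#'
#' @param collectionA,collectionB [segment_collection()]s (pass the same
#'   object twice for intramolecular search).
#' @param relation a `cc_relation`; defaults to same-gene pairs.
#' @param config a [search_config()].
#' @param score compute significance scores (default TRUE; requires keeping
#'   the untrimmed indexes).
#' @return a list of class `cc_result`: `hits` (`cc_hits`), `duplexes`
#'   (`cc_duplexes`), `config`, and `manifest` (stage counts, input digests
#'   and the config snapshot).
#' @export
run_search <- function(collectionA, collectionB = collectionA,
                       relation = NULL, config = search_config(),
                       score = TRUE) {
  stopifnot(inherits(config, "search_config"))
  if (is.null(relation))
    relation <- build_relation(collectionA, collectionB, "same-gene")
  rel <- as_relation(relation)
  same <- identical(collectionA, collectionB)
  idxA <- build_index(collectionA, config)
  idxB <- if (same) idxA else build_index(collectionB, config)
  n_occ <- nrow(idxA$occ) + if (same) 0L else nrow(idxB$occ)
  trA <- trim_index(idxA, config$t0, config$delta)
  trB <- if (same) trA else trim_index(idxB, config$t0, config$delta)
  n_occ_trimmed <- nrow(trA$occ) + if (same) 0L else nrow(trB$occ)
  hits <- pair_and_trim(trA, trB, rel, config)
  duplexes <- merge_clusters(hits, config)
  if (score && nrow(duplexes) > 0L)
    duplexes <- score_duplexes(duplexes, hits, idxA, idxB, rel, config)
  manifest <- list(
    config = unclass(config),
    n_segments_A = nrow(collectionA$segments),
    n_segments_B = nrow(collectionB$segments),
    n_species = nrow(collectionA$species_table),
    n_relation_pairs = nrow(rel),
    n_keys = length(unique(idxA$occ$key)),
    n_occurrences = n_occ,
    n_occurrences_trimmed = n_occ_trimmed,
    n_hits = nrow(hits),
    n_duplexes = nrow(duplexes),
    n_segment_pairs_with_duplex =
      if (nrow(duplexes)) nrow(unique(as.data.table(duplexes)[, .(left_id, right_id)]))
      else 0L
  )
  structure(list(hits = hits, duplexes = duplexes, config = config,
                 manifest = manifest),
            class = "cc_result")
}

#' @export
print.cc_result <- function(x, ...) {
  m <- x$manifest
  cat("cc_result:\n")
  cat(sprintf("  %d+%d segments, %d species, %d relation pairs\n",
              m$n_segments_A, m$n_segments_B, m$n_species,
              m$n_relation_pairs))
  cat(sprintf("  occurrences %d -> %d after trimming at t0=%g\n",
              m$n_occurrences, m$n_occurrences_trimmed, m$config$t0))
  cat(sprintf("  %d hits, %d duplexes in %d segment pairs (t=%g, L=%d)\n",
              m$n_hits, m$n_duplexes, m$n_segment_pairs_with_duplex,
              m$config$t, m$config$L))
  invisible(x)
}

#' Write a search report to a directory
#'
#' Emits `hits.tsv`, `duplexes.tsv`, `manifest.json` and, when alignments
#' are requested, `alignments.txt`.
#'
#' @param result a `cc_result` from [run_search()].
#' @param dir output directory (created if absent).
#' @param alignments optional list from [naive_alignment()].
#' @return the directory path, invisibly.
#' @export
write_report <- function(result, dir, alignments = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_hits(result$hits, file.path(dir, "hits.tsv"))
  write_duplexes(result$duplexes, file.path(dir, "duplexes.tsv"))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(alignments))
    writeLines(unlist(lapply(alignments, format_alignment)),
               file.path(dir, "alignments.txt"))
  invisible(dir)
}
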