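# Optional harness around external programs (an MSA aligner and RNAplex).
# The package never requires these: every function here degrades to an
# informative error when the executable is absent, and the test suite only
# exercises them when they are found on the PATH.

#' Locate an external executable
#'
#' @param names candidate executable names, tried in order.
#' @return the path of the first executable found, or "" if none.
#' @export
find_executable <- function(names) {
  for (nm in names) {
    p <- Sys.which(nm)
    if (nzchar(p)) return(unname(p))
  }
  ""
}

#' Parse one RNAplex duplex line into base pairs
#'
#' RNAplex reports a duplex as `structure  i,j : k,l (energy)` where the
#' structure is the target part and query part joined by `&`, and i..j / k..l
#' are 1-based inclusive coordinates. The nth `(` of the target part pairs
#' the nth-from-last `)` of the query part.
#'
#' @param line one RNAplex output line.
#' @return a data.table with 0-based columns `left_pos`, `right_pos` and the
#'   `energy`, or NULL if the line is not a duplex line.
#' @export
parse_rnaplex_line <- function(line) {
  m <- regmatches(line, regexec(
    "^([.()&]+)\\s+(\\d+),(\\d+)\\s*:\\s*(\\d+),(\\d+)\\s+\\(\\s*(-?[0-9.]+)\\)",
    line))[[1]]
  if (length(m) != 7) return(NULL)
  parts <- strsplit(m[2], "&", fixed = TRUE)[[1]]
  if (length(parts) != 2) return(NULL)
  tchr <- strsplit(parts[1], "")[[1]]
  qchr <- strsplit(parts[2], "")[[1]]
  ti <- as.integer(m[3]); qi <- as.integer(m[5])
  topen <- ti - 1L + which(tchr == "(") - 1L       # 0-based
  qclose <- qi - 1L + which(qchr == ")") - 1L
  if (length(topen) != length(qclose)) return(NULL)
  data.table(left_pos = topen, right_pos = rev(qclose),
             energy = as.numeric(m[7]))
}

#' Predict duplexes for segment pairs with RNAplex
#'
#' Runs RNAplex on the reference species' sequences of every relation pair
#' and returns the predicted base pairs.
#'
#' @param collection a [segment_collection()].
#' @param relation a `cc_relation` of segment pairs to test.
#' @param ref_species species whose sequences are folded.
#' @param rnaplex path to the RNAplex executable (found automatically by
#'   default).
#' @return a data.table with columns `left_id`, `right_id`, `left_pos`,
#'   `right_pos`, `energy` (one row per predicted base pair, 0-based).
#' @export
run_rnaplex <- function(collection, relation, ref_species,
                        rnaplex = find_executable("RNAplex")) {
  if (!nzchar(rnaplex)) stop("RNAplex executable not found")
  rel <- as_relation(relation)
  segs <- collection$segments[species == ref_species]
  seqs <- segs$sequence; names(seqs) <- segs$segment_id
  miss <- setdiff(unique(c(rel$left_id, rel$right_id)), names(seqs))
  if (length(miss)) stop("segments absent in reference species: ",
                         paste(head(miss, 5), collapse = ", "))
  td <- tempfile("rnaplex"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  tfa <- file.path(td, "t.fa"); qfa <- file.path(td, "q.fa")
  # RNAplex pairs the i-th query with the i-th target when both files have
  # the same number of records? It does all-vs-all per invocation; to keep
  # the pairing explicit, run in batches of one target vs its queries.
  out <- list()
  for (grp in split(seq_len(nrow(rel)), rel$left_id)) {
    lid <- rel$left_id[grp[1]]
    writeLines(c(paste0(">", lid), seqs[lid]), tfa)
    writeLines(unlist(lapply(rel$right_id[grp], function(r)
      c(paste0(">", r), seqs[r]))), qfa)
    res <- suppressWarnings(
      system2(rnaplex, c("-t", tfa, "-q", qfa), stdout = TRUE))
    cur_q <- NA_character_
    for (line in res) {
      if (startsWith(line, ">")) {
        nm <- sub("^>", "", line)
        if (nm != lid) cur_q <- nm
        next
      }
      bp <- parse_rnaplex_line(line)
      if (!is.null(bp) && !is.na(cur_q))
        out[[length(out) + 1L]] <-
          data.table(left_id = lid, right_id = cur_q, bp)
    }
  }
  res <- rbindlist(out)
  if (nrow(res) == 0L)
    res <- data.table(left_id = character(), right_id = character(),
                      left_pos = integer(), right_pos = integer(),
                      energy = numeric())
  res[]
}

#' Tree-simulation benchmark against RNAplex
#'
#' Reproduces the alignable-sequence benchmark: evolve orthologous groups on
#' a balanced binary tree, predict duplexes for all pairwise group
#' combinations with RNAplex on the reference species, post-filter the
#' predictions (consecutive complementarity, wobble cap, cross-species word
#' conservation), and run the internal hash search on the same segments with
#' an all-pairs relation. Reports both pair sets and whether every filtered
#' RNAplex pair was also found internally.
#'
#' @param n_groups,ancestor_length,m,rate,rng_seed forwarded to
#'   [evolve_on_tree()].
#' @param config internal search settings (defaults: k=8, G=1, t=0.75, no
#'   gaps, L=k).
#' @param min_species conservation requirement of the post-filter (default
#'   12 of 16).
#' @return a list: `rnaplex_pairs`, `internal_pairs` (data.tables of
#'   unordered segment pairs), `containment` (logical), `collection`.
#' @export
tree_benchmark <- function(n_groups = 100L, ancestor_length = 150L,
                           m = 16L, rate = 0.03, rng_seed = 1L,
                           config = search_config(k = 8, t0 = 0.75,
                                                  t = 0.75, G = 1, h = 0,
                                                  L = 8, gamma = 0,
                                                  M = 10000),
                           min_species = 12L) {
  sim <- evolve_on_tree(n_groups, ancestor_length, m, rate, rng_seed)
  coll <- sim$collection
  ref <- reference_species(coll$species_table)
  ids <- sort(unique(coll$segments$segment_id))
  # unordered pairwise combinations, as both directions for the search
  cmb <- t(combn(ids, 2))
  rel_unord <- as_relation(data.table(left_id = cmb[, 1],
                                      right_id = cmb[, 2]))
  pred <- run_rnaplex(coll, rel_unord, ref)
  filt <- if (nrow(pred))
    duplex_post_filter(pred, coll, ref, min_run = config$k,
                       max_gt = config$G, min_species = min_species)
  else data.table(left_id = character(), right_id = character())
  rel_all <- build_relation(coll, coll, "all-pairs")
  res <- run_search(coll, coll, rel_all, config, score = FALSE)
  dup <- as.data.table(res$duplexes)
  internal <- if (nrow(dup)) {
    u <- unique(dup[, .(left_id, right_id)])
    unique(u[, .(left_id = pmin(left_id, right_id),
                 right_id = pmax(left_id, right_id))])
  } else data.table(left_id = character(), right_id = character())
  filt_u <- if (nrow(filt))
    unique(filt[, .(left_id = pmin(left_id, right_id),
                    right_id = pmax(left_id, right_id))])
  else filt
  containment <- nrow(filt_u) == 0L ||
    nrow(merge(filt_u, internal, by = c("left_id", "right_id"))) ==
      nrow(filt_u)
  list(rnaplex_pairs = filt_u, internal_pairs = internal,
       containment = containment, collection = coll)
}
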