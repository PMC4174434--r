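#' Search parameters
#'
#' Bundles the tunable thresholds of the conserved-complementarity search.
#'
#' @param k seed length in nt (default 8; feasible range 8-11).
#' @param t0 trimming threshold: minimum summed species weight for a k-mer to
#'   be kept in a segment (fraction, 0-1). Meta-data trimmed at t0 can only be
#'   re-trimmed at a threshold at least as high, hence t >= t0.
#' @param t intersection threshold: minimum summed species weight for a
#'   complementary k-mer pair (fraction, 0-1).
#' @param G maximum number of wobble G.T base pairs allowed per k-mer duplex.
#' @param h minimum number of G-C base pairs required per k-mer duplex.
#' @param L minimum number of complementary nucleotides per cluster (nt).
#' @param gamma maximum central gap size in a gapped seed (nt; 0 disables
#'   gapped seeds).
#' @param delta maximum positional divergence between occurrences in
#'   different species (nt); `Inf` disables positional comparison, the
#'   default, since unaligned sequences cannot be meaningfully compared by
#'   position.
#' @param M maximum segment length (nt, even): longer segments keep only the
#'   first and last M/2 nt.
#' @param unique_flag report only ordered pairs alpha < beta, preventing the
#'   same complementary pair from being reported twice when the left and
#'   right sets intersect.
#' @return an object of class `search_config` (a validated list).
#' @export
search_config <- function(k = 8L, t0 = 0.5, t = 0.8, G = 1L, h = 0L,
                          L = 12L, gamma = 0L, delta = Inf, M = 10000L,
                          unique_flag = TRUE) {
  cfg <- list(k = as.integer(k), t0 = as.numeric(t0), t = as.numeric(t),
              G = as.integer(G), h = as.integer(h), L = as.integer(L),
              gamma = as.integer(gamma), delta = as.numeric(delta),
              M = as.integer(M), unique_flag = isTRUE(unique_flag))
  with(cfg, {
    if (k < 4 || k > 15) stop("k must be in 4..15")
    if (k < 8 || k > 11)
      warning("k outside the feasible 8-11 nt range", call. = FALSE)
    if (t0 < 0 || t0 > 1 || t < 0 || t > 1) stop("t0 and t must be in [0,1]")
    if (t < t0) stop("t must be >= t0 (meta-data trimmed at t0 cannot be re-trimmed lower)")
    if (G < 0 || G > k) stop("G must be in 0..k")
    if (h < 0 || h > k) stop("h must be in 0..k")
    if (L < k) stop("L must be >= k")
    if (gamma < 0) stop("gamma must be >= 0")
    if (!is.infinite(delta) && delta < 0) stop("delta must be >= 0 or Inf")
    if (M %% 2 != 0 || M < 2 * k) stop("M must be even and >= 2k")
  })
  structure(cfg, class = "search_config")
}

#' @export
print.search_config <- function(x, ...) {
  cat("search_config:",
      sprintf("k=%d t0=%g t=%g G=%d h=%d L=%d gamma=%d delta=%s M=%d unique=%s",
              x$k, x$t0, x$t, x$G, x$h, x$L, x$gamma,
              ifelse(is.infinite(x$delta), "Inf", format(x$delta)),
              x$M, x$unique_flag), "\n")
  invisible(x)
}

#' Read a search configuration from a YAML file
#'
#' Field names mirror [search_config()] arguments; absent fields take the
#' defaults.
#'
#' @param path YAML file path.
#' @return a `search_config`.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files")
  vals <- yaml::read_yaml(path)
  known <- names(formals(search_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(search_config, vals)
}
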