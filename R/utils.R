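#' @import data.table
#' @importFrom stats quantile rbinom runif sd qnorm
#' @importFrom utils head tail write.table read.table
NULL

# complement table used everywhere; N maps to N
.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement over the \{A,C,G,T,N\} alphabet.
#'
#' @param x character vector of DNA strings (upper case).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    paste(rev(unname(.COMP[chars])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed so package randomness never leaks into user code
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# random DNA of given lengths, equal nucleotide probabilities
random_dna <- function(lengths) {
  vapply(lengths, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
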