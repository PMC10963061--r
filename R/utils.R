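#' @useDynLib tcrpair, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm runif setNames sd
#' @importFrom utils adist head modifyList
NULL

# The 20 canonical residues in alphabetical order; the package-wide one-hot
# column order (no gap/X symbol: preprocessing rejects non-canonical letters).
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Check that a string is a valid amino-acid sequence
#'
#' @param x character vector.
#' @return logical vector; `TRUE` where every character is one of the 20
#'   canonical residues and the string is non-empty.
#' @examples
#' isAaSeq(c("CASSF", "CAXSF", ""))
#' @export
isAaSeq <- function(x) {
  !is.na(x) & nzchar(x) & !grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), x)
}

# Deterministic 31-bit polynomial string hash (mod 2^31 - 1). Used to derive
# reproducible seeds from sequences/labels without touching the global RNG.
hashString <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (code in utf8ToInt(s)) h <- (h * 131 + code) %% 2147483647
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

# Derive a child seed from (seed, tag); counter-based so stages/folds are
# independently reproducible from one global seed.
deriveSeed <- function(seed, tag) {
  (as.integer(seed) %% 1000003L) * 2011L %% 2147483647L + hashString(as.character(tag)) %% 1000003L
}

# Run code under a local RNG seed without disturbing the caller's RNG stream.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# sample() without the length-1 surprise.
sampleVec <- function(x, size = length(x), replace = FALSE) {
  x[sample.int(length(x), size = size, replace = replace)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
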