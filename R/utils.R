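#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor lm pf quantile rbeta rbinom rexp rgamma rnbinom
#'   rnorm rpois runif sd var p.adjust setNames
#' @importFrom utils combn read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG stream.  seed = NULL leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed from a parent seed and a stream label, so that
## sub-simulations are reproducible but decorrelated.  The label hash is
## order-sensitive (polynomial rolling hash); result kept < 2^31.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- as.double(seed) %% 2147483647
  for (c in utf8ToInt(as.character(stream))) {
    h <- (h * 131 + c) %% 2147483647
  }
  as.integer(h)
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(utf8ToInt(a) != utf8ToInt(b))
}

## Character matrix (n x width) from equal-width strings; fast path for
## mismatch counting.
seq_matrix <- function(x, width = nchar(x[1])) {
  stopifnot(all(nchar(x) == width))
  matrix(utf8ToInt(paste(x, collapse = "")), ncol = width, byrow = TRUE)
}

## Pairwise Hamming distances among equal-width strings via one-hot
## cross-products; returns an integer matrix.
hamming_matrix <- function(x) {
  w <- nchar(x[1])
  m <- seq_matrix(x, w)
  same <- matrix(0, length(x), length(x))
  for (b in unique(as.vector(m))) {
    ind <- (m == b) * 1
    same <- same + tcrossprod(ind)
  }
  w - same
}

## Vectorized mismatch count between two equal-width string vectors.
mismatch_count <- function(a, b) {
  if (!length(a)) return(integer(0))
  w <- nchar(a[1])
  rowSums(seq_matrix(a, w) != seq_matrix(b, w))
}

## Phred+33 helpers ---------------------------------------------------------

phred_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

int_to_phred <- function(q) {
  vapply(q, function(x) intToUtf8(x + 33L), character(1))
}

## Apply substitutions to a sequence: pos/alt are parallel vectors of
## 1-based positions and single-base replacements.
apply_substitutions <- function(seq, pos, alt) {
  if (!length(pos)) return(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  s[pos] <- alt
  paste(s, collapse = "")
}

assert_that <- function(ok, msg) {
  if (!ok) stop(msg, call. = FALSE)
  invisible(TRUE)
}
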