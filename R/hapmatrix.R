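## Haplotype presence/absence matrix container ------------------------------
##
## Integer matrix, samples x (locus, haplotype) columns.  Cell values:
##   1  = haplotype present in the sample
##   0  = haplotype absent (the locus WAS observed in the sample)
##   NA = the locus is missing in the sample (no surviving haplotype); all
##        columns of a missing locus are NA together, never 0.
## The column -> locus map travels in the "column_key" attribute.

new_hap_matrix <- function(m, column_key, extra = list()) {
  stopifnot(is.matrix(m), nrow(column_key) == ncol(m),
            all(column_key$column == colnames(m)))
  structure(m, column_key = column_key, class = c("hap_matrix", "matrix"),
            extra = extra)
}

#' Column metadata of a haplotype matrix
#'
#' @param hm a \code{hap_matrix}.
#' @return data.frame with at least \code{column}, \code{locus} and
#'   \code{hap} columns, one row per matrix column.
#' @export
column_key <- function(hm) attr(hm, "column_key")

#' @export
print.hap_matrix <- function(x, ...) {
  key <- column_key(x)
  cat(sprintf(
    "<hap_matrix> %d samples x %d haplotype columns (%d loci); %.1f%% missing\n",
    nrow(x), ncol(x), length(unique(key$locus)),
    100 * mean(is.na(unclass(x)))))
  invisible(x)
}

## Subset a hap_matrix keeping its key consistent.
hap_subset <- function(hm, samples = NULL, loci = NULL) {
  key <- column_key(hm)
  m <- unclass(hm)
  attr(m, "column_key") <- NULL
  attr(m, "extra") <- NULL
  if (!is.null(samples)) m <- m[samples, , drop = FALSE]
  if (!is.null(loci)) {
    keep <- key$locus %in% loci
    m <- m[, keep, drop = FALSE]
    key <- key[keep, , drop = FALSE]
  }
  new_hap_matrix(m, key)
}

#' Per-sample locus observation matrix
#'
#' Collapses haplotype columns to loci: TRUE where the sample has at least
#' one surviving haplotype at the locus (i.e. the locus is non-missing).
#'
#' @param hm a \code{hap_matrix}.
#' @return logical matrix, samples x loci.
#' @export
locus_observed <- function(hm) {
  key <- column_key(hm)
  loci <- unique(key$locus)
  m <- unclass(hm)
  obs <- matrix(FALSE, nrow(m), length(loci),
                dimnames = list(rownames(m), loci))
  for (i in seq_along(loci)) {
    obs[, i] <- rowSums(!is.na(m[, key$locus == loci[i], drop = FALSE])) > 0
  }
  obs
}

#' Write/read a haplotype matrix as TSV
#'
#' The matrix is stored samples-in-rows with the missing-data code
#' \code{NA}; the column key is stored in a sibling file
#' \code{<path>.key.tsv}.
#'
#' @param hm a \code{hap_matrix}.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
write_hap_matrix <- function(hm, path) {
  m <- as.data.frame(unclass(hm))
  m <- cbind(sample = rownames(hm), m)
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(column_key(hm), paste0(path, ".key.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hap_matrix
#' @export
read_hap_matrix <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  key <- read.delim(paste0(path, ".key.tsv"), stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- d$sample
  new_hap_matrix(m, key)
}
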