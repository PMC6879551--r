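#' Simulate a bacterial reference genome with CDS annotations
#'
#' Generates a multi-scaffold toy genome of i.i.d. uniform nucleotides and a
#' set of non-overlapping protein-coding features tiled along each scaffold
#' on alternating strands.  The genome stands in for a real ~4.5 Mb symbiont
#' assembly at desk scale (default: 200 kb over 8 scaffolds).
#'
#' @param n_scaffolds number of scaffolds.
#' @param scaffold_lengths integer vector (recycled) of scaffold lengths,
#'   each >= 1000.
#' @param cds_fraction target fraction of each scaffold covered by CDS
#'   features, in \[0, 0.95\]. CDS lengths are multiples of 3.
#' @param seed integer seed; the function is a pure function of its inputs
#'   and the seed.
#' @param mean_cds_len mean coding-feature length in bp (rounded to codons).
#' @return An object of class \code{rad_reference}: a list with
#'   \code{$scaffolds} (named character vector of sequences) and
#'   \code{$annotations} (data.frame: scaffold, start, end, strand, gene,
#'   product).
#' @export
make_reference <- function(n_scaffolds = 8, scaffold_lengths = 25000,
                           cds_fraction = 0.6, seed = 1,
                           mean_cds_len = 900) {
  scaffold_lengths <- rep_len(as.integer(scaffold_lengths), n_scaffolds)
  assert_that(all(scaffold_lengths >= 1000), "scaffold lengths must be >= 1000")
  assert_that(cds_fraction >= 0 && cds_fraction <= 0.95,
              "cds_fraction must lie in [0, 0.95]")
  with_seed(seed, {
    ids <- sprintf("scaffold_%d", seq_len(n_scaffolds))
    scaffolds <- setNames(vapply(scaffold_lengths, random_dna, character(1)),
                          ids)
    ann <- list()
    gene_i <- 0L
    for (s in seq_len(n_scaffolds)) {
      if (cds_fraction == 0) next
      len <- scaffold_lengths[s]
      mean_gap <- mean_cds_len * (1 / cds_fraction - 1)
      pos <- max(1L, as.integer(rpois(1, mean_gap / 2)) + 1L)
      strand <- if (runif(1) < 0.5) "+" else "-"
      while (pos + 30L <= len) {
        cds_len <- 3L * max(10L, as.integer(round(rnorm(1, mean_cds_len / 3,
                                                        mean_cds_len / 9))))
        end <- min(pos + cds_len - 1L, len)
        end <- pos + (((end - pos + 1L) %/% 3L) * 3L) - 1L
        if (end - pos + 1L >= 30L) {
          gene_i <- gene_i + 1L
          ann[[length(ann) + 1L]] <- data.frame(
            scaffold = ids[s], start = pos, end = end, strand = strand,
            gene = sprintf("gene_%04d", gene_i),
            product = sprintf("hypothetical protein %04d", gene_i),
            stringsAsFactors = FALSE)
          strand <- if (strand == "+") "-" else "+"
        }
        gap <- as.integer(rexp(1, 1 / max(mean_gap, 1))) + 1L
        pos <- end + gap + 1L
      }
    }
    ann <- if (length(ann)) do.call(rbind, ann) else data.frame(
      scaffold = character(0), start = integer(0), end = integer(0),
      strand = character(0), gene = character(0), product = character(0),
      stringsAsFactors = FALSE)
    ref <- structure(list(scaffolds = scaffolds, annotations = ann),
                     class = "rad_reference")
    validate_reference(ref)
    ref
  })
}

validate_reference <- function(ref) {
  assert_that(!anyDuplicated(names(ref$scaffolds)), "duplicate scaffold ids")
  assert_that(all(nchar(ref$scaffolds) > 0), "empty scaffold sequence")
  a <- ref$annotations
  if (nrow(a)) {
    assert_that(all(a$start <= a$end), "CDS start > end")
    assert_that(all(a$end <= nchar(ref$scaffolds)[a$scaffold]),
                "CDS outside scaffold")
    assert_that(all((a$end - a$start + 1L) %% 3L == 0L),
                "CDS length not a multiple of 3")
  }
  invisible(ref)
}

#' @export
print.rad_reference <- function(x, ...) {
  cat(sprintf("<rad_reference> %d scaffolds, %s bp total, %d CDS features\n",
              length(x$scaffolds),
              format(sum(nchar(x$scaffolds)), big.mark = ","),
              nrow(x$annotations)))
  invisible(x)
}

#' Write a simulated reference as FASTA + GFF3
#'
#' @param ref a \code{rad_reference}.
#' @param fasta,gff output paths.
#' @return invisibly, the two paths.
#' @export
write_reference <- function(ref, fasta, gff) {
  seqs <- Biostrings::DNAStringSet(ref$scaffolds)
  Biostrings::writeXStringSet(seqs, fasta, width = 70)
  a <- ref$annotations
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", names(ref$scaffolds),
                     nchar(ref$scaffolds)))
  if (nrow(a)) {
    lines <- c(lines, sprintf(
      "%s\tsymrad\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;gene=%s;product=%s",
      a$scaffold, a$start, a$end, a$strand, a$gene, a$gene, a$product))
  }
  writeLines(lines, gff)
  invisible(c(fasta = fasta, gff = gff))
}

#' Read a reference genome from FASTA + GFF3
#'
#' Only CDS rows of the GFF3 are retained; \code{gene=} and \code{product=}
#' attributes are parsed when present.
#'
#' @param fasta,gff input paths (\code{gff} may be NULL for an
#'   annotation-free reference).
#' @return a \code{rad_reference}.
#' @export
read_reference <- function(fasta, gff = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  scaffolds <- setNames(as.character(seqs),
                        sub("\\s.*$", "", names(seqs)))
  ann <- data.frame(scaffold = character(0), start = integer(0),
                    end = integer(0), strand = character(0),
                    gene = character(0), product = character(0),
                    stringsAsFactors = FALSE)
  if (!is.null(gff)) {
    ln <- readLines(gff)
    ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
    if (length(ln)) {
      f <- strsplit(ln, "\t", fixed = TRUE)
      f <- f[vapply(f, length, integer(1)) == 9L]
      typ <- vapply(f, `[[`, character(1), 3)
      f <- f[typ == "CDS"]
      if (length(f)) {
        attr_get <- function(a, key) {
          m <- regmatches(a, regexec(paste0("(?:^|;)", key, "=([^;]*)"), a))
          vapply(m, function(z) if (length(z) == 2) z[2] else NA_character_,
                 character(1))
        }
        attrs <- vapply(f, `[[`, character(1), 9)
        ann <- data.frame(
          scaffold = vapply(f, `[[`, character(1), 1),
          start = as.integer(vapply(f, `[[`, character(1), 4)),
          end = as.integer(vapply(f, `[[`, character(1), 5)),
          strand = vapply(f, `[[`, character(1), 7),
          gene = attr_get(attrs, "gene"),
          product = attr_get(attrs, "product"),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(scaffolds = scaffolds, annotations = ann),
            class = "rad_reference")
}
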