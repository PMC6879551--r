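#' Demultiplex inline-barcoded reads
#'
#' Assigns each read to the unique nearest barcode within
#' \code{max_mismatch} mismatches over its first \code{nchar(barcode)}
#' bases (default: one-mismatch rescue, as in process_radtags), strips the
#' barcode from sequence and quality, and routes ambiguous or unmatched
#' reads to an unassigned bin.
#'
#' @param reads data.frame with \code{id}, \code{seq}, \code{qual} (and
#'   optionally \code{comment}) columns.
#' @param sheet sample sheet with \code{sample} and \code{barcode} columns;
#'   a barcode collision rejects the sheet.
#' @param max_mismatch maximum barcode mismatches for rescue (0 = exact
#'   only).
#' @return list with \code{$reads} (assigned reads, barcode stripped, plus
#'   a \code{sample} column), \code{$unassigned}, and \code{$log}
#'   (data.frame of per-sample read counts plus the unassigned count).
#' @export
demultiplex <- function(reads, sheet, max_mismatch = 1) {
  assert_that(!anyDuplicated(sheet$barcode), "barcode collision in sheet")
  bc_len <- nchar(sheet$barcode[1])
  assert_that(all(nchar(sheet$barcode) == bc_len),
              "barcodes must share one length")
  obs <- substr(reads$seq, 1, bc_len)
  hit <- match(obs, sheet$barcode)
  if (max_mismatch > 0 && anyNA(hit)) {
    todo <- which(is.na(hit))
    om <- seq_matrix(obs[todo], bc_len)
    bm <- seq_matrix(sheet$barcode, bc_len)
    mm <- matrix(0L, length(todo), nrow(sheet))
    for (j in seq_len(nrow(sheet))) {
      mm[, j] <- rowSums(om != matrix(bm[j, ], nrow(om), bc_len,
                                      byrow = TRUE))
    }
    best <- apply(mm, 1, min)
    n_best <- rowSums(mm == best)
    ok <- best <= max_mismatch & n_best == 1
    hit[todo[ok]] <- apply(mm[ok, , drop = FALSE], 1, which.min)
  }
  assigned <- !is.na(hit)
  out <- reads[assigned, , drop = FALSE]
  out$sample <- sheet$sample[hit[assigned]]
  out$seq <- substring(out$seq, bc_len + 1L)
  out$qual <- substring(out$qual, bc_len + 1L)
  counts <- table(factor(out$sample, levels = sheet$sample))
  log <- data.frame(sample = c(sheet$sample, "(unassigned)"),
                    n_reads = c(as.integer(counts), sum(!assigned)),
                    stringsAsFactors = FALSE)
  list(reads = out, unassigned = reads[!assigned, , drop = FALSE],
       log = log)
}

#' Sliding-window quality filter
#'
#' Drops a read when any sliding window (of \code{window_fraction} of the
#' read length) has mean Phred quality below \code{q_threshold} --
#' process_radtags-style behaviour.  \code{rule = "min_q"} instead keeps
#' only reads whose every base is at least \code{q_threshold} (the literal
#' "Phred >= 33" reading, for comparison).
#'
#' @param reads read data.frame (equal-length reads).
#' @param window_fraction sliding-window size as a fraction of read length.
#' @param q_threshold mean-quality threshold (default 20).
#' @param rule "window_mean" (default) or "min_q".
#' @return list with \code{$reads} (retained) and \code{$retained_fraction}.
#' @export
quality_filter <- function(reads, window_fraction = 0.15, q_threshold = 20,
                           rule = c("window_mean", "min_q")) {
  rule <- match.arg(rule)
  if (!nrow(reads)) return(list(reads = reads, retained_fraction = NaN))
  len <- nchar(reads$qual[1])
  assert_that(all(nchar(reads$qual) == len),
              "quality_filter expects equal-length reads")
  q <- seq_matrix(reads$qual, len) - 33L
  keep <- if (q_threshold <= 0) {
    rep(TRUE, nrow(reads))
  } else if (rule == "min_q") {
    apply(q >= q_threshold, 1, all)
  } else {
    w <- max(1L, as.integer(floor(window_fraction * len)))
    cs <- cbind(0L, t(apply(q, 1, cumsum)))
    ok <- rep(TRUE, nrow(reads))
    for (s in seq_len(len - w + 1L)) {
      ok <- ok & (cs[, s + w] - cs[, s]) / w >= q_threshold
    }
    ok
  }
  list(reads = reads[keep, , drop = FALSE],
       retained_fraction = mean(keep))
}

#' Seed-and-extend ungapped read alignment
#'
#' A deliberately simple behavioural stand-in for a short-read aligner:
#' candidate placements are found by exact matching of two read seeds (the
#' first and last \code{seed_length} bases) on both strands, extended
#' ungapped, and scored by mismatch count.  The uniqueness score is a
#' monotone MAPQ surrogate: 60 for a unique best hit whose runner-up is
#' worse by >= 2 mismatches, 3 for a tie, and linear in the margin between;
#' the only downstream contract is the "> 20" cut separating unique from
#' ambiguous placements.
#'
#' @param reads read data.frame (post-demultiplex, equal length).
#' @param reference a \code{rad_reference} or named character vector.
#' @param max_mismatches maximum mismatches for a reported placement.
#' @param seed_length exact-match seed length.
#' @return data.frame: \code{id}, \code{scaffold}, \code{pos} (1-based
#'   leftmost on the forward strand), \code{strand}, \code{mismatches},
#'   \code{uniqueness}; unaligned reads are absent from the table.
#' @export
align_reads <- function(reads, reference, max_mismatches = 4,
                        seed_length = 20) {
  scaffolds <- if (inherits(reference, "rad_reference"))
    reference$scaffolds else reference
  assert_that(length(scaffolds) > 0 && sum(nchar(scaffolds)) > 0,
              "empty reference")
  if (!nrow(reads)) {
    return(data.frame(id = character(0), scaffold = character(0),
                      pos = integer(0), strand = character(0),
                      mismatches = integer(0), uniqueness = numeric(0),
                      stringsAsFactors = FALSE))
  }
  len <- nchar(reads$seq[1])
  assert_that(all(nchar(reads$seq) == len),
              "align_reads expects equal-length reads")
  assert_that(seed_length <= len, "seed longer than read")
  fwd <- reads$seq
  rev <- revcomp(fwd)
  ## three tiled seeds (start / middle / end): a read is only invisible to
  ## the candidate search when every seed region carries a mismatch
  offs <- unique(c(1L, (len - seed_length) %/% 2L + 1L,
                   len - seed_length + 1L))

  cand <- list()  # per (strand, offset, scaffold) candidate tables
  for (strand in c("+", "-")) {
    rseq <- if (strand == "+") fwd else rev
    for (off in offs) {
      seeds <- substr(rseq, off, off + seed_length - 1L)
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
      for (sc in names(scaffolds)) {
        m <- Biostrings::matchPDict(pd, Biostrings::DNAString(scaffolds[[sc]]))
        st <- Biostrings::startIndex(m)
        nhit <- lengths(st)
        if (!sum(nhit)) next
        ridx <- rep(seq_along(nhit), nhit)
        pos <- unlist(st) - (off - 1L)
        ok <- pos >= 1L & pos + len - 1L <= nchar(scaffolds[[sc]])
        if (!any(ok)) next
        cand[[length(cand) + 1L]] <- data.frame(
          read = ridx[ok], scaffold = sc, pos = pos[ok], strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(id = character(0), scaffold = character(0),
                      pos = integer(0), strand = character(0),
                      mismatches = integer(0), uniqueness = numeric(0),
                      stringsAsFactors = FALSE))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[!duplicated(cand[c("read", "scaffold", "pos", "strand")]), ,
               drop = FALSE]
  refsub <- substring(scaffolds[cand$scaffold], cand$pos,
                      cand$pos + len - 1L)
  qry <- ifelse(cand$strand == "+", fwd[cand$read], rev[cand$read])
  cand$mismatches <- mismatch_count(qry, refsub)
  cand <- cand[cand$mismatches <= max_mismatches, , drop = FALSE]
  if (!nrow(cand)) {
    return(data.frame(id = character(0), scaffold = character(0),
                      pos = integer(0), strand = character(0),
                      mismatches = integer(0), uniqueness = numeric(0),
                      stringsAsFactors = FALSE))
  }
  o <- order(cand$read, cand$mismatches)
  cand <- cand[o, , drop = FALSE]
  first <- !duplicated(cand$read)
  best <- cand[first, , drop = FALSE]
  ## runner-up mismatch count per read (Inf when none)
  second_idx <- which(first) + 1L
  has_second <- second_idx <= nrow(cand) &
    cand$read[pmin(second_idx, nrow(cand))] == best$read
  margin <- rep(Inf, nrow(best))
  margin[has_second] <- cand$mismatches[second_idx[has_second]] -
    best$mismatches[has_second]
  uniq <- ifelse(margin >= 2, 60, 3 + 28.5 * pmax(margin, 0))
  data.frame(id = reads$id[best$read], scaffold = best$scaffold,
             pos = best$pos, strand = best$strand,
             mismatches = best$mismatches, uniqueness = uniq,
             stringsAsFactors = FALSE)
}

#' Partition reads into symbiont / contaminant / host bins
#'
#' Reads are first aligned to the symbiont reference: confident hits
#' (uniqueness > \code{min_uniqueness}, the MAPQ-like cut) form the
#' symbiont bin.  The remainder are screened against any decoy genomes
#' (contaminant bin) and everything left is classified as host.  Reads
#' that aligned to the symbiont but failed the uniqueness cut are
#' low-uniqueness leakage: by default they fall through to the
#' decoy/host route (and are counted in the log);
#' \code{ambiguous_to = "unassigned"} drops them instead.
#'
#' @param reads post-demultiplex read data.frame (with \code{sample}).
#' @param symbiont_ref symbiont reference.
#' @param decoy_refs list (possibly empty) of decoy references.
#' @param min_uniqueness uniqueness cut for the symbiont bin (default 20).
#' @param max_mismatches,seed_length passed to [align_reads()].
#' @param ambiguous_to where uniqueness-filtered symbiont hits go:
#'   "host" route (default) or "unassigned".
#' @return list with \code{$symbiont}, \code{$contaminant}, \code{$host},
#'   \code{$unassigned} read data.frames (symbiont rows carry alignment
#'   columns), and \code{$log}.
#' @export
partition_reads <- function(reads, symbiont_ref, decoy_refs = list(),
                            min_uniqueness = 20, max_mismatches = 4,
                            seed_length = 20,
                            ambiguous_to = c("host", "unassigned")) {
  ambiguous_to <- match.arg(ambiguous_to)
  aln <- align_reads(reads, symbiont_ref, max_mismatches, seed_length)
  conf <- aln[aln$uniqueness > min_uniqueness, , drop = FALSE]
  sym_idx <- match(conf$id, reads$id)
  symbiont <- cbind(reads[sym_idx, , drop = FALSE],
                    conf[c("scaffold", "pos", "strand", "mismatches",
                           "uniqueness")])
  lowuniq_ids <- setdiff(aln$id, conf$id)
  rest <- reads[!(reads$id %in% conf$id), , drop = FALSE]
  unassigned <- rest[0, , drop = FALSE]
  if (ambiguous_to == "unassigned" && length(lowuniq_ids)) {
    unassigned <- rest[rest$id %in% lowuniq_ids, , drop = FALSE]
    rest <- rest[!(rest$id %in% lowuniq_ids), , drop = FALSE]
  }
  contam <- rest[0, , drop = FALSE]
  for (decoy in decoy_refs) {
    if (!nrow(rest)) break
    da <- align_reads(rest, decoy, max_mismatches, seed_length)
    hit <- rest$id %in% da$id
    contam <- rbind(contam, rest[hit, , drop = FALSE])
    rest <- rest[!hit, , drop = FALSE]
  }
  log <- data.frame(
    bin = c("symbiont", "contaminant", "host", "unassigned",
            "low_uniqueness_leakage"),
    n_reads = c(nrow(symbiont), nrow(contam), nrow(rest), nrow(unassigned),
                length(lowuniq_ids)), stringsAsFactors = FALSE)
  list(symbiont = symbiont, contaminant = contam, host = rest,
       unassigned = unassigned, log = log)
}

#' Per-sample read and stack-depth summary
#'
#' Stacks are groups of identical reads sharing an alignment anchor
#' (scaffold, leftmost position, strand) within a sample; mean stack depth
#' is reads per stack.
#'
#' @param symbiont_bin symbiont bin from [partition_reads()] (reads with
#'   alignment columns and \code{sample}).
#' @return data.frame: sample, n_reads, mean_stack_depth.
#' @export
read_stats <- function(symbiont_bin) {
  if (!nrow(symbiont_bin)) {
    return(data.frame(sample = character(0), n_reads = integer(0),
                      mean_stack_depth = numeric(0)))
  }
  key <- paste(symbiont_bin$sample, symbiont_bin$scaffold,
               symbiont_bin$pos, symbiont_bin$strand, symbiont_bin$seq)
  st <- table(key)
  sample_of <- sub(" .*$", "", names(st))
  n_reads <- tapply(as.integer(st), sample_of, sum)
  depth <- tapply(as.integer(st), sample_of, mean)
  data.frame(sample = names(n_reads), n_reads = as.integer(n_reads),
             mean_stack_depth = as.numeric(depth), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Per-sample QC gate on read totals and stack depth
#'
#' Mirrors the library-evenness screen: samples with fewer than
#' \code{min_reads} total reads or mean stack depth below
#' \code{min_mean_depth} are discarded from all downstream datasets.  The
#' survey-scale defaults (100,000 reads, 100x) apply at \code{scale = 1};
#' \code{scale} multiplies both thresholds for desk-scale simulations.
#'
#' @param stats per-sample stats data.frame from [read_stats()] (columns
#'   sample, n_reads, mean_stack_depth).
#' @param min_reads,min_mean_depth QC thresholds.
#' @param scale multiplier applied to both thresholds.
#' @return data.frame: sample, n_reads, mean_stack_depth, pass.  Halts if
#'   every sample fails.
#' @export
sample_qc <- function(stats, min_reads = 100000, min_mean_depth = 100,
                      scale = 1) {
  stats$pass <- stats$n_reads >= min_reads * scale &
    stats$mean_stack_depth >= min_mean_depth * scale
  assert_that(any(stats$pass),
              "all samples fail QC; lower the thresholds or qc scale")
  stats
}

#' Write alignments as a minimal SAM file
#'
#' QNAME/FLAG/RNAME/POS/MAPQ/CIGAR/SEQ/QUAL only; ungapped CIGAR
#' (\code{<len>M}); reverse-strand reads emitted reverse-complemented with
#' FLAG 16, per convention.
#'
#' @param symbiont_bin aligned reads (as from [partition_reads()]).
#' @param reference the reference aligned against (for @SQ headers).
#' @param path output SAM path.
#' @return invisibly, \code{path}.
#' @export
write_sam <- function(symbiont_bin, reference, path) {
  scaffolds <- if (inherits(reference, "rad_reference"))
    reference$scaffolds else reference
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(scaffolds), nchar(scaffolds)))
  b <- symbiont_bin
  flag <- ifelse(b$strand == "-", 16L, 0L)
  seq_out <- ifelse(b$strand == "-", revcomp(b$seq), b$seq)
  qual_out <- ifelse(b$strand == "-",
                     vapply(strsplit(b$qual, ""), function(x)
                       paste(rev(x), collapse = ""), character(1)),
                     b$qual)
  rows <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                  b$id, flag, b$scaffold, b$pos,
                  as.integer(round(b$uniqueness)), nchar(b$seq),
                  seq_out, qual_out)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_sam
#' @export
read_sam <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  f <- strsplit(ln, "\t", fixed = TRUE)
  strand <- ifelse(bitwAnd(as.integer(vapply(f, `[[`, character(1), 2)),
                           16L) > 0L, "-", "+")
  seq <- vapply(f, `[[`, character(1), 10)
  qual <- vapply(f, `[[`, character(1), 11)
  seq[strand == "-"] <- revcomp(seq[strand == "-"])
  qual[strand == "-"] <- vapply(strsplit(qual[strand == "-"], ""),
                                function(x) paste(rev(x), collapse = ""),
                                character(1))
  data.frame(id = vapply(f, `[[`, character(1), 1),
             scaffold = vapply(f, `[[`, character(1), 3),
             pos = as.integer(vapply(f, `[[`, character(1), 4)),
             strand = strand,
             uniqueness = as.numeric(vapply(f, `[[`, character(1), 5)),
             seq = seq, qual = qual, stringsAsFactors = FALSE)
}
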