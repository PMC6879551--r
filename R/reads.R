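#' Emit barcoded single-end reads from fragment templates
#'
#' Reads start at the EcoRI end of each retained fragment (templates are
#' supplied already in read orientation), carry the sample's 10-bp inline
#' barcode as the first cycles, and receive uniform random substitution
#' errors.  Per-template depth is negative binomial with mean \code{mu} and
#' dispersion \code{size}: over-dispersed coverage that exercises downstream
#' depth filters.
#'
#' @param templates data.frame with columns \code{frag_id}, \code{hap}
#'   (template haplotype label), \code{seq} (read-orientation template,
#'   at most \code{read_len - nchar(barcode)} bp; shorter templates yield
#'   truncated reads flagged in the truth tag).
#' @param mu numeric vector (recycled) of expected depths per template row.
#' @param size negative-binomial dispersion (smaller = more over-dispersed).
#' @param error_rate per-base substitution error probability in \[0, 0.02\].
#' @param barcode the sample's inline barcode.
#' @param read_len total read length including barcode (default 100).
#' @param q constant Phred quality emitted for every base (default 37).
#' @param sample sample id written into the truth tag.
#' @param origin origin label ("symbiont"/"host") for the truth tag.
#' @param seed integer seed.
#' @return data.frame with columns \code{id}, \code{comment} (truth tag),
#'   \code{seq}, \code{qual}; one row per read.
#' @export
generate_reads <- function(templates, mu, size = 5, error_rate = 0,
                           barcode, read_len = 100, q = 37,
                           sample = "s1", origin = "symbiont", seed = NULL) {
  assert_that(error_rate >= 0 && error_rate <= 0.02,
              "error_rate must be in [0, 0.02]")
  tpl_len <- read_len - nchar(barcode)
  assert_that(all(nchar(templates$seq) <= tpl_len),
              "template longer than read payload")
  with_seed(seed, {
    mu <- rep_len(mu, nrow(templates))
    depth <- rnbinom(nrow(templates), size = size, mu = mu)
    idx <- rep(seq_len(nrow(templates)), depth)
    if (!length(idx)) {
      return(data.frame(id = character(0), comment = character(0),
                        seq = character(0), qual = character(0),
                        stringsAsFactors = FALSE))
    }
    seqs <- paste0(barcode, templates$seq[idx])
    trunc <- nchar(templates$seq[idx]) < tpl_len
    lens <- nchar(seqs)
    ## substitution errors over the full read (barcode included)
    if (error_rate > 0) {
      n_err <- rbinom(length(seqs), lens, error_rate)
      hit <- which(n_err > 0)
      for (i in hit) {
        pos <- sample.int(lens[i], n_err[i])
        old <- strsplit(substring(seqs[i], 1, lens[i]), "")[[1]][pos]
        alt <- vapply(old, function(b) sample(setdiff(DNA_BASES, b), 1),
                      character(1))
        seqs[i] <- apply_substitutions(seqs[i], pos, alt)
      }
    }
    quals <- strrep(intToUtf8(q + 33L), lens)
    data.frame(
      id = sprintf("%s_r%06d", sample, seq_along(idx)),
      comment = sprintf("org=%s sample=%s hap=%s frag=%s trunc=%d",
                        origin, sample, templates$hap[idx],
                        templates$frag_id[idx], as.integer(trunc)),
      seq = seqs, qual = quals, stringsAsFactors = FALSE)
  })
}

## Read-orientation symbiont templates: one row per (fragment, strain).
build_symbiont_templates <- function(ref, pools, frags, template_len = 90,
                                     strains = pools$strains$strain) {
  win <- fragment_template_window(frags, template_len)
  ref_tpl <- template_sequences(ref, win)
  v <- pools$variants
  out <- vector("list", nrow(win) * length(strains))
  k <- 0L
  for (j in seq_len(nrow(win))) {
    ids_w <- variants_in_window(pools, win$scaffold[j], win$start[j],
                                win$end[j])
    wlen <- win$end[j] - win$start[j] + 1L
    for (s in strains) {
      k <- k + 1L
      mine <- intersect(pools$strain_variants[[s]], ids_w)
      seq <- ref_tpl[j]
      if (length(mine)) {
        pos_fwd <- v$pos[mine] - win$start[j] + 1L
        alt <- v$alt[mine]
        if (win$rc[j]) {
          pos_rd <- wlen - pos_fwd + 1L
          alt <- unname(chartr("ACGT", "TGCA", alt))
        } else pos_rd <- pos_fwd
        seq <- apply_substitutions(seq, pos_rd, alt)
      }
      out[[k]] <- data.frame(frag_id = win$frag_id[j], hap = s, seq = seq,
                             truncated = win$truncated[j],
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write reads as a 4-line-record FASTQ (Phred+33)
#'
#' Truth tags travel in the header comment field, where standard parsers
#' ignore them.
#'
#' @param reads data.frame from [generate_reads()] (columns id, comment,
#'   seq, qual).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_fastq <- function(reads, path) {
  hdr <- if (is.null(reads$comment)) reads$id else
    ifelse(nzchar(reads$comment), paste(reads$id, reads$comment), reads$id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", hdr, "\n", reads$seq, "\n+\n", reads$qual), con)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  hdr <- names(x)
  id <- sub("\\s.*$", "", hdr)
  comment <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  data.frame(id = id, comment = comment, seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

## Parse truth tags ("key=value" space-separated comments) into a df.
parse_truth_tags <- function(comment) {
  kv <- strsplit(comment, " ", fixed = TRUE)
  keys <- unique(unlist(lapply(kv, function(x) sub("=.*$", "", x))))
  out <- lapply(keys, function(k) {
    vapply(kv, function(x) {
      hit <- startsWith(x, paste0(k, "="))
      if (any(hit)) sub("^[^=]+=", "", x[hit][1]) else NA_character_
    }, character(1))
  })
  names(out) <- keys
  as.data.frame(out, stringsAsFactors = FALSE)
}
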