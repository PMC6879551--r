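#' In-silico double digest with size selection
#'
#' Cuts each scaffold at every forward-strand occurrence of the two
#' restriction sites and retains fragments that carry one EcoRI-type end and
#' one MseI-type end and whose length falls inside the size-selection
#' window.  Defaults model an EcoRI (G^AATTC) x MseI (T^TAA) double digest.
#'
#' Recognition sites containing characters other than A/C/G/T (e.g. N
#' spacers) never match, so N runs act as uncuttable separators.
#'
#' @param genome a \code{rad_reference}, or a named character vector of
#'   scaffold sequences.
#' @param enzyme_a_site,enzyme_b_site recognition sequences (exact match,
#'   forward strand).
#' @param cut_a,cut_b number of site bases left on the upstream fragment
#'   (EcoRI G^AATTC: 1; MseI T^TAA: 1).
#' @param size_window length-2 numeric: retained fragment length range
#'   (inclusive).
#' @return data.frame with one row per retained fragment: \code{frag_id},
#'   \code{scaffold}, \code{start}, \code{end}, \code{length},
#'   \code{ecori_end} ("left"/"right": which fragment end was cut by enzyme
#'   A).
#' @export
digest_and_select <- function(genome, enzyme_a_site = "GAATTC",
                              enzyme_b_site = "TTAA", cut_a = 1L,
                              cut_b = 1L, size_window = c(150, 450)) {
  scaffolds <- if (inherits(genome, "rad_reference")) genome$scaffolds
               else genome
  if (is.null(names(scaffolds)))
    names(scaffolds) <- sprintf("scaffold_%d", seq_along(scaffolds))
  assert_that(all(nchar(scaffolds) > 0), "zero-length scaffold")
  out <- list()
  for (sc in names(scaffolds)) {
    seq <- scaffolds[[sc]]
    subj <- Biostrings::DNAString(seq)
    pos_a <- Biostrings::start(Biostrings::matchPattern(enzyme_a_site, subj))
    pos_b <- Biostrings::start(Biostrings::matchPattern(enzyme_b_site, subj))
    ## cut coordinate = last base of the upstream fragment
    cuts <- data.frame(cut = c(pos_a + cut_a - 1L, pos_b + cut_b - 1L),
                       enz = rep(c("A", "B"), c(length(pos_a), length(pos_b))))
    if (nrow(cuts) < 2) next
    cuts <- cuts[order(cuts$cut), , drop = FALSE]
    ## overlapping site hits at the same cut coordinate: keep first
    cuts <- cuts[!duplicated(cuts$cut), , drop = FALSE]
    n <- nrow(cuts)
    start <- cuts$cut[-n] + 1L
    end <- cuts$cut[-1]
    left_enz <- cuts$enz[-n]
    right_enz <- cuts$enz[-1]
    len <- end - start + 1L
    keep <- left_enz != right_enz & len >= size_window[1] &
      len <= size_window[2] & len > 0
    if (!any(keep)) next
    out[[sc]] <- data.frame(
      scaffold = sc, start = start[keep], end = end[keep],
      length = len[keep],
      ecori_end = ifelse(left_enz[keep] == "A", "left", "right"),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    warning("digest produced no retained fragments")
    return(data.frame(frag_id = character(0), scaffold = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), ecori_end = character(0),
                      stringsAsFactors = FALSE))
  }
  frags <- do.call(rbind, out)
  rownames(frags) <- NULL
  frags <- cbind(frag_id = sprintf("frag_%04d", seq_len(nrow(frags))), frags,
                 stringsAsFactors = FALSE)
  frags
}

## Read-template region of a fragment: `template_len` bases starting at the
## EcoRI end, expressed on the forward reference strand.  Returns start/end
## of the window plus whether the template must be reverse-complemented to
## be in read orientation.
fragment_template_window <- function(frags, template_len) {
  w_start <- ifelse(frags$ecori_end == "left", frags$start,
                    pmax(frags$start, frags$end - template_len + 1L))
  w_end <- ifelse(frags$ecori_end == "left",
                  pmin(frags$end, frags$start + template_len - 1L),
                  frags$end)
  data.frame(frag_id = frags$frag_id, scaffold = frags$scaffold,
             start = as.integer(w_start), end = as.integer(w_end),
             rc = frags$ecori_end == "right",
             truncated = (w_end - w_start + 1L) < template_len,
             stringsAsFactors = FALSE)
}
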