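#' Generate inline barcodes with a minimum pairwise Hamming distance
#'
#' Greedy random search for \code{n} distinct 10-bp barcodes that are
#' mutually at least \code{min_dist} mismatches apart, so that single-error
#' rescue during demultiplexing is unambiguous.
#'
#' @param n number of barcodes.
#' @param length barcode length (bp).
#' @param min_dist minimum pairwise Hamming distance.
#' @param seed integer seed.
#' @return character vector of barcodes.
#' @export
make_barcodes <- function(n, length = 10L, min_dist = 3L, seed = 1) {
  with_seed(seed, {
    out <- character(0)
    tries <- 0L
    while (length(out) < n) {
      cand <- random_dna(length)
      tries <- tries + 1L
      assert_that(tries < 200000L, "barcode search failed; relax min_dist")
      if (!length(out) ||
          all(vapply(out, hamming, integer(1), b = cand) >= min_dist)) {
        out <- c(out, cand)
      }
    }
    out
  })
}

#' Build a sample sheet for a simulated collection design
#'
#' One row per light organ library: sample id, 10-bp barcode, sampling
#' location, year, and fish standard length (mm; a proxy for age, drawn
#' from a truncated normal).
#'
#' @param design data.frame with columns \code{location}, \code{year},
#'   \code{n} (samples per location x year cell).
#' @param seed integer seed.
#' @param length_mean,length_sd standard-length distribution (mm).
#' @return data.frame: sample, barcode, location, year, length_mm.
#' @export
design_sheet <- function(design, seed = 1, length_mean = 45,
                         length_sd = 8) {
  n_tot <- sum(design$n)
  bc <- make_barcodes(n_tot, seed = child_seed(seed, "barcodes"))
  with_seed(child_seed(seed, "lengths"), {
    len <- pmax(20, rnorm(n_tot, length_mean, length_sd))
    loc <- rep(design$location, design$n)
    yr <- rep(design$year, design$n)
    data.frame(
      sample = sprintf("%s%d_%02d", loc, yr,
                       unlist(lapply(design$n, seq_len))),
      barcode = bc, location = loc, year = as.integer(yr),
      length_mm = round(len, 1), stringsAsFactors = FALSE)
  })
}

#' The default 282-organ, 11-location, 3-year collection design
#'
#' Location x year sample sizes for a regional survey: ten Okinawa Island
#' sites sampled in 2013, four sites (one on Kume Island, 140 km west) in
#' 2014, and one site (Sesoko, "S") sampled in three consecutive years.
#' Kume ("K") forms its own island group; all other sites share one group.
#'
#' @return data.frame: location, year, n, group.
#' @export
siphamia_design <- function() {
  d <- data.frame(
    location = c("S", "S", "S", "M", "N", "Hd", "It", "It", "O", "Y",
                 "Ik", "Ik", "Hk", "A", "K"),
    year = c(2012L, 2013L, 2014L, 2013L, 2013L, 2013L, 2013L, 2014L,
             2013L, 2013L, 2013L, 2014L, 2013L, 2013L, 2014L),
    n = c(16L, 18L, 21L, 20L, 21L, 17L, 14L, 27L, 16L, 16L, 15L, 22L,
          17L, 16L, 26L),
    stringsAsFactors = FALSE)
  d$group <- ifelse(d$location == "K", "group_2", "group_1")
  d
}

#' A small structured two-island design for power simulations
#'
#' Four sites, two per island group, sampled in one year.
#'
#' @param n_per_site samples per site.
#' @param year sampling year label.
#' @return data.frame: location, year, n, group.
#' @export
structured_design <- function(n_per_site = 20, year = 2014L) {
  data.frame(location = c("S", "It", "K", "Km2"),
             year = as.integer(year), n = as.integer(n_per_site),
             group = c("group_1", "group_1", "group_2", "group_2"),
             stringsAsFactors = FALSE)
}

#' Write/read the sample sheet TSV
#'
#' @param sheet sample sheet data.frame.
#' @param path TSV path.
#' @return invisibly \code{path} (write) or the sheet (read).
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  sheet <- read.delim(path, stringsAsFactors = FALSE)
  assert_that(all(c("sample", "barcode", "location", "year") %in%
                    names(sheet)), "sample sheet missing required columns")
  assert_that(!anyDuplicated(sheet$barcode), "barcode collision in sheet")
  sheet
}
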