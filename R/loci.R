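## Locus catalogs -----------------------------------------------------------
##
## A rad_catalog holds RAD loci plus per-sample haplotype calls:
##   $loci  : data.frame(locus, scaffold, start, strand)   [reference-guided]
##            or data.frame(locus, consensus)              [de novo]
##   $calls : data.frame(locus, sample, hap_seq, depth)

new_rad_catalog <- function(loci, calls, kind) {
  structure(list(loci = loci, calls = calls, kind = kind),
            class = "rad_catalog")
}

#' @export
print.rad_catalog <- function(x, ...) {
  cat(sprintf("<rad_catalog:%s> %d loci, %d haplotype calls in %d samples\n",
              x$kind, nrow(x$loci), nrow(x$calls),
              length(unique(x$calls$sample))))
  invisible(x)
}

#' Build a reference-guided locus catalog from aligned reads
#'
#' Reads are grouped into loci by their alignment anchor (scaffold,
#' leftmost position, strand).  Within each sample, identical read
#' sequences form stacks; stacks below \code{min_stack_depth} are
#' discarded and the survivors are the sample's haplotypes at the locus.
#' Reads whose length differs from the locus's modal template length
#' (truncated fragments) are dropped and counted.
#'
#' @param symbiont_bin aligned reads: data.frame with \code{sample},
#'   \code{scaffold}, \code{pos}, \code{strand}, \code{seq}.
#' @param min_stack_depth minimum reads per stack (default 3).
#' @return a \code{rad_catalog} (kind "reference").
#' @export
build_reference_catalog <- function(symbiont_bin, min_stack_depth = 3) {
  b <- symbiont_bin
  if (!nrow(b)) {
    return(new_rad_catalog(
      data.frame(locus = character(0), scaffold = character(0),
                 start = integer(0), strand = character(0)),
      data.frame(locus = character(0), sample = character(0),
                 hap_seq = character(0), depth = integer(0)),
      "reference"))
  }
  anchor <- paste(b$scaffold, b$pos, b$strand)
  ## modal read length per anchor; drop non-modal (truncated) reads
  len <- nchar(b$seq)
  modal <- vapply(split(len, anchor), function(x) {
    tx <- table(x); as.integer(names(tx)[which.max(tx)])
  }, integer(1))
  keep <- len == modal[anchor]
  n_dropped <- sum(!keep)
  if (n_dropped) message(n_dropped,
                         " read(s) dropped for non-modal template length")
  b <- b[keep, , drop = FALSE]
  anchor <- anchor[keep]

  stacks <- as.data.frame(table(anchor = anchor, sample = b$sample,
                                hap_seq = b$seq),
                          stringsAsFactors = FALSE)
  stacks <- stacks[stacks$Freq >= min_stack_depth, , drop = FALSE]
  uanch <- unique(anchor)
  parts <- strsplit(uanch, " ", fixed = TRUE)
  loci <- data.frame(
    scaffold = vapply(parts, `[[`, character(1), 1),
    start = as.integer(vapply(parts, `[[`, character(1), 2)),
    strand = vapply(parts, `[[`, character(1), 3),
    anchor = uanch, stringsAsFactors = FALSE)
  loci <- loci[order(loci$scaffold, loci$start, loci$strand), , drop = FALSE]
  loci$locus <- sprintf("L%04d", seq_len(nrow(loci)))
  calls <- data.frame(locus = loci$locus[match(stacks$anchor, loci$anchor)],
                      sample = stacks$sample, hap_seq = stacks$hap_seq,
                      depth = as.integer(stacks$Freq),
                      stringsAsFactors = FALSE)
  calls <- calls[order(calls$locus, calls$sample, calls$hap_seq), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  new_rad_catalog(loci[c("locus", "scaffold", "start", "strand")], calls,
                  "reference")
}

#' Haplotype presence/absence matrix from a catalog
#'
#' Within each locus, haplotypes reaching \code{min_hap_depth} coverage in
#' a sample are scored present for that sample; a sample with no surviving
#' haplotype at a locus is missing (NA) at all of that locus's columns.
#' Columns exist only for haplotypes surviving in at least one sample.
#'
#' @param catalog a \code{rad_catalog}.
#' @param min_hap_depth minimum per-sample haplotype coverage (default 6;
#'   5/8/10 are the usual sensitivity alternates).
#' @param samples optional character vector fixing the sample set (samples
#'   without any call are all-missing rows).
#' @return a \code{hap_matrix}.
#' @export
call_symbiont_haplotypes <- function(catalog, min_hap_depth = 6,
                                     samples = NULL) {
  calls <- catalog$calls[catalog$calls$depth >= min_hap_depth, ,
                         drop = FALSE]
  if (is.null(samples)) samples <- sort(unique(catalog$calls$sample))
  if (!nrow(calls)) {
    warning("no haplotypes survive min_hap_depth; empty matrix")
    key <- data.frame(column = character(0), locus = character(0),
                      hap = integer(0), seq = character(0),
                      stringsAsFactors = FALSE)
    return(new_hap_matrix(
      matrix(NA_integer_, length(samples), 0,
             dimnames = list(samples, NULL)), key))
  }
  key <- unique(calls[c("locus", "hap_seq")])
  key <- key[order(key$locus, key$hap_seq), , drop = FALSE]
  key$hap <- as.integer(stats::ave(seq_len(nrow(key)), key$locus,
                                   FUN = seq_along))
  key$column <- sprintf("%s:h%d", key$locus, key$hap)
  m <- matrix(NA_integer_, length(samples), nrow(key),
              dimnames = list(samples, key$column))
  ## a sample observes a locus iff it has >= 1 surviving haplotype there
  obs_key <- unique(calls[c("sample", "locus")])
  for (lc in unique(key$locus)) {
    cols <- which(key$locus == lc)
    obs_samples <- obs_key$sample[obs_key$locus == lc]
    m[match(obs_samples, samples), cols] <- 0L
  }
  ci <- match(paste(calls$locus, calls$hap_seq),
              paste(key$locus, key$hap_seq))
  ri <- match(calls$sample, samples)
  m[cbind(ri, ci)] <- 1L
  key2 <- data.frame(column = key$column, locus = key$locus, hap = key$hap,
                     seq = key$hap_seq, stringsAsFactors = FALSE)
  new_hap_matrix(m, key2)
}

#' Build a de novo locus catalog from unaligned host reads
#'
#' Within each sample, exact-sequence stacks with depth >=
#' \code{min_stack_depth} are merged greedily, deepest first, into
#' sample-level loci when within \code{max_within_mismatch} mismatches of
#' the locus seed.  Sample-locus consensus sequences (the seed stack) are
#' then merged across samples into catalog loci when within
#' \code{max_catalog_mismatch} mismatches of the catalog consensus, deepest
#' first with lexicographic tie-break.  Reads of non-modal length are
#' dropped first.
#'
#' @param host_reads data.frame with \code{sample} and \code{seq}.
#' @param max_within_mismatch within-sample merge distance (M, default 2).
#' @param max_catalog_mismatch across-sample merge distance (n, default 1).
#' @param min_stack_depth minimum stack depth (m, default 3).
#' @return a \code{rad_catalog} (kind "denovo"; loci carry a
#'   \code{consensus} column).
#' @export
build_denovo_catalog <- function(host_reads, max_within_mismatch = 2,
                                 max_catalog_mismatch = 1,
                                 min_stack_depth = 3) {
  r <- host_reads
  empty <- function() new_rad_catalog(
    data.frame(locus = character(0), consensus = character(0)),
    data.frame(locus = character(0), sample = character(0),
               hap_seq = character(0), depth = integer(0)), "denovo")
  if (!nrow(r)) return(empty())
  len <- nchar(r$seq)
  tl <- table(len)
  modal <- as.integer(names(tl)[which.max(tl)])
  r <- r[len == modal, , drop = FALSE]
  if (!nrow(r)) return(empty())

  stacks <- as.data.frame(table(sample = r$sample, seq = r$seq),
                          stringsAsFactors = FALSE)
  stacks <- stacks[stacks$Freq >= min_stack_depth, , drop = FALSE]
  if (!nrow(stacks)) return(empty())
  stacks <- stacks[order(stacks$sample, -stacks$Freq, stacks$seq), ,
                   drop = FALSE]

  ## within-sample greedy merge, deepest-first
  sl <- list()  # sample-locus records: sample, consensus, stacks(df)
  for (smp in unique(stacks$sample)) {
    st <- stacks[stacks$sample == smp, , drop = FALSE]
    seeds <- character(0)
    members <- list()
    for (i in seq_len(nrow(st))) {
      d <- if (length(seeds))
        vapply(seeds, hamming, integer(1), b = st$seq[i]) else integer(0)
      j <- if (length(d) && min(d) <= max_within_mismatch)
        which.min(d) else 0L
      if (j == 0L) {
        seeds <- c(seeds, st$seq[i])
        members[[length(members) + 1L]] <- i
      } else {
        members[[j]] <- c(members[[j]], i)
      }
    }
    for (j in seq_along(seeds)) {
      sl[[length(sl) + 1L]] <- list(
        sample = smp, consensus = seeds[j],
        depth = sum(st$Freq[members[[j]]]),
        haps = data.frame(hap_seq = st$seq[members[[j]]],
                          depth = st$Freq[members[[j]]],
                          stringsAsFactors = FALSE))
    }
  }

  ## across-sample greedy merge of consensus sequences
  cons <- vapply(sl, `[[`, character(1), "consensus")
  dep <- vapply(sl, `[[`, numeric(1), "depth")
  ord <- order(-dep, cons)
  cat_seeds <- character(0)
  locus_of <- integer(length(sl))
  for (i in ord) {
    d <- if (length(cat_seeds))
      vapply(cat_seeds, hamming, integer(1), b = cons[i]) else integer(0)
    j <- if (length(d) && min(d) <= max_catalog_mismatch)
      which.min(d) else 0L
    if (j == 0L) {
      cat_seeds <- c(cat_seeds, cons[i])
      j <- length(cat_seeds)
    }
    locus_of[i] <- j
  }
  o <- order(cat_seeds)
  rank_of <- match(seq_along(cat_seeds), o)
  loci <- data.frame(locus = sprintf("D%04d", seq_along(cat_seeds)),
                     consensus = cat_seeds[o], stringsAsFactors = FALSE)
  calls <- do.call(rbind, lapply(seq_along(sl), function(i) {
    data.frame(locus = sprintf("D%04d", rank_of[locus_of[i]]),
               sample = sl[[i]]$sample, hap_seq = sl[[i]]$haps$hap_seq,
               depth = sl[[i]]$haps$depth, stringsAsFactors = FALSE)
  }))
  ## one sample may contribute two sample-loci to a catalog locus (the two
  ## alleles of a diploid): collapse duplicate (locus, sample, hap) rows
  key <- paste(calls$locus, calls$sample, calls$hap_seq)
  if (anyDuplicated(key)) {
    calls$depth <- stats::ave(calls$depth, key, FUN = sum)
    calls <- calls[!duplicated(key), , drop = FALSE]
  }
  calls <- calls[order(calls$locus, calls$sample, calls$hap_seq), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  new_rad_catalog(loci, calls, "denovo")
}

#' Call per-individual SNP genotypes from a de novo catalog
#'
#' For each catalog locus the leftmost polymorphic column across all called
#' haplotypes is the locus SNP.  A sample's diploid genotype is the count
#' of minor alleles among its one (homozygote) or two haplotypes; samples
#' with more than two haplotypes at a locus are set missing and counted.
#' Loci are dropped when not called in at least
#' \code{presence_min_per_pop} of individuals in every population, when
#' monomorphic, or when minor allele frequency falls below \code{maf_min}.
#'
#' @param catalog a \code{rad_catalog}.
#' @param populations named character vector: sample -> population.
#' @param maf_min minor-allele-frequency floor (default 0.05).
#' @param presence_min_per_pop per-population call-rate floor (default 0.7).
#' @return integer matrix (class \code{snp_matrix}) samples x loci with
#'   values 0/1/2/NA, with a \code{snp_key} attribute (locus, snp_col,
#'   major, minor).
#' @export
call_host_snps <- function(catalog, populations, maf_min = 0.05,
                           presence_min_per_pop = 0.70) {
  ## the study sample set comes from `populations`, so that samples with no
  ## call anywhere still count against per-population presence
  samples <- if (!is.null(names(populations))) sort(names(populations))
             else sort(unique(catalog$calls$sample))
  pops <- populations[samples]
  assert_that(!anyNA(pops), "populations must cover every called sample")
  assert_that(all(catalog$calls$sample %in% samples),
              "populations must cover every called sample")
  g_cols <- list()
  key <- list()
  n_multi <- 0L
  for (lc in unique(catalog$calls$locus)) {
    cl <- catalog$calls[catalog$calls$locus == lc, , drop = FALSE]
    haps_of <- split(cl$hap_seq, cl$sample)
    multi <- names(haps_of)[lengths(haps_of) > 2L]
    n_multi <- n_multi + length(multi)
    haps_of[multi] <- NULL
    if (!length(haps_of)) next
    called <- names(haps_of)
    ## per-population presence
    pres_ok <- all(vapply(split(samples, pops), function(s)
      mean(s %in% called) >= presence_min_per_pop, logical(1)))
    if (!pres_ok) next
    ## leftmost polymorphic column among all called haplotypes
    uh <- unique(unlist(haps_of))
    if (length(uh) < 2) next
    hm <- seq_matrix(uh)
    poly <- which(apply(hm, 2, function(x) length(unique(x)) > 1))
    if (!length(poly)) next
    col <- min(poly)
    ## chromosomes: homozygote contributes its allele twice
    chrom <- unlist(lapply(haps_of, function(h) {
      a <- substr(h, col, col)
      if (length(a) == 1) rep(a, 2) else a
    }))
    tab <- sort(table(chrom), decreasing = TRUE)
    if (length(tab) < 2) next
    major <- names(tab)[1]; minor <- names(tab)[2]
    geno <- rep(NA_integer_, length(samples))
    names(geno) <- samples
    for (s in called) {
      a <- substr(haps_of[[s]], col, col)
      if (length(a) == 1) a <- rep(a, 2)
      if (all(a %in% c(major, minor))) geno[s] <- sum(a == minor)
    }
    nn <- sum(!is.na(geno))
    if (nn == 0) next
    maf <- sum(geno, na.rm = TRUE) / (2 * nn)
    if (maf < maf_min || maf > 1 - maf_min) next
    g_cols[[length(g_cols) + 1L]] <- geno
    key[[length(key) + 1L]] <- data.frame(
      locus = lc, snp_col = col, major = major, minor = minor,
      stringsAsFactors = FALSE)
  }
  if (n_multi) message(n_multi,
                       " sample-locus call(s) with >2 haplotypes set missing")
  if (!length(g_cols)) {
    m <- matrix(NA_integer_, length(samples), 0,
                dimnames = list(samples, NULL))
    return(structure(m, snp_key = do.call(rbind, key),
                     class = c("snp_matrix", "matrix")))
  }
  key <- do.call(rbind, key)
  m <- do.call(cbind, g_cols)
  colnames(m) <- key$locus
  structure(m, snp_key = key, class = c("snp_matrix", "matrix"))
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("<snp_matrix> %d samples x %d SNP loci; %.1f%% missing\n",
              nrow(x), ncol(x), 100 * mean(is.na(unclass(x)))))
  invisible(x)
}

#' The missing-data filter cascade
#'
#' Stage 1 keeps loci observed (non-missing) in at least
#' \code{presence_all} of all samples.  Stage 2 keeps loci observed in at
#' least \code{presence_pop} of the samples of every population
#' (location x year sampling group).  Stage 3 splits samples into the
#' analysis datasets (each year across all sites, plus every location
#' sampled in three or more years across its years).  Stage 4, within each
#' dataset, drops individuals with more than \code{max_missing} missing
#' loci and then loci missing in more than \code{max_missing} of the
#' remaining individuals (one pass by default; \code{iterate = TRUE}
#' repeats to a fixed point).
#'
#' @param hm a \code{hap_matrix} (all samples).
#' @param meta data.frame with \code{sample}, \code{location}, \code{year}.
#' @param presence_all stage-1 threshold (default 0.70).
#' @param presence_pop stage-2 per-population threshold (default 0.50).
#' @param max_missing stage-4 missingness ceiling (default 0.15).
#' @param iterate iterate stage 4 to a fixed point.
#' @return list with \code{$full} (the stage-2 filtered matrix, the
#'   "all-datasets" catalog view), \code{$datasets} (named list of
#'   \code{hap_matrix}), and \code{$report} (per-stage sample/locus
#'   counts).
#' @export
filter_cascade <- function(hm, meta, presence_all = 0.70,
                           presence_pop = 0.50, max_missing = 0.15,
                           iterate = FALSE) {
  meta <- meta[match(rownames(hm), meta$sample), , drop = FALSE]
  assert_that(!anyNA(meta$sample), "meta must cover every sample in hm")
  obs <- locus_observed(hm)
  report <- list()
  note <- function(stage, dataset, m) {
    report[[length(report) + 1L]] <<- data.frame(
      stage = stage, dataset = dataset, n_samples = nrow(m),
      n_loci = length(unique(column_key(m)$locus)),
      stringsAsFactors = FALSE)
  }
  note("input", "all", hm)

  ## stage 1: locus observed in >= presence_all of all samples
  keep1 <- colnames(obs)[colMeans(obs) >= presence_all]
  hm1 <- hap_subset(hm, loci = keep1)
  note("presence_all", "all", hm1)

  ## stage 2: locus observed in >= presence_pop of EVERY population
  pop <- paste(meta$location, meta$year, sep = "_")
  obs1 <- obs[, keep1, drop = FALSE]
  pop_ok <- rep(TRUE, length(keep1))
  for (p in unique(pop)) {
    pop_ok <- pop_ok &
      colMeans(obs1[pop == p, , drop = FALSE]) >= presence_pop
  }
  keep2 <- keep1[pop_ok]
  hm2 <- hap_subset(hm, loci = keep2)
  note("presence_pop", "all", hm2)

  ## stage 3: dataset splits
  datasets <- list()
  for (y in sort(unique(meta$year))) {
    ## a year forms a spatial dataset only when >= 2 locations were sampled
    if (length(unique(meta$location[meta$year == y])) >= 2) {
      datasets[[as.character(y)]] <- meta$sample[meta$year == y]
    }
  }
  yrs_per_loc <- tapply(meta$year, meta$location,
                        function(x) length(unique(x)))
  for (loc in names(yrs_per_loc)[yrs_per_loc >= 3]) {
    datasets[[loc]] <- meta$sample[meta$location == loc]
  }

  ## stage 4: within-dataset missing-data pruning
  out <- list()
  for (d in names(datasets)) {
    sub <- hap_subset(hm2, samples = match(datasets[[d]], rownames(hm2)))
    note("split", d, sub)
    repeat {
      ob <- locus_observed(sub)
      drop_ind <- rowMeans(!ob) > max_missing
      if (any(drop_ind))
        sub <- hap_subset(sub, samples = which(!drop_ind))
      ob <- locus_observed(sub)
      drop_loc <- colMeans(!ob) > max_missing
      if (any(drop_loc))
        sub <- hap_subset(sub, loci = colnames(ob)[!drop_loc])
      if (!iterate || (!any(drop_ind) && !any(drop_loc))) break
    }
    note("missing15", d, sub)
    pops_in <- unique(pop[match(datasets[[d]], meta$sample)])
    pops_left <- unique(pop[match(rownames(sub), meta$sample)])
    if (!all(pops_in %in% pops_left)) {
      stop("filter cascade emptied population(s) ",
           paste(setdiff(pops_in, pops_left), collapse = ", "),
           " in dataset ", d, call. = FALSE)
    }
    out[[d]] <- sub
  }
  list(full = hm2, datasets = out, report = do.call(rbind, report))
}

#' Export a SNP genotype matrix as a minimal VCF
#'
#' GT-only body (0/0, 0/1, 1/1, ./.) with one row per SNP locus; REF/ALT
#' are the major/minor alleles of the catalog key.
#'
#' @param snps a \code{snp_matrix} from [call_host_snps()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_genotype_vcf <- function(snps, path) {
  key <- attr(snps, "snp_key")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(snps)), collapse = "\t"))
  gt <- c("0/0", "0/1", "1/1")
  rows <- vapply(seq_len(ncol(snps)), function(j) {
    g <- unclass(snps)[, j]
    gs <- ifelse(is.na(g), "./.", gt[g + 1L])
    paste(c(key$locus[j], key$snp_col[j], key$locus[j], key$major[j],
            key$minor[j], ".", "PASS", ".", "GT", gs), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
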