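#' End-to-end ddRAD library simulation for a host/symbiont survey
#'
#' Builds a symbiont reference (annotated) and an independent host
#' reference, digests both with EcoRI x MseI, simulates site-structured
#' symbiont strain pools and a panmictic (or weakly structured) diploid
#' host, composes each light organ from 2-10 strains of its site pool, and
#' emits one multiplexed FASTQ-ready read table with full truth tags.
#'
#' One strain pool is created per sampling location; pools inherit the
#' island-group labels of the design, so \code{theta_b} controls
#' between-island divergence and \code{theta_w} within-pool strain
#' diversity.
#'
#' @param design sampling design data.frame (columns location, year, n,
#'   group), e.g. [structured_design()] or [siphamia_design()].
#' @param seed master integer seed; all stage seeds derive from it.
#' @param sym_scaffolds,sym_scaffold_len,sym_cds_fraction symbiont
#'   reference shape.
#' @param host_scaffolds,host_scaffold_len host reference shape.
#' @param theta_w,theta_b strain-pool divergence densities.
#' @param strains_per_pool strains available in each site pool.
#' @param k_range admissible strain counts per light organ.
#' @param host_fst target host differentiation (0 = panmictic).
#' @param lambda_sym expected symbiont read depth per fragment per organ
#'   (shared across the organ's strains proportionally to abundance).
#' @param lambda_host expected host read depth per fragment (both alleles).
#' @param dispersion negative-binomial size parameter of the depth model.
#' @param error_rate per-base substitution error rate.
#' @param read_len total read length including the 10-bp barcode.
#' @param size_window digest size-selection window.
#' @return list of class \code{ddrad_sim}: \code{$sheet}, \code{$reads}
#'   (all samples pooled, shuffled), \code{$ref}, \code{$host_ref},
#'   \code{$frags}, \code{$host_frags}, \code{$pools}, \code{$organs},
#'   \code{$host} (genotype truth), \code{$host_loci},
#'   \code{$pool_of_location}, \code{$template_len}.
#' @export
simulate_ddrad <- function(design = structured_design(), seed = 1,
                           sym_scaffolds = 8, sym_scaffold_len = 25000,
                           sym_cds_fraction = 0.6,
                           host_scaffolds = 2, host_scaffold_len = 30000,
                           theta_w = 0.003, theta_b = 0.002,
                           strains_per_pool = 12, k_range = 2:10,
                           host_fst = 0, lambda_sym = 20, lambda_host = 20,
                           dispersion = 5, error_rate = 0, read_len = 100,
                           size_window = c(150, 450)) {
  ref <- make_reference(sym_scaffolds, sym_scaffold_len, sym_cds_fraction,
                        seed = child_seed(seed, "sym_ref"))
  host_ref <- make_reference(host_scaffolds, host_scaffold_len, 0,
                             seed = child_seed(seed, "host_ref"))
  names(host_ref$scaffolds) <- sprintf("host_scaffold_%d",
                                       seq_along(host_ref$scaffolds))
  frags <- digest_and_select(ref, size_window = size_window)
  host_frags <- digest_and_select(host_ref, size_window = size_window)
  sheet <- design_sheet(design, seed = child_seed(seed, "sheet"))
  template_len <- read_len - 10L

  locs <- unique(design$location)
  grp <- design$group[match(locs, design$location)]
  pools <- simulate_strain_pools(
    ref, strains_per_pool = strains_per_pool, theta_w = theta_w,
    theta_b = theta_b, seed = child_seed(seed, "pools"),
    pool_groups = grp)
  pool_of_location <- setNames(pools$pools$pool, locs)
  organs <- compose_light_organs(sheet, pools, pool_of_location, k_range,
                                 seed = child_seed(seed, "organs"))
  hp <- plant_host_loci(host_ref, host_frags, nrow(sheet),
                        fst_target = host_fst,
                        populations = sheet$location,
                        template_len = template_len,
                        seed = child_seed(seed, "host"))

  sym_tpl <- build_symbiont_templates(ref, pools, frags, template_len)
  host_win <- hp$windows
  reads <- vector("list", nrow(sheet))
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample[i]
    comp <- organs[organs$sample == sid, , drop = FALSE]
    tpl_i <- sym_tpl[sym_tpl$hap %in% comp$strain, , drop = FALSE]
    mu_sym <- lambda_sym * comp$abundance[match(tpl_i$hap, comp$strain)]
    r_sym <- generate_reads(tpl_i, mu_sym, dispersion, error_rate,
                            sheet$barcode[i], read_len, sample = sid,
                            origin = "symbiont",
                            seed = child_seed(seed, paste0("rs_", sid)))
    g <- hp$host$genotypes[i, ]
    htpl <- rbind(
      data.frame(frag_id = hp$loci$frag_id, hap = "ref",
                 seq = hp$loci$ref_template, stringsAsFactors = FALSE),
      data.frame(frag_id = hp$loci$frag_id, hap = "alt",
                 seq = hp$loci$alt_template, stringsAsFactors = FALSE))
    mu_host <- lambda_host * c(2L - g, g) / 2
    keep <- mu_host > 0
    r_host <- generate_reads(htpl[keep, , drop = FALSE], mu_host[keep],
                             dispersion, error_rate, sheet$barcode[i],
                             read_len, sample = sid, origin = "host",
                             seed = child_seed(seed, paste0("rh_", sid)))
    reads[[i]] <- rbind(r_sym, r_host)
  }
  reads <- do.call(rbind, reads)
  reads <- with_seed(child_seed(seed, "shuffle"),
                     reads[sample.int(nrow(reads)), , drop = FALSE])
  reads$id <- sprintf("read_%07d", seq_len(nrow(reads)))
  rownames(reads) <- NULL
  structure(list(sheet = sheet, reads = reads, ref = ref,
                 host_ref = host_ref, frags = frags,
                 host_frags = host_frags, pools = pools, organs = organs,
                 host = hp$host, host_loci = hp$loci,
                 host_windows = hp$windows,
                 pool_of_location = pool_of_location,
                 template_len = template_len),
            class = "ddrad_sim")
}

#' @export
print.ddrad_sim <- function(x, ...) {
  cat(sprintf(
    "<ddrad_sim> %d samples, %d reads (%d symbiont fragments, %d host)\n",
    nrow(x$sheet), nrow(x$reads), nrow(x$frags), nrow(x$host_frags)))
  invisible(x)
}

#' Write a simulation to disk as standard interchange files
#'
#' Emits reference FASTA + GFF3 (symbiont), host FASTA, multiplexed FASTQ,
#' the sample sheet TSV, and TSV truth tables (strain compositions,
#' planted variants, host genotypes).
#'
#' @param sim a \code{ddrad_sim}.
#' @param dir output directory (created if needed).
#' @return invisibly, a named vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(ref_fasta = file.path(dir, "symbiont_ref.fasta"),
         ref_gff = file.path(dir, "symbiont_ref.gff3"),
         host_fasta = file.path(dir, "host_ref.fasta"),
         fastq = file.path(dir, "reads.fastq"),
         sheet = file.path(dir, "sample_sheet.tsv"),
         organs = file.path(dir, "truth_strain_composition.tsv"),
         variants = file.path(dir, "truth_variants.tsv"),
         host_geno = file.path(dir, "truth_host_genotypes.tsv"))
  write_reference(sim$ref, p["ref_fasta"], p["ref_gff"])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(
    sim$host_ref$scaffolds), p["host_fasta"], width = 70)
  write_fastq(sim$reads, p["fastq"])
  write_sample_sheet(sim$sheet, p["sheet"])
  write.table(sim$organs, p["organs"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$pools$variants, p["variants"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  g <- as.data.frame(sim$host$genotypes)
  g <- cbind(sample = sim$sheet$sample, population = sim$host$populations, g)
  write.table(g, p["host_geno"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(p)
}

#' Read a flat key=value configuration file
#'
#' Blank lines and lines starting with \code{#} are ignored; values are
#' auto-coerced to numeric where possible, and comma-separated values
#' become vectors.
#'
#' @param path config path.
#' @return named list.
#' @export
read_config <- function(path) {
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))
  assert_that(all(lengths(kv) == 3), "config lines must be key=value")
  out <- lapply(kv, function(x) {
    v <- strsplit(trimws(x[3]), ",", fixed = TRUE)[[1]]
    v <- trimws(v)
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else v
  })
  names(out) <- vapply(kv, function(x) trimws(x[2]), character(1))
  out
}
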