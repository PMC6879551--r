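#' Simulate diploid host genotypes
#'
#' Draws biallelic genotypes for a host population that is panmictic by
#' default (\code{fst_target = 0}).  For \code{fst_target > 0} per-population
#' allele frequencies are perturbed around the ancestral frequency with a
#' Balding-Nichols beta distribution,
#' Beta(p(1-F)/F, (1-p)(1-F)/F), whose realized Weir-Cockerham F_ST is
#' approximately \code{fst_target}.
#'
#' @param n_samples total number of diploid individuals.
#' @param n_loci number of biallelic loci (>= 100 unless
#'   \code{allow_small = TRUE}).
#' @param fst_target target differentiation in \[0, 0.5).
#' @param maf_dist function(n) returning n ancestral minor allele
#'   frequencies; default Uniform(0.05, 0.5).
#' @param populations character/factor of length \code{n_samples} assigning
#'   individuals to populations (default: one population).
#' @param seed integer seed.
#' @param allow_small bypass the n_loci >= 100 guard for toy fixtures.
#' @return list with \code{$genotypes} (integer matrix samples x loci,
#'   minor-allele dosage 0/1/2), \code{$p_anc} (ancestral frequencies),
#'   \code{$p_pop} (matrix populations x loci of realized frequencies) and
#'   \code{$populations}.
#' @export
simulate_host <- function(n_samples, n_loci = 1000, fst_target = 0,
                          maf_dist = function(n) runif(n, 0.05, 0.5),
                          populations = NULL, seed = 1,
                          allow_small = FALSE) {
  assert_that(allow_small || n_loci >= 100, "n_loci must be >= 100")
  assert_that(fst_target >= 0 && fst_target < 0.5,
              "fst_target must be in [0, 0.5)")
  if (is.null(populations)) populations <- rep("pop_1", n_samples)
  populations <- as.character(populations)
  assert_that(length(populations) == n_samples,
              "populations must have length n_samples")
  with_seed(seed, {
    p_anc <- maf_dist(n_loci)
    pops <- unique(populations)
    p_pop <- matrix(rep(p_anc, each = length(pops)), nrow = length(pops),
                    dimnames = list(pops, NULL))
    if (fst_target > 0) {
      shape_scale <- (1 - fst_target) / fst_target
      for (i in seq_along(pops)) {
        p_pop[i, ] <- rbeta(n_loci, p_anc * shape_scale,
                            (1 - p_anc) * shape_scale)
      }
    }
    g <- matrix(0L, n_samples, n_loci,
                dimnames = list(sprintf("ind_%03d", seq_len(n_samples)),
                                sprintf("hl_%04d", seq_len(n_loci))))
    for (i in seq_len(n_samples)) {
      g[i, ] <- rbinom(n_loci, 2L, p_pop[populations[i], ])
    }
    list(genotypes = g, p_anc = p_anc, p_pop = p_pop,
         populations = populations)
  })
}

## Plant one biallelic SNP per host locus (fragment template window) and
## express host diploid haplotypes.  Returns per-locus SNP metadata plus a
## function-ready haplotype table: for each sample x locus, the two allele
## sequences implied by the genotype.
plant_host_loci <- function(host_ref, frags, n_samples, fst_target = 0,
                            populations = NULL, template_len = 90,
                            seed = 1, maf_dist = function(n)
                              runif(n, 0.1, 0.5)) {
  win <- fragment_template_window(frags, template_len)
  win <- win[!win$truncated, , drop = FALSE]
  n_loci <- nrow(win)
  assert_that(n_loci > 0, "host reference yields no usable fragments")
  host <- simulate_host(n_samples, n_loci, fst_target, maf_dist,
                        populations, seed = child_seed(seed, "host_geno"),
                        allow_small = TRUE)
  with_seed(child_seed(seed, "host_snps"), {
    ref_tpl <- template_sequences(host_ref, win)
    snp_col <- sample.int(template_len, n_loci, replace = TRUE)
    ref_base <- substring(ref_tpl, snp_col, snp_col)
    alt_base <- vapply(ref_base, function(r)
      sample(setdiff(DNA_BASES, r), 1), character(1))
    alt_tpl <- ref_tpl
    substr(alt_tpl, snp_col, snp_col) <- alt_base
    list(host = host, windows = win,
         loci = data.frame(frag_id = win$frag_id, snp_col = snp_col,
                           ref = unname(ref_base), alt = unname(alt_base),
                           ref_template = ref_tpl, alt_template = alt_tpl,
                           stringsAsFactors = FALSE))
  })
}

## Read-orientation template sequences for fragment windows.
template_sequences <- function(ref, win) {
  s <- substring(ref$scaffolds[win$scaffold], win$start, win$end)
  s[win$rc] <- revcomp(s[win$rc])
  unname(s)
}
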