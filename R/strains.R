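#' Simulate hierarchically structured symbiont strain pools
#'
#' Plants substitution variants against the reference under a two-level
#' hierarchy: island groups carry group-level variants shared by every pool
#' (site) in the group, at per-site density \code{theta_b}; each strain
#' additionally carries private variants at density \code{theta_w}.  With
#' \code{theta_b = 0} the group level contributes no signal and all strains
#' are exchangeable across groups.
#'
#' @param ref a \code{rad_reference} (annotations, when present, are used to
#'   pre-compute the coding consequence of every planted variant).
#' @param n_groups number of island groups.
#' @param pools_per_group number of site-level pools per group.
#' @param strains_per_pool strains in each pool.
#' @param theta_w per-site density of strain-private variants, in \[0, 0.02\].
#' @param theta_b per-site density of group-level shared variants, in
#'   \[0, 0.02\].
#' @param seed integer seed.
#' @param pool_groups optional character vector giving the group label of
#'   each pool explicitly (for unbalanced designs); overrides
#'   \code{n_groups}/\code{pools_per_group}.
#' @return An object of class \code{strain_pools}: list with
#'   \code{$variants} (data.frame: variant_id, scaffold, pos, ref, alt,
#'   level, group, strain, type, effect), \code{$strains} (data.frame:
#'   strain, pool, group), \code{$pools} (data.frame: pool, group),
#'   \code{$strain_variants} (named list strain -> integer variant ids) and
#'   \code{$genome_length}.
#' @export
simulate_strain_pools <- function(ref, n_groups = 2, pools_per_group = 2,
                                  strains_per_pool = 5, theta_w = 0.003,
                                  theta_b = 0.002, seed = 1,
                                  pool_groups = NULL) {
  assert_that(theta_w >= 0 && theta_w <= 0.02, "theta_w must be in [0, 0.02]")
  assert_that(theta_b >= 0 && theta_b <= 0.02, "theta_b must be in [0, 0.02]")
  scaff_len <- nchar(ref$scaffolds)
  L <- sum(scaff_len)
  offsets <- cumsum(c(0, scaff_len[-length(scaff_len)]))
  names(offsets) <- names(scaff_len)
  with_seed(seed, {
    pools <- if (is.null(pool_groups)) {
      data.frame(
        pool = sprintf("pool_%d", seq_len(n_groups * pools_per_group)),
        group = rep(sprintf("group_%d", seq_len(n_groups)),
                    each = pools_per_group),
        stringsAsFactors = FALSE)
    } else {
      data.frame(pool = sprintf("pool_%d", seq_along(pool_groups)),
                 group = as.character(pool_groups),
                 stringsAsFactors = FALSE)
    }
    strains <- data.frame(
      strain = sprintf("%s_s%d", rep(pools$pool, each = strains_per_pool),
                       rep(seq_len(strains_per_pool), nrow(pools))),
      pool = rep(pools$pool, each = strains_per_pool),
      group = rep(pools$group, each = strains_per_pool),
      stringsAsFactors = FALSE)

    draw_positions <- function(theta) {
      n <- rpois(1, theta * L)
      sort(sample.int(L, min(n, L)))
    }
    genome_pos <- function(gpos) {
      sc_idx <- findInterval(gpos, cumsum(scaff_len) - scaff_len + 1)
      data.frame(scaffold = names(scaff_len)[sc_idx],
                 pos = as.integer(gpos - offsets[sc_idx]),
                 stringsAsFactors = FALSE)
    }
    rows <- list()
    for (g in unique(pools$group)) {
      p <- genome_pos(draw_positions(theta_b))
      if (nrow(p)) rows[[length(rows) + 1L]] <-
        cbind(p, level = "group", group = g, strain = NA_character_,
              stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(strains))) {
      p <- genome_pos(draw_positions(theta_w))
      if (nrow(p)) rows[[length(rows) + 1L]] <-
        cbind(p, level = "strain", group = strains$group[i],
              strain = strains$strain[i], stringsAsFactors = FALSE)
    }
    variants <- if (length(rows)) do.call(rbind, rows) else
      data.frame(scaffold = character(0), pos = integer(0),
                 level = character(0), group = character(0),
                 strain = character(0), stringsAsFactors = FALSE)
    if (nrow(variants)) {
      ## collisions at the same genomic position: keep the first planted
      key <- paste(variants$scaffold, variants$pos)
      ## identical (position, carrier) duplicates are impossible; cross-
      ## carrier collisions would create inconsistent alt alleles
      dup <- duplicated(key)
      if (any(dup)) {
        message(sum(dup), " variant position collision(s) resolved by ",
                "keeping the first planted variant")
        variants <- variants[!dup, , drop = FALSE]
      }
      variants$ref <- substring(ref$scaffolds[variants$scaffold],
                                variants$pos, variants$pos)
      ref_idx <- match(variants$ref, DNA_BASES)
      variants$alt <- DNA_BASES[
        (ref_idx - 1L + sample(3L, nrow(variants), replace = TRUE)) %% 4L +
          1L]
      variants$variant_id <- seq_len(nrow(variants))
      csq <- classify_variants(variants, ref)
      variants$type <- csq$type
      variants$effect <- csq$effect
      variants$gene <- csq$gene
      variants$product <- csq$product
    } else {
      variants$ref <- character(0); variants$alt <- character(0)
      variants$variant_id <- integer(0); variants$type <- character(0)
      variants$effect <- character(0); variants$gene <- character(0)
      variants$product <- character(0)
    }
    strain_variants <- lapply(seq_len(nrow(strains)), function(i) {
      v <- variants$variant_id[
        (variants$level == "group" & variants$group == strains$group[i]) |
        (variants$level == "strain" &
           !is.na(variants$strain) & variants$strain == strains$strain[i])]
      sort(v)
    })
    names(strain_variants) <- strains$strain
    structure(list(variants = variants, strains = strains, pools = pools,
                   strain_variants = strain_variants, genome_length = L),
              class = "strain_pools")
  })
}

#' @export
print.strain_pools <- function(x, ...) {
  cat(sprintf(
    "<strain_pools> %d groups, %d pools, %d strains, %d planted variants\n",
    length(unique(x$pools$group)), nrow(x$pools), nrow(x$strains),
    nrow(x$variants)))
  invisible(x)
}

#' Compose the symbiont population of one light organ
#'
#' Draws the number of strains k uniformly from \code{k_range}, picks k
#' distinct strains from the sample's site pool, and assigns relative
#' abundances from a symmetric Dirichlet(1) distribution.
#'
#' @param sample_id sample identifier recorded in the output.
#' @param pool pool id (must exist in \code{pools$pools}).
#' @param pools a \code{strain_pools} object.
#' @param k_range integer vector of admissible strain counts.
#' @param seed integer seed.
#' @return data.frame: sample, strain, abundance (summing to 1).
#' @export
compose_light_organ <- function(sample_id, pool, pools, k_range = 2:10,
                                seed = NULL) {
  avail <- pools$strains$strain[pools$strains$pool == pool]
  assert_that(length(avail) > 0, paste("unknown or empty pool:", pool))
  with_seed(seed, {
    k_range <- k_range[k_range <= length(avail)]
    assert_that(length(k_range) > 0,
                "k_range exceeds the number of available strains")
    k <- if (length(k_range) == 1) k_range else sample(k_range, 1)
    chosen <- sample(avail, k, replace = FALSE)
    ab <- rgamma(k, shape = 1)
    data.frame(sample = sample_id, strain = chosen, abundance = ab / sum(ab),
               stringsAsFactors = FALSE)
  })
}

#' Compose light organs for a whole sample sheet
#'
#' @param sheet sample sheet (data.frame with \code{sample} and
#'   \code{location} columns).
#' @param pools a \code{strain_pools} object.
#' @param pool_of_location named character: location id -> pool id.  By
#'   default locations are assigned to pools round-robin in order of first
#'   appearance.
#' @param k_range,seed see [compose_light_organ()].
#' @return data.frame: sample, strain, abundance; one block per sample.
#' @export
compose_light_organs <- function(sheet, pools, pool_of_location = NULL,
                                 k_range = 2:10, seed = 1) {
  locs <- unique(sheet$location)
  if (is.null(pool_of_location)) {
    pool_of_location <- setNames(
      rep_len(pools$pools$pool, length(locs)), locs)
  }
  assert_that(all(locs %in% names(pool_of_location)),
              "every location needs a pool assignment")
  out <- lapply(seq_len(nrow(sheet)), function(i) {
    compose_light_organ(sheet$sample[i],
                        pool_of_location[[sheet$location[i]]], pools,
                        k_range, seed = child_seed(seed, sheet$sample[i]))
  })
  do.call(rbind, out)
}

## Variant ids within a forward-strand window for each strain --------------

variants_in_window <- function(pools, scaffold, start, end) {
  v <- pools$variants
  v$variant_id[v$scaffold == scaffold & v$pos >= start & v$pos <= end]
}

#' Truth-level symbiont haplotype presence matrix
#'
#' Builds the samples x (locus, haplotype) presence matrix implied by the
#' simulation truth alone (perfect sequencing at infinite depth): at each
#' locus window, strains are partitioned into haplotype classes by the set
#' of planted variants they carry inside the window, and a sample is
#' "present" for every class represented in its light organ.
#'
#' @param pools a \code{strain_pools} object.
#' @param organs composition data.frame from [compose_light_organs()].
#' @param frags fragment table from [digest_and_select()].
#' @param template_len read-template length (bp) taken from the EcoRI end.
#' @return a \code{hap_matrix}: binary matrix (1 = present, 0 = absent; no
#'   missing data at truth level) with a \code{column_key} attribute
#'   (data.frame: column, locus, hap, n_variants) and a
#'   \code{strain_classes} attribute (matrix strains x loci of class ids).
#' @export
truth_haplotype_matrix <- function(pools, organs, frags, template_len = 90) {
  win <- fragment_template_window(frags, template_len)
  strains <- pools$strains$strain
  sv <- pools$strain_variants
  samples <- unique(organs$sample)
  class_mat <- matrix(NA_integer_, length(strains), nrow(win),
                      dimnames = list(strains, win$frag_id))
  cols <- list()
  pres <- list()
  for (j in seq_len(nrow(win))) {
    ids_w <- variants_in_window(pools, win$scaffold[j], win$start[j],
                                win$end[j])
    sig <- vapply(strains, function(s)
      paste(intersect(sv[[s]], ids_w), collapse = ","), character(1))
    classes <- match(sig, unique(sig))
    class_mat[, j] <- classes
    for (h in sort(unique(classes))) {
      cols[[length(cols) + 1L]] <- data.frame(
        locus = win$frag_id[j], hap = h,
        n_variants = length(strsplit(sig[match(h, classes)], ",")[[1]]),
        stringsAsFactors = FALSE)
      pres[[length(pres) + 1L]] <- strains[classes == h]
    }
  }
  key <- do.call(rbind, cols)
  key$column <- sprintf("%s:h%d", key$locus, key$hap)
  m <- matrix(0L, length(samples), nrow(key),
              dimnames = list(samples, key$column))
  strain_of <- split(organs$strain, organs$sample)
  for (i in seq_along(samples)) {
    mine <- strain_of[[samples[i]]]
    m[i, ] <- vapply(pres, function(members) as.integer(any(mine %in% members)),
                     integer(1))
  }
  new_hap_matrix(m, key[, c("column", "locus", "hap", "n_variants")],
                 extra = list(strain_classes = class_mat))
}
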