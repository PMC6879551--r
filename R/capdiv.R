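## Variant-effect classification --------------------------------------------

EFFECT_OF_TYPE <- c(synonymous = "LOW", "non-synonymous" = "MODERATE",
                    "stop-gained" = "HIGH", upstream = "MODIFIER",
                    intergenic = "none", consensus = "none")
SEVERITY <- c(HIGH = 4, MODERATE = 3, LOW = 2, MODIFIER = 1, none = 0)

## reverse-complement a vector of codons (pure string ops; hot path)
revcomp_codon <- function(x) {
  y <- chartr("ACGT", "TGCA", x)
  paste0(substr(y, 3, 3), substr(y, 2, 2), substr(y, 1, 1))
}

## Classify planted/observed substitutions against an annotated reference.
## variants: data.frame(scaffold, pos, ref, alt).  Returns type/effect/gene/
## product per row; a variant inside overlapping CDS features is classified
## against each and summarized by the most severe call (flagged).
## Vectorized for non-overlapping annotations (the generator guarantees
## this); scaffolds with overlapping CDS fall back to a per-variant scan.
classify_variants <- function(variants, ref, upstream_window = 500) {
  ann <- ref$annotations
  n <- nrow(variants)
  out <- data.frame(type = rep("intergenic", n),
                    effect = rep("none", n),
                    gene = rep(NA_character_, n),
                    product = rep(NA_character_, n),
                    multi_cds = rep(FALSE, n),
                    stringsAsFactors = FALSE)
  if (!n) return(out)
  for (sc in unique(variants$scaffold)) {
    vi <- which(variants$scaffold == sc)
    a <- ann[ann$scaffold == sc, , drop = FALSE]
    a <- a[order(a$start), , drop = FALSE]
    overlapping <- nrow(a) > 1 && any(a$end[-nrow(a)] >= a$start[-1])
    if (overlapping) {
      for (i in vi) {
        out[i, ] <- classify_one(variants$pos[i], variants$alt[i],
                                 ref$scaffolds[[sc]], a, upstream_window)
      }
      next
    }
    pos <- variants$pos[vi]
    alt <- variants$alt[vi]
    res <- classify_scaffold(pos, alt, ref$scaffolds[[sc]], a,
                             upstream_window)
    out$type[vi] <- res$type
    out$effect[vi] <- res$effect
    out$gene[vi] <- res$gene
    out$product[vi] <- res$product
  }
  out
}

## Vectorized classification for one scaffold with sorted, non-overlapping
## CDS features.
classify_scaffold <- function(pos, alt, scaffold_seq, a, upstream_window) {
  n <- length(pos)
  type <- rep("intergenic", n)
  gene <- product <- rep(NA_character_, n)
  if (nrow(a)) {
    fi <- findInterval(pos, a$start)
    in_cds <- fi > 0 & pos <= a$end[pmax(fi, 1)]
    if (any(in_cds)) {
      i <- which(in_cds); f <- fi[i]
      plus <- a$strand[f] == "+"
      codon <- new <- character(length(i))
      ## forward-strand features: frame anchored at start
      if (any(plus)) {
        off <- pos[i][plus] - a$start[f][plus]
        cst <- a$start[f][plus] + (off %/% 3L) * 3L
        codon[plus] <- substring(scaffold_seq, cst, cst + 2L)
        nw <- codon[plus]
        substr(nw, off %% 3L + 1L, off %% 3L + 1L) <- alt[i][plus]
        new[plus] <- nw
      }
      ## reverse-strand features: frame anchored at end
      if (any(!plus)) {
        off <- a$end[f][!plus] - pos[i][!plus]
        cen <- a$end[f][!plus] - (off %/% 3L) * 3L
        cf <- substring(scaffold_seq, cen - 2L, cen)
        nf <- cf
        substr(nf, 3L - off %% 3L, 3L - off %% 3L) <- alt[i][!plus]
        codon[!plus] <- revcomp_codon(cf)
        new[!plus] <- revcomp_codon(nf)
      }
      aa_old <- Biostrings::GENETIC_CODE[codon]
      aa_new <- Biostrings::GENETIC_CODE[new]
      type[i] <- ifelse(aa_old == aa_new, "synonymous",
                        ifelse(aa_new == "*", "stop-gained",
                               "non-synonymous"))
      gene[i] <- a$gene[f]
      product[i] <- a$product[f]
    }
    ## strand-aware upstream window for the remainder
    rest <- which(!in_cds)
    if (length(rest)) {
      sp <- a[a$strand == "+", , drop = FALSE]
      sm <- a[a$strand == "-", , drop = FALSE]
      cand_d <- rep(Inf, length(rest))
      cand_h <- rep(NA_integer_, length(rest))
      if (nrow(sp)) {
        nxt <- findInterval(pos[rest], sp$start) + 1L
        ok <- nxt <= nrow(sp)
        d <- ifelse(ok, sp$start[pmin(nxt, nrow(sp))] - pos[rest], Inf)
        upd <- d <= upstream_window & d < cand_d
        cand_d[upd] <- d[upd]
        cand_h[upd] <- which(a$strand == "+")[nxt[upd]]
      }
      if (nrow(sm)) {
        prv <- findInterval(pos[rest] - 1L, sm$end)
        ok <- prv >= 1
        d <- ifelse(ok, pos[rest] - sm$end[pmax(prv, 1)], Inf)
        upd <- d <= upstream_window & d < cand_d & d >= 1
        cand_d[upd] <- d[upd]
        cand_h[upd] <- which(a$strand == "-")[prv[upd]]
      }
      hit <- !is.na(cand_h)
      type[rest][hit] <- "upstream"
      gene[rest][hit] <- a$gene[cand_h[hit]]
      product[rest][hit] <- a$product[cand_h[hit]]
    }
  }
  list(type = type, effect = unname(EFFECT_OF_TYPE[type]), gene = gene,
       product = product)
}

## General per-variant path (overlapping CDS allowed; most severe call
## wins, multi_cds flagged).
classify_one <- function(pos, alt, scaffold_seq, a, upstream_window) {
  hits <- which(a$start <= pos & a$end >= pos)
  if (length(hits)) {
    res <- lapply(hits, function(h)
      classify_scaffold(pos, alt, scaffold_seq, a[h, , drop = FALSE],
                        upstream_window))
    sev <- vapply(res, function(r) SEVERITY[[r$effect]], numeric(1))
    best <- res[[which.max(sev)]]
    return(data.frame(type = best$type, effect = best$effect,
                      gene = best$gene, product = best$product,
                      multi_cds = length(hits) > 1,
                      stringsAsFactors = FALSE))
  }
  r <- classify_scaffold(pos, alt, scaffold_seq, a, upstream_window)
  data.frame(type = r$type, effect = r$effect, gene = r$gene,
             product = r$product, multi_cds = FALSE,
             stringsAsFactors = FALSE)
}

#' Annotate a called haplotype against the annotated reference
#'
#' Aligns the haplotype gap-free at its locus anchor, emits one variant
#' call per mismatching column, classifies each (codon translation inside
#' CDS; strand-aware 500 bp upstream window otherwise) and summarizes the
#' haplotype by its most severe effect (HIGH > MODERATE > LOW > MODIFIER).
#' A haplotype identical to the reference is type "consensus" with effect
#' "none".
#'
#' @param hap_seq haplotype sequence in read orientation.
#' @param anchor list/row with \code{scaffold}, \code{start}, \code{strand}
#'   (locus anchor; \code{strand == "-"} means the read orientation is the
#'   reverse strand).
#' @param ref annotated \code{rad_reference}.
#' @param upstream_window bp upstream of a CDS start classified MODIFIER.
#' @return list: \code{$calls} (data.frame scaffold, pos, ref, alt, type,
#'   effect, gene, product, multi_cds), \code{$type}, \code{$effect},
#'   \code{$gene}, \code{$product} (haplotype-level summary).
#' @export
annotate_variant <- function(hap_seq, anchor, ref, upstream_window = 500) {
  len <- nchar(hap_seq)
  fwd <- if (anchor$strand == "-") revcomp(hap_seq) else hap_seq
  region <- substr(ref$scaffolds[[anchor$scaffold]], anchor$start,
                   anchor$start + len - 1L)
  assert_that(nchar(region) == len, "locus anchor outside scaffold")
  a <- strsplit(fwd, "")[[1]]
  b <- strsplit(region, "")[[1]]
  mism <- which(a != b)
  if (!length(mism)) {
    calls <- data.frame(scaffold = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        type = character(0), effect = character(0),
                        gene = character(0), product = character(0),
                        multi_cds = logical(0), stringsAsFactors = FALSE)
    return(list(calls = calls, type = "consensus", effect = "none",
                gene = NA_character_, product = NA_character_))
  }
  calls <- data.frame(scaffold = anchor$scaffold,
                      pos = anchor$start + mism - 1L,
                      ref = b[mism], alt = a[mism],
                      stringsAsFactors = FALSE)
  cls <- classify_variants(calls, ref, upstream_window)
  calls <- cbind(calls, cls)
  worst <- which.max(SEVERITY[calls$effect])
  list(calls = calls, type = calls$type[worst],
       effect = calls$effect[worst], gene = calls$gene[worst],
       product = calls$product[worst])
}

## Constrained ordination ----------------------------------------------------

#' Constrained analysis of principal coordinates (db-RDA)
#'
#' PCoA of the dissimilarity matrix (positive-eigenvalue axes), followed by
#' least-squares projection of the coordinates on the factor's centered
#' indicator matrix; the constrained axes are the principal directions of
#' the fitted values.  Sample scores are the projections of the (full)
#' PCoA coordinates onto the constrained axes; haplotype (column) scores
#' are presence-weighted averages of sample scores.  An optional
#' permutation test of the constraint permutes factor labels.
#'
#' @param D dissimilarity matrix of the samples.
#' @param hm the \code{hap_matrix} the distances came from (same samples,
#'   same order); used for haplotype scores.
#' @param groups factor/character constraint (>= 2 levels).
#' @param n_permutations permutations for the constraint test (0 = skip).
#' @param seed integer seed.
#' @return list of class \code{cap_result}: \code{$sample_scores} (samples
#'   x constrained axes), \code{$hap_scores} (columns x axes),
#'   \code{$eigenvalues} (constrained), \code{$groups},
#'   \code{$p} (NA unless tested).
#' @export
cap <- function(D, hm, groups, n_permutations = 0, seed = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  groups <- as.character(groups)
  assert_that(length(groups) == n, "groups must match D")
  assert_that(length(unique(groups)) >= 2, "constraint has a single level")
  pc <- pcoa(D)
  Y <- pc$coordinates
  X <- stats::model.matrix(~ 0 + factor(groups))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qrX <- qr(Xc)
  fitted <- qr.fitted(qrX, Y)
  sv <- svd(fitted)
  tol <- max(sv$d) * 1e-8
  keep <- which(sv$d > tol)
  k <- length(keep)
  V <- sv$v[, keep, drop = FALSE]
  scores <- Y %*% V
  ## deterministic orientation
  for (j in seq_len(ncol(scores))) {
    if (k && scores[which.max(abs(scores[, j])), j] < 0) {
      scores[, j] <- -scores[, j]
      V[, j] <- -V[, j]
    }
  }
  colnames(scores) <- if (k) sprintf("CAP%d", seq_len(k)) else character(0)
  rownames(scores) <- rownames(D)
  eig <- sv$d[keep]^2 / (n - 1)
  m <- unclass(hm)
  hap_scores <- matrix(NA_real_, ncol(m), k,
                       dimnames = list(colnames(m), colnames(scores)))
  if (k && ncol(m)) {
    pres <- m == 1L & !is.na(m)
    npres <- colSums(pres)
    for (j in seq_len(k)) {
      hap_scores[, j] <- ifelse(npres > 0,
                                colSums(pres * scores[, j]) / npres, NA)
    }
  }
  p <- NA_real_
  if (n_permutations > 0 && k) {
    tot <- sum(Y^2)
    stat <- function(g) {
      Xp <- scale(stats::model.matrix(~ 0 + factor(g)), center = TRUE,
                  scale = FALSE)
      sum(qr.fitted(qr(Xp), Y)^2)
    }
    s_obs <- sum(fitted^2)
    s_perm <- with_seed(seed, vapply(seq_len(n_permutations), function(i)
      stat(groups[sample.int(n)]), numeric(1)))
    p <- (1 + sum(s_perm >= s_obs - 1e-12)) / (1 + n_permutations)
  }
  structure(list(sample_scores = scores, hap_scores = hap_scores,
                 eigenvalues = eig, groups = groups, p = p,
                 pcoa = pc), class = "cap_result")
}

#' @export
print.cap_result <- function(x, ...) {
  cat(sprintf("<cap_result> %d constrained axes over %d samples",
              length(x$eigenvalues), nrow(x$sample_scores)))
  if (!is.na(x$p)) cat(sprintf("; constraint p = %.4g", x$p))
  cat("\n")
  invisible(x)
}

#' Select outlier haplotypes from CAP column scores
#'
#' Stage 1 flags haplotypes beyond the \code{pct_high}/\code{pct_low}
#' percentile cuts of the score distribution on either of the first two
#' constrained axes.  Stage 2 keeps those whose absolute score also
#' exceeds \code{gap_factor} times the percentile-cut magnitude on the
#' flagging axis -- an explicit operationalization of "large difference
#' relative to all other haplotypes".  With fewer than 100 scored
#' haplotypes the percentile cut degenerates; the top and bottom score on
#' each axis are used instead (with a warning).
#'
#' @param capres a \code{cap_result}.
#' @param pct_high,pct_low percentile cuts (defaults 0.99 / 0.01).
#' @param gap_factor stage-2 multiplier on the cut magnitude (default 2).
#' @return data.frame: column, locus, hap, axis, score, cut, stage2.
#' @export
select_outlier_haplotypes <- function(capres, pct_high = 0.99,
                                      pct_low = 0.01, gap_factor = 2.0) {
  hs <- capres$hap_scores
  n_axes <- min(2L, ncol(hs))
  assert_that(n_axes >= 1, "no constrained axes to select from")
  rows <- list()
  for (ax in seq_len(n_axes)) {
    s <- hs[, ax]
    s <- s[!is.na(s)]
    if (length(s) < 100) {
      warning("fewer than 100 scored haplotypes; using rank-based ",
              "top/bottom 1 on axis ", ax)
      hi <- max(s); lo <- min(s)
      cand <- names(s)[s >= hi | s <= lo]
      cuts <- setNames(rep(NA_real_, length(cand)), cand)
      st2 <- rep(TRUE, length(cand))
    } else {
      hi <- quantile(s, pct_high, names = FALSE)
      lo <- quantile(s, pct_low, names = FALSE)
      cand <- names(s)[s > hi | s < lo]
      cuts <- ifelse(s[cand] > hi, hi, lo)
      st2 <- abs(s[cand]) > gap_factor * abs(cuts)
    }
    if (length(cand)) {
      rows[[length(rows) + 1L]] <- data.frame(
        column = cand, axis = ax, score = unname(s[cand]),
        cut = unname(cuts), stage2 = unname(st2),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(column = character(0), axis = integer(0),
               score = numeric(0), cut = numeric(0), stage2 = logical(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-locus genome context and inter-locus spacing
#'
#' Maps each reference-anchored locus to its scaffold coordinates and any
#' overlapping CDS feature, and returns all pairwise within-scaffold
#' distances between locus starts (the marker-spacing distribution).
#'
#' @param catalog a reference-guided \code{rad_catalog}.
#' @param ref annotated \code{rad_reference}.
#' @param template_len locus template length (bp).
#' @return list: \code{$loci} (locus, scaffold, start, strand, gene,
#'   product), \code{$distances} (numeric vector of within-scaffold
#'   pairwise start distances).
#' @export
locus_genome_map <- function(catalog, ref, template_len = 90) {
  assert_that(catalog$kind == "reference",
              "locus_genome_map needs a reference-anchored catalog")
  loci <- catalog$loci
  ann <- ref$annotations
  gene <- product <- rep(NA_character_, nrow(loci))
  for (i in seq_len(nrow(loci))) {
    s <- loci$start[i]; e <- s + template_len - 1L
    hit <- which(ann$scaffold == loci$scaffold[i] & ann$start <= e &
                   ann$end >= s)
    if (length(hit)) {
      gene[i] <- ann$gene[hit[1]]
      product[i] <- ann$product[hit[1]]
    }
  }
  dists <- numeric(0)
  for (sc in unique(loci$scaffold)) {
    st <- loci$start[loci$scaffold == sc]
    if (length(st) >= 2) {
      dd <- abs(outer(st, st, "-"))
      dists <- c(dists, dd[upper.tri(dd)])
    }
  }
  list(loci = cbind(loci, gene = gene, product = product,
                    stringsAsFactors = FALSE),
       distances = dists)
}
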