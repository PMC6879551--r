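## Distance matrices ---------------------------------------------------------

new_dist_matrix <- function(m, ids) {
  dimnames(m) <- list(ids, ids)
  diag(m) <- 0
  structure(m, class = c("dist_matrix", "matrix"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %d samples, range [%.4g, %.4g]\n", nrow(x),
              min(x), max(x)))
  invisible(x)
}

#' Bray-Curtis dissimilarity on a binary haplotype matrix
#'
#' For presence/absence data, d(i,j) = 1 - 2W/(A+B) where W is the number
#' of shared presences and A, B the presence counts of the two samples,
#' computed over the columns non-missing in both samples
#' (\code{mode = "pairwise"}, the default) or only over columns with no
#' missing value anywhere (\code{mode = "complete"}).  A pair with no
#' jointly observed presence gets d = 1 (and is counted in a message).
#'
#' @param hm a \code{hap_matrix} (or plain 0/1/NA matrix).
#' @param mode missing-data handling.
#' @return a \code{dist_matrix}.
#' @export
bray_curtis <- function(hm, mode = c("pairwise", "complete")) {
  mode <- match.arg(mode)
  m <- unclass(hm)
  if (mode == "complete") m <- m[, colSums(is.na(m)) == 0, drop = FALSE]
  p <- m; p[is.na(p)] <- 0L
  ob <- (!is.na(m)) * 1L
  W <- tcrossprod(p)
  A <- tcrossprod(p, ob)    # presences of i over columns observed in j
  B <- tcrossprod(ob, p)    # presences of j over columns observed in i
  tot <- A + B
  d <- 1 - 2 * W / tot
  empty <- tot == 0
  if (any(empty[upper.tri(empty)])) {
    message(sum(empty[upper.tri(empty)]),
            " sample pair(s) share no observed presence; d set to 1")
    d[empty] <- 1
  }
  new_dist_matrix(d, rownames(m))
}

#' Euclidean distance on a 0/1/2 genotype matrix
#'
#' Pairwise-complete columns with scale correction: squared distances over
#' the jointly observed loci are rescaled by L / L_obs so sparsely shared
#' pairs remain comparable.  \code{mode = "complete"} restricts to columns
#' with no missing value instead.  A pair with zero shared loci is an
#' error.
#'
#' @param snps a \code{snp_matrix} (or plain numeric matrix).
#' @param mode missing-data handling.
#' @return a \code{dist_matrix}.
#' @export
euclidean_genotype_distance <- function(snps, mode = c("pairwise",
                                                       "complete")) {
  mode <- match.arg(mode)
  g <- unclass(snps)
  storage.mode(g) <- "double"
  if (mode == "complete") g <- g[, colSums(is.na(g)) == 0, drop = FALSE]
  L <- ncol(g)
  ob <- (!is.na(g)) * 1
  g0 <- g; g0[is.na(g0)] <- 0
  l_obs <- tcrossprod(ob)
  assert_that(all(l_obs[upper.tri(l_obs)] > 0),
              "sample pair with zero shared loci")
  sq <- tcrossprod(g0^2, ob) + tcrossprod(ob, g0^2) - 2 * tcrossprod(g0)
  d2 <- sq * L / l_obs
  d2[d2 < 0] <- 0
  new_dist_matrix(sqrt(d2), rownames(g))
}

#' Principal coordinates analysis (metric MDS)
#'
#' Gower double-centering of -D^2/2 followed by eigendecomposition.
#' Coordinates are returned for positive eigenvalues only (eigenvector
#' scaled by sqrt(eigenvalue)); negative eigenvalues are reported
#' unmodified.  Axis signs are fixed so each axis's largest-magnitude
#' coordinate is positive.
#'
#' @param D a \code{dist_matrix} (or symmetric matrix with zero diagonal).
#' @param eps eigenvalues within \code{eps * max(|lambda|)} of zero are
#'   treated as null.
#' @return list of class \code{pcoa_result}: \code{$coordinates} (samples x
#'   positive axes), \code{$eigenvalues} (all, descending),
#'   \code{$prop_var} (share of the positive eigenvalue total).
#' @export
pcoa <- function(D, eps = 1e-9) {
  D <- as.matrix(D)
  n <- nrow(D)
  assert_that(n >= 3, "pcoa needs at least 3 samples")
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  tol <- eps * max(abs(e$values), 1e-300)
  pos <- which(e$values > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  ## deterministic axis orientation
  for (j in seq_len(ncol(coords))) {
    if (coords[which.max(abs(coords[, j])), j] < 0)
      coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(rownames(D), sprintf("PCo%d", seq_along(pos)))
  structure(list(coordinates = coords, eigenvalues = e$values,
                 prop_var = e$values[pos] / sum(e$values[pos]),
                 trace = sum(diag(B))),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d samples, %d positive axes; axis 1-2: %.1f%% + %.1f%%\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * x$prop_var[1], 100 * (x$prop_var[2] %||% NA)))
  invisible(x)
}

## Shared PERMANOVA machinery ------------------------------------------------

## SS_total and SS_within for squared distances and integer group codes.
permanova_ss <- function(D2, groups) {
  n <- nrow(D2)
  ss_total <- sum(D2) / (2 * n)   # diagonal is zero
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ss_within <- ss_within + sum(D2[idx, idx]) / (2 * length(idx))
  }
  c(total = ss_total, within = ss_within)
}

permanova_f <- function(D2, groups, n, g) {
  ss <- permanova_ss(D2, groups)
  ss_among <- ss["total"] - ss["within"]
  unname((ss_among / (g - 1)) / (ss["within"] / (n - g)))
}

## All permutations of 1..n (n <= 8) as a matrix, one permutation per row.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(rep(k, nrow(sub)),
                   sub + (sub >= k))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the sum of squared interpoint distances among and within
#' groups: SS_total = sum of d^2 / n over all pairs, SS_within the
#' group-size-weighted analogue, pseudo-F =
#' (SS_among/(g-1)) / (SS_within/(n-g)).  The p-value is obtained by free
#' permutation of sample labels with the (1 + count) / (1 + N) estimator,
#' or by complete enumeration of all n! label permutations when
#' \code{exact = TRUE} (n <= 8).
#'
#' @param D a \code{dist_matrix}.
#' @param groups factor/character of group labels (>= 2 groups, each with
#'   >= 2 members).
#' @param n_permutations number of random permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @param exact enumerate all permutations instead (n <= 8).
#' @return list of class \code{permanova_result} with \code{df_among},
#'   \code{df_residual}, \code{ss_among}, \code{ss_residual},
#'   \code{ss_total}, \code{f}, \code{r2}, \code{p}, \code{n_permutations}.
#' @export
permanova <- function(D, groups, n_permutations = 999, seed = NULL,
                      exact = FALSE) {
  D <- as.matrix(D)
  n <- nrow(D)
  groups <- as.character(groups)
  assert_that(length(groups) == n, "groups must match D")
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop("singleton group(s): ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  g <- length(sizes)
  assert_that(g >= 2, "need at least two groups")
  D2 <- D^2
  ss <- permanova_ss(D2, groups)
  ss_among <- unname(ss["total"] - ss["within"])
  f_obs <- (ss_among / (g - 1)) / (unname(ss["within"]) / (n - g))
  if (exact) {
    assert_that(n <= 8, "exact enumeration limited to n <= 8")
    perms <- all_permutations(n)
    f_perm <- vapply(seq_len(nrow(perms)), function(i)
      permanova_f(D2, groups[perms[i, ]], n, g), numeric(1))
    p <- mean(f_perm >= f_obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    f_perm <- with_seed(seed, vapply(seq_len(n_permutations), function(i)
      permanova_f(D2, groups[sample.int(n)], n, g), numeric(1)))
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_permutations)
    n_used <- n_permutations
  }
  structure(list(df_among = g - 1L, df_residual = n - g,
                 ss_among = ss_among, ss_residual = unname(ss["within"]),
                 ss_total = unname(ss["total"]), f = f_obs,
                 r2 = ss_among / unname(ss["total"]), p = p,
                 n_permutations = n_used, exact = exact),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA (free label permutation)\n")
  cat(sprintf("          DF        SS        F        R2        P\n"))
  cat(sprintf("among   %4d  %8.4g  %7.4g  %8.4g  %7.4g\n", x$df_among,
              x$ss_among, x$f, x$r2, x$p))
  cat(sprintf("within  %4d  %8.4g\n", x$df_residual, x$ss_residual))
  invisible(x)
}

#' Pairwise PERMANOVA between all group pairs
#'
#' One PERMANOVA per unordered pair of groups on the extracted sub-matrix,
#' with multiplicity correction of the p-values (Bonferroni by default).
#'
#' @inheritParams permanova
#' @param correction p-value adjustment: "bonferroni" (default), "holm" or
#'   "BH".
#' @return data.frame: group1, group2, df_among, ss_among, f, r2, p,
#'   p_adjusted.
#' @export
pairwise_permanova <- function(D, groups, n_permutations = 999,
                               correction = c("bonferroni", "holm", "BH"),
                               seed = NULL) {
  correction <- match.arg(correction)
  D <- as.matrix(D)
  groups <- as.character(groups)
  gl <- sort(unique(groups))
  pairs <- combn(gl, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    sel <- groups %in% pairs[, k]
    r <- permanova(D[sel, sel, drop = FALSE], groups[sel], n_permutations,
                   seed = child_seed(seed, paste(pairs[, k],
                                                 collapse = "_")))
    data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
               df_among = r$df_among, ss_among = r$ss_among, f = r$f,
               r2 = r$r2, p = r$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p, method = correction)
  out
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower-triangle vectors; one-sided p-value
#' (statistic >= observed) under simultaneous row/column permutation of the
#' second matrix, with complete 120-permutation enumeration available for
#' n = 5 scale fixtures via \code{exact = TRUE} (n <= 8).
#'
#' @param D1,D2 distance matrices over the same samples in the same order.
#' @param n_permutations number of permutations (default 1000).
#' @param seed integer seed.
#' @param exact enumerate all n! permutations.
#' @return list of class \code{mantel_result}: \code{$r}, \code{$p},
#'   \code{$n_permutations}.
#' @export
mantel <- function(D1, D2, n_permutations = 1000, seed = NULL,
                   exact = FALSE) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  assert_that(all(dim(D1) == dim(D2)), "matrices must be conformable")
  lt <- lower.tri(D1)
  v1 <- D1[lt]
  assert_that(sd(v1) > 0 && sd(D2[lt]) > 0,
              "constant distance vector; r undefined")
  r_obs <- cor(v1, D2[lt])
  n <- nrow(D1)
  stat <- function(perm) cor(v1, D2[perm, perm][lt])
  if (exact) {
    assert_that(n <= 8, "exact enumeration limited to n <= 8")
    perms <- all_permutations(n)
    r_perm <- vapply(seq_len(nrow(perms)), function(i) stat(perms[i, ]),
                     numeric(1))
    p <- mean(r_perm >= r_obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    r_perm <- with_seed(seed, vapply(seq_len(n_permutations), function(i)
      stat(sample.int(n)), numeric(1)))
    p <- (1 + sum(r_perm >= r_obs - 1e-12)) / (1 + n_permutations)
    n_used <- n_permutations
  }
  structure(list(r = r_obs, p = p, n_permutations = n_used),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4g, p = %.4g (%d permutations)\n",
              x$r, x$p, x$n_permutations))
  invisible(x)
}

## Weir & Cockerham (1984) variance components for one locus, two or more
## populations.  geno: 0/1/2/NA dosage vector; pop: integer codes.
wc_components <- function(geno, pop) {
  ok <- !is.na(geno)
  geno <- geno[ok]; pop <- pop[ok]
  tab <- table(pop)
  if (length(tab) < 2 || any(tab < 1)) return(c(a = NA, b = NA, c = NA))
  r <- length(tab)
  n_i <- as.numeric(tab)
  nbar <- mean(n_i)
  if (nbar <= 1) return(c(a = NA, b = NA, c = NA))
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  p_i <- tapply(geno, pop, mean) / 2
  h_i <- tapply(geno == 1, pop, mean)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) /
       (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

## Multi-locus Weir-Cockerham theta for a genotype matrix and two-level (or
## multi-level) population factor.  Monomorphic loci contribute a zero
## denominator and are effectively excluded.
wc_theta <- function(geno, pop) {
  comp <- vapply(seq_len(ncol(geno)), function(j)
    wc_components(geno[, j], pop), numeric(3))
  num <- sum(comp[1, ], na.rm = TRUE)
  den <- sum(colSums(comp), na.rm = TRUE)
  if (den == 0) return(NA_real_)
  num / den
}

#' Pairwise Weir-Cockerham F_ST with permutation tests
#'
#' Multi-locus theta from the 1984 variance components (a, b, c summed
#' over loci; loci with zero total variance drop out of both sums).
#' Significance is assessed by permuting individuals across the population
#' pair; p-values are Bonferroni-corrected across pairs.
#'
#' @param snps a \code{snp_matrix} (0/1/2/NA).
#' @param populations named or positional character vector of population
#'   labels (one per row of \code{snps}).
#' @param n_permutations permutations per pair (default 1000).
#' @param seed integer seed.
#' @return data.frame of class \code{fst_result}: pop1, pop2, theta, p,
#'   p_adjusted.
#' @export
weir_cockerham_fst <- function(snps, populations, n_permutations = 1000,
                               seed = NULL) {
  g <- unclass(snps)
  populations <- as.character(populations)
  assert_that(length(populations) == nrow(g),
              "populations must match rows of snps")
  pl <- sort(unique(populations))
  pairs <- combn(pl, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    sel <- populations %in% pairs[, k]
    gg <- g[sel, , drop = FALSE]
    pp <- match(populations[sel], pairs[, k])
    th <- wc_theta(gg, pp)
    th_perm <- with_seed(
      child_seed(seed, paste(pairs[, k], collapse = "_")),
      vapply(seq_len(n_permutations), function(i)
        wc_theta(gg, pp[sample.int(length(pp))]), numeric(1)))
    p <- (1 + sum(th_perm >= th - 1e-12, na.rm = TRUE)) /
      (1 + n_permutations)
    data.frame(pop1 = pairs[1, k], pop2 = pairs[2, k], theta = th, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p * nrow(out))
  class(out) <- c("fst_result", "data.frame")
  out
}

#' Minimum strain count per light organ
#'
#' The within-light-organ diversity floor: the maximum, across loci, of the
#' number of haplotypes present in the sample.  Loci missing for a sample
#' are ignored; samples with every locus missing are excluded with a
#' warning.
#'
#' @param hm a \code{hap_matrix} (typically the stage-2 "all datasets"
#'   matrix, before the per-dataset 15 percent filters).
#' @param meta optional sample sheet; when given, \code{length_mm} is
#'   attached for the length regression.
#' @return data.frame: sample, strain_count, and (if available) length_mm.
#' @export
strain_count <- function(hm, meta = NULL) {
  m <- unclass(hm)
  key <- column_key(hm)
  loci <- unique(key$locus)
  counts <- matrix(NA_integer_, nrow(m), length(loci))
  for (i in seq_along(loci)) {
    sub <- m[, key$locus == loci[i], drop = FALSE]
    n_pres <- rowSums(sub == 1L, na.rm = TRUE)
    n_pres[rowSums(!is.na(sub)) == 0] <- NA_integer_
    counts[, i] <- n_pres
  }
  all_missing <- rowSums(!is.na(counts)) == 0
  if (any(all_missing)) {
    warning(sum(all_missing), " sample(s) with all loci missing excluded")
  }
  sc <- apply(counts, 1, function(x)
    if (all(is.na(x))) NA_integer_ else as.integer(max(x, na.rm = TRUE)))
  out <- data.frame(sample = rownames(m), strain_count = sc,
                    stringsAsFactors = FALSE)
  out <- out[!all_missing, , drop = FALSE]
  if (!is.null(meta)) {
    out$length_mm <- meta$length_mm[match(out$sample, meta$sample)]
  }
  out
}

#' OLS regression of strain count on host standard length
#'
#' Ordinary least squares of the per-organ strain count on fish standard
#' length, with the F test of the slope and adjusted R-squared -- the
#' "does symbiont diversity grow with host age" check.
#'
#' @param counts data.frame from [strain_count()] with \code{strain_count}
#'   and \code{length_mm}.
#' @return list of class \code{lenreg_result}: \code{$f}, \code{$df}
#'   (c(1, n-2)), \code{$r2_adj}, \code{$p}, \code{$slope},
#'   \code{$intercept}.
#' @export
length_regression <- function(counts) {
  x <- counts$length_mm
  y <- counts$strain_count
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  assert_that(n >= 3, "need at least 3 observations")
  assert_that(sd(x) > 0, "constant predictor")
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  fit <- intercept + slope * x
  sse <- sum((y - fit)^2)
  sst <- sum((y - mean(y))^2)
  ssr <- sst - sse
  f <- (ssr / 1) / (sse / (n - 2))
  r2 <- ssr / sst
  structure(list(f = f, df = c(1L, n - 2L),
                 r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2),
                 p = pf(f, 1, n - 2, lower.tail = FALSE),
                 slope = slope, intercept = intercept),
            class = "lenreg_result")
}

#' @export
print.lenreg_result <- function(x, ...) {
  cat(sprintf("OLS: F_%d,%d = %.4g, adj. R2 = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$f, x$r2_adj, x$p))
  invisible(x)
}

#' Write a distance matrix as a square TSV
#'
#' @param D a \code{dist_matrix}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_dist_matrix <- function(D, path) {
  d <- as.data.frame(as.matrix(D))
  d <- cbind(sample = rownames(d), d)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
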