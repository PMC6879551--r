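## Independent oracles, deliberately written as naive per-pair / per-locus
## loops so they share no code path with the package implementations.

## Bray-Curtis by set arithmetic over jointly observed columns.
oracle_bray <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ok <- !is.na(m[i, ]) & !is.na(m[j, ])
    a <- sum(m[i, ok] == 1)
    b <- sum(m[j, ok] == 1)
    w <- sum(m[i, ok] == 1 & m[j, ok] == 1)
    d[i, j] <- if (a + b == 0) 1 else 1 - 2 * w / (a + b)
  }
  d
}

## Euclidean with pairwise-complete rescaling.
oracle_euclid <- function(g) {
  n <- nrow(g); L <- ncol(g)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ok <- !is.na(g[i, ]) & !is.na(g[j, ])
    d[i, j] <- sqrt(sum((g[i, ok] - g[j, ok])^2) * L / sum(ok))
  }
  d
}

## PERMANOVA pseudo-F via the Gower-centered inner-product route (a
## different formulation from the package's pairwise-sum route).
oracle_permanova_f <- function(D, groups) {
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  X <- stats::model.matrix(~ factor(groups))
  H <- X %*% solve(crossprod(X)) %*% t(X)
  g <- length(unique(groups))
  ss_among <- sum(diag(H %*% G %*% H))
  ss_res <- sum(diag((diag(n) - H) %*% G %*% (diag(n) - H)))
  (ss_among / (g - 1)) / (ss_res / (n - g))
}

## Exhaustive PERMANOVA p over all n! label permutations.
oracle_permanova_exact_p <- function(D, groups) {
  perms <- symrad:::all_permutations(nrow(D))
  f_obs <- oracle_permanova_f(D, groups)
  f_perm <- vapply(seq_len(nrow(perms)), function(i)
    oracle_permanova_f(D, groups[perms[i, ]]), numeric(1))
  mean(f_perm >= f_obs - 1e-12)
}

## Exhaustive Mantel p over all n! simultaneous permutations of D2.
oracle_mantel_exact <- function(D1, D2) {
  lt <- lower.tri(D1)
  r_obs <- cor(D1[lt], D2[lt])
  perms <- symrad:::all_permutations(nrow(D1))
  r_perm <- vapply(seq_len(nrow(perms)), function(i) {
    p <- perms[i, ]
    cor(D1[lt], D2[p, p][lt])
  }, numeric(1))
  list(r = r_obs, p = mean(r_perm >= r_obs - 1e-12))
}

## Weir & Cockerham (1984) theta, scalar arithmetic straight from the
## published variance-component formulas, one locus at a time.
oracle_wc_theta <- function(geno, pop) {
  num <- den <- 0
  for (l in seq_len(ncol(geno))) {
    g <- geno[, l]; p <- pop[!is.na(g)]; g <- g[!is.na(g)]
    pops <- unique(p)
    r <- length(pops)
    if (r < 2) next
    n_i <- sapply(pops, function(x) sum(p == x))
    if (any(n_i < 1)) next
    nbar <- mean(n_i)
    if (nbar <= 1) next
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    p_i <- sapply(pops, function(x) mean(g[p == x]) / 2)
    h_i <- sapply(pops, function(x) mean(g[p == x] == 1))
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- (nbar / nc) * (s2 - 1 / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
      (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

## Closed-form simple OLS F statistic.
oracle_ols <- function(x, y) {
  n <- length(x)
  bx <- cov(x, y) / var(x)
  b0 <- mean(y) - bx * mean(x)
  sse <- sum((y - b0 - bx * x)^2)
  sst <- sum((y - mean(y))^2)
  f <- (sst - sse) / (sse / (n - 2))
  r2 <- 1 - sse / sst
  list(f = f, r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2),
       p = pf(f, 1, n - 2, lower.tail = FALSE))
}

## Brute-force all-positions Hamming-scan aligner (both strands).
oracle_align <- function(read, scaffolds, max_mm = 4) {
  hits <- data.frame(scaffold = character(0), pos = integer(0),
                     strand = character(0), mm = integer(0))
  for (strand in c("+", "-")) {
    q <- if (strand == "+") read else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
    qv <- utf8ToInt(q)
    for (sc in names(scaffolds)) {
      s <- scaffolds[[sc]]
      for (p in seq_len(nchar(s) - nchar(q) + 1L)) {
        mm <- sum(utf8ToInt(substr(s, p, p + nchar(q) - 1L)) != qv)
        if (mm <= max_mm) {
          hits <- rbind(hits, data.frame(scaffold = sc, pos = p,
                                         strand = strand, mm = mm))
        }
      }
    }
  }
  hits
}

## Brute-force filter-cascade stage counts by direct rule application on a
## plain locus-observation representation.
oracle_cascade <- function(m, key, meta, p_all = 0.7, p_pop = 0.5,
                           mx = 0.15) {
  loci <- unique(key$locus)
  obs <- sapply(loci, function(l) {
    cols <- which(key$locus == l)
    apply(!is.na(m[, cols, drop = FALSE]), 1, any)
  })
  keep1 <- loci[colMeans(obs) >= p_all]
  pop <- paste(meta$location, meta$year, sep = "_")
  keep2 <- keep1[sapply(keep1, function(l) {
    all(tapply(obs[, l], pop, mean) >= p_pop)
  })]
  datasets <- list()
  for (y in sort(unique(meta$year))) {
    if (length(unique(meta$location[meta$year == y])) >= 2)
      datasets[[as.character(y)]] <- which(meta$year == y)
  }
  for (loc in unique(meta$location)) {
    if (length(unique(meta$year[meta$location == loc])) >= 3)
      datasets[[loc]] <- which(meta$location == loc)
  }
  out <- list()
  for (d in names(datasets)) {
    rows <- datasets[[d]]
    ob <- obs[rows, keep2, drop = FALSE]
    keep_ind <- rowMeans(!ob) <= mx
    ob <- ob[keep_ind, , drop = FALSE]
    keep_loc <- colMeans(!ob) <= mx
    out[[d]] <- c(n_samples = sum(keep_ind), n_loci = sum(keep_loc))
  }
  list(stage1 = length(keep1), stage2 = length(keep2), datasets = out)
}

## Small deterministic fixtures ---------------------------------------------

tiny_reference <- function(seed = 42, n_scaffolds = 2, len = 3000,
                           cds_fraction = 0.5) {
  make_reference(n_scaffolds, len, cds_fraction, seed = seed)
}

## A small, fast end-to-end simulation used by several test files.
tiny_sim <- function(seed = 11, n_per_site = 6, error_rate = 0.001,
                     lambda_sym = 15, lambda_host = 16, ...) {
  simulate_ddrad(design = structured_design(n_per_site = n_per_site),
                 sym_scaffolds = 4, sym_scaffold_len = 15000,
                 host_scaffolds = 2, host_scaffold_len = 30000,
                 lambda_sym = lambda_sym, lambda_host = lambda_host,
                 error_rate = error_rate, seed = seed, ...)
}
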