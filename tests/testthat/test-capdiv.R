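## A reference fixture with hand-placed CDS features for annotation tests:
## one forward gene, one reverse gene, with known codons.
anno_fixture <- function() {
  ## scaffold: 12 bp pad | fwd CDS (24 bp) | 30 bp gap | rev CDS (24 bp) | pad
  pad1 <- "ACACACACACAC"
  fwd <- "ATGGAACTGTGGAAACCCGGGTAA"  # M E L W K P G *
  gap <- strrep("T", 30)
  rev_coding <- "ATGTTTAGCGCAACCGATCACTAA"  # coding strand of the - gene
  rev_genomic <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(rev_coding)))
  pad2 <- "GTGTGTGTGTGT"
  seqs <- c(sc = paste0(pad1, fwd, gap, rev_genomic, pad2))
  ann <- data.frame(
    scaffold = "sc",
    start = c(13L, 13L + 24L + 30L),
    end = c(36L, 13L + 24L + 30L + 23L),
    strand = c("+", "-"),
    gene = c("fwdA", "revB"),
    product = c("forward test protein", "reverse test protein"),
    stringsAsFactors = FALSE)
  structure(list(scaffolds = seqs, annotations = ann),
            class = "rad_reference")
}

test_that("coding variants are classified by codon translation", {
  ref <- anno_fixture()
  ## GAA -> GAG (Glu -> Glu): synonymous, LOW.  GAA is codon 2 at 16-18.
  v <- data.frame(scaffold = "sc", pos = 18L, ref = "A", alt = "G")
  r <- symrad:::classify_variants(v, ref)
  expect_equal(r$type, "synonymous")
  expect_equal(r$effect, "LOW")
  expect_equal(r$gene, "fwdA")
  ## TGG -> TGA (Trp -> stop): stop-gained, HIGH.  TGG is codon 4 at 22-24.
  v2 <- data.frame(scaffold = "sc", pos = 24L, ref = "G", alt = "A")
  r2 <- symrad:::classify_variants(v2, ref)
  expect_equal(r2$type, "stop-gained")
  expect_equal(r2$effect, "HIGH")
  ## CTG -> CCG (Leu -> Pro): non-synonymous, MODERATE.  Codon 3, pos 20.
  v3 <- data.frame(scaffold = "sc", pos = 20L, ref = "T", alt = "C")
  r3 <- symrad:::classify_variants(v3, ref)
  expect_equal(r3$type, "non-synonymous")
  expect_equal(r3$effect, "MODERATE")
})

test_that("reverse-strand codons translate strand-aware", {
  ref <- anno_fixture()
  a <- ref$annotations[2, ]
  ## second codon of revB is TTT (Phe); its genomic position is end-3..end-5.
  ## mutate the middle T: coding TTT -> TAT (Phe -> Tyr), non-synonymous
  pos <- a$end - 4L
  genomic_ref <- substr(ref$scaffolds[["sc"]], pos, pos)
  expect_equal(genomic_ref, "A")  # complement of coding T
  v <- data.frame(scaffold = "sc", pos = pos, ref = genomic_ref, alt = "T")
  r <- symrad:::classify_variants(v, ref)
  expect_equal(r$type, "non-synonymous")
  expect_equal(r$gene, "revB")
  ## coding TCA would arise from AGC codon 3... instead check synonymous:
  ## third codon AGC (Ser) -> AGT (Ser) via genomic position of its last base
  pos3 <- a$end - 8L   # codon 3 last base (coding orientation)
  v2 <- data.frame(scaffold = "sc", pos = pos3,
                   ref = substr(ref$scaffolds[["sc"]], pos3, pos3),
                   alt = "A")  # genomic A = coding T
  r2 <- symrad:::classify_variants(v2, ref)
  expect_equal(r2$type, "synonymous")
  expect_equal(r2$effect, "LOW")
})

test_that("upstream and intergenic variants get MODIFIER / none", {
  ref <- anno_fixture()
  ## position 5 is 8 bp upstream of the + CDS start (13)
  v <- data.frame(scaffold = "sc", pos = 5L, ref = "A", alt = "G")
  r <- symrad:::classify_variants(v, ref)
  expect_equal(r$type, "upstream")
  expect_equal(r$effect, "MODIFIER")
  expect_equal(r$gene, "fwdA")
  ## just past the - CDS end (downstream in genomic coords = upstream of the
  ## - gene) is upstream of revB
  a <- ref$annotations[2, ]
  v2 <- data.frame(scaffold = "sc", pos = a$end + 3L, ref = "G", alt = "A")
  r2 <- symrad:::classify_variants(v2, ref)
  expect_equal(r2$type, "upstream")
  expect_equal(r2$gene, "revB")
  ## with a tiny upstream window the same variant is intergenic
  r3 <- symrad:::classify_variants(v2, ref, upstream_window = 1)
  expect_equal(r3$type, "intergenic")
  expect_equal(r3$effect, "none")
})

test_that("annotate_variant summarizes haplotypes and handles consensus", {
  ref <- anno_fixture()
  anchor <- list(scaffold = "sc", start = 13L, strand = "+")
  region <- substr(ref$scaffolds[["sc"]], 13, 13 + 23)
  ## consensus haplotype
  r0 <- annotate_variant(region, anchor, ref)
  expect_equal(r0$type, "consensus")
  expect_equal(r0$effect, "none")
  expect_equal(nrow(r0$calls), 0)
  ## one synonymous + one stop-gained: summary is the most severe (HIGH)
  hap <- region
  substr(hap, 6, 6) <- "G"    # GAA -> GAG (pos 18): LOW
  substr(hap, 12, 12) <- "A"  # TGG -> TGA (pos 24): HIGH
  r1 <- annotate_variant(hap, anchor, ref)
  expect_equal(nrow(r1$calls), 2)
  expect_setequal(r1$calls$effect, c("LOW", "HIGH"))
  expect_equal(r1$effect, "HIGH")
  expect_equal(r1$type, "stop-gained")
  ## a reverse-orientation locus anchor reverse-complements before mapping
  anchor_rc <- list(scaffold = "sc", start = 13L, strand = "-")
  hap_rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(hap)))
  r2 <- annotate_variant(hap_rc, anchor_rc, ref)
  expect_equal(sort(r2$calls$pos), sort(r1$calls$pos))
  expect_equal(r2$effect, "HIGH")
})

test_that("planted simulation variants annotate with zero misclassification", {
  ref <- make_reference(4, 10000, 0.6, seed = 17)
  pools <- simulate_strain_pools(ref, 2, 1, 4, theta_w = 0.004,
                                 theta_b = 0.002, seed = 18)
  v <- pools$variants
  ## Table-3-style mapping holds for every planted variant
  expect_true(all(v$effect[v$type == "synonymous"] == "LOW"))
  expect_true(all(v$effect[v$type == "non-synonymous"] == "MODERATE"))
  expect_true(all(v$effect[v$type == "stop-gained"] == "HIGH"))
  expect_true(all(v$effect[v$type == "upstream"] == "MODIFIER"))
  expect_gt(sum(v$type == "synonymous"), 0)
  expect_gt(sum(v$type == "non-synonymous"), 0)
  ## independent re-derivation via Biostrings translation
  cds <- v[v$type %in% c("synonymous", "non-synonymous", "stop-gained"), ]
  ann <- ref$annotations
  for (i in sample(nrow(cds), min(60, nrow(cds)))) {
    f <- ann[ann$scaffold == cds$scaffold[i] & ann$start <= cds$pos[i] &
               ann$end >= cds$pos[i], ][1, ]
    dna <- substr(ref$scaffolds[[cds$scaffold[i]]], f$start, f$end)
    mut <- dna
    substr(mut, cds$pos[i] - f$start + 1, cds$pos[i] - f$start + 1) <-
      cds$alt[i]
    if (f$strand == "-") {
      dna <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(dna)))
      mut <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(mut)))
    }
    ## translate only the affected codon (the toy genome's CDS intervals
    ## are annotation-only uniform DNA, so whole-ORF translation is
    ## meaningless); coding-orientation codon index from the variant
    off <- if (f$strand == "+") cds$pos[i] - f$start else f$end - cds$pos[i]
    ci <- off %/% 3
    old_codon <- substr(dna, 3 * ci + 1, 3 * ci + 3)
    new_codon <- substr(mut, 3 * ci + 1, 3 * ci + 3)
    aa_old <- as.character(Biostrings::translate(
      Biostrings::DNAString(old_codon), no.init.codon = TRUE))
    aa_new <- as.character(Biostrings::translate(
      Biostrings::DNAString(new_codon), no.init.codon = TRUE))
    expected <- if (aa_old == aa_new) "synonymous"
                else if (aa_new == "*") "stop-gained" else "non-synonymous"
    expect_equal(cds$type[i], expected,
                 label = paste("variant", cds$variant_id[i]))
  }
})

test_that("cap constrains ordination by the factor", {
  set.seed(19)
  m <- matrix(rbinom(30 * 60, 1, 0.35), 30, 60,
              dimnames = list(sprintf("s%d", 1:30), sprintf("h%d", 1:60)))
  ## plant a two-group split on columns 1:10
  g <- rep(c("a", "b"), each = 15)
  m[g == "a", 1:10] <- 1L
  m[g == "b", 1:10] <- 0L
  D <- bray_curtis(m)
  cr <- cap(D, m, g, n_permutations = 199, seed = 4)
  expect_equal(length(cr$eigenvalues), 1)   # 2 levels -> 1 axis
  expect_lt(cr$p, 0.05)
  ## the constrained axis reproduces the separation seen on PCoA axis 1
  p1 <- pcoa(D)$coordinates[, 1]
  expect_gt(abs(cor(cr$sample_scores[, 1], p1)), 0.99)
  ## scores are column-centered
  expect_lt(max(abs(colMeans(cr$sample_scores))), 1e-9)
  ## rank bound: 4 groups -> at most 3 axes
  g4 <- rep(c("a", "b", "c", "d"), length.out = 30)
  expect_lte(length(cap(D, m, g4)$eigenvalues), 3)
  ## single-level factor errors
  expect_error(cap(D, m, rep("a", 30)), "single level")
  ## group-diagnostic haplotypes sit at the extremes of the hap scores
  hs <- cr$hap_scores[, 1]
  planted <- rank(-abs(hs))[1:10]
  expect_true(all(planted <= 12))
})

test_that("full-rank constraint reduces CAP to PCoA", {
  set.seed(20)
  m <- matrix(rbinom(10 * 40, 1, 0.4), 10, 40,
              dimnames = list(sprintf("s%d", 1:10), NULL))
  D <- bray_curtis(m)
  cr <- cap(D, m, letters[1:10])
  pc <- pcoa(D)
  expect_lt(max(abs(as.matrix(dist(cr$sample_scores)) -
                      as.matrix(dist(pc$coordinates)))), 1e-6)
})

test_that("cap agrees with vegan::capscale on the shared subspace", {
  skip_if_not_installed("vegan")
  set.seed(21)
  m <- matrix(rbinom(24 * 50, 1, 0.4), 24, 50,
              dimnames = list(sprintf("s%d", 1:24), NULL))
  g <- rep(c("a", "b", "c"), each = 8)
  m[g == "a", 1:6] <- 1L
  D <- bray_curtis(m)
  cr <- cap(D, m, g)
  cs <- vegan::capscale(stats::as.dist(unclass(D)) ~ factor(g))
  wa <- vegan::scores(cs, display = "wa", choices = 1:2)
  expect_gt(abs(cor(cr$sample_scores[, 1], wa[, 1])), 0.999)
  expect_gt(abs(cor(cr$sample_scores[, 2], wa[, 2])), 0.999)
})

test_that("outlier selection flags planted extremes with gap monotonicity", {
  set.seed(22)
  n <- 300
  scores <- matrix(rnorm(2 * n, sd = 0.05), n, 2,
                   dimnames = list(sprintf("h%d", 1:n), c("CAP1", "CAP2")))
  q99 <- quantile(scores[, 1], 0.99)
  scores["h1", 1] <- 10 * q99
  fake <- structure(list(hap_scores = scores), class = "cap_result")
  out <- select_outlier_haplotypes(fake, gap_factor = 2)
  expect_true("h1" %in% out$column[out$stage2])
  ## only the planted extreme survives stage 2 on axis 1
  expect_equal(out$column[out$stage2 & out$axis == 1], "h1")
  ## pct_high = 1 empties the high tail
  out2 <- select_outlier_haplotypes(fake, pct_high = 1, pct_low = 0)
  expect_equal(nrow(out2[out2$score > 0 & out2$axis == 1, ]), 0)
  ## raising gap_factor never adds outliers
  sizes <- vapply(c(1, 2, 4, 8), function(gf)
    sum(select_outlier_haplotypes(fake, gap_factor = gf)$stage2),
    numeric(1))
  expect_true(all(diff(sizes) <= 0))
  ## < 100 haplotypes: rank-based fallback with warning
  small <- structure(list(hap_scores = scores[1:50, ]),
                     class = "cap_result")
  ## one warning per axis
  expect_warning(expect_warning(out3 <- select_outlier_haplotypes(small),
                                "fewer than 100"), "fewer than 100")
  expect_true("h1" %in% out3$column)
})

test_that("locus_genome_map reports feature context and spacing", {
  ref <- make_reference(2, 20000, 0.6, seed = 23)
  loci <- data.frame(locus = c("L1", "L2", "L3"),
                     scaffold = c("scaffold_1", "scaffold_1", "scaffold_2"),
                     start = c(100L, 600L, 50L),
                     strand = "+", stringsAsFactors = FALSE)
  catg <- symrad:::new_rad_catalog(
    loci, data.frame(locus = character(0), sample = character(0),
                     hap_seq = character(0), depth = integer(0)),
    "reference")
  lm_ <- locus_genome_map(catg, ref)
  expect_equal(lm_$distances, 500)
  ## k loci on one scaffold -> k(k-1)/2 distances
  loci5 <- data.frame(locus = paste0("L", 1:5), scaffold = "scaffold_1",
                      start = c(10L, 500L, 2000L, 9000L, 15000L),
                      strand = "+", stringsAsFactors = FALSE)
  catg5 <- symrad:::new_rad_catalog(
    loci5, catg$calls, "reference")
  expect_equal(length(locus_genome_map(catg5, ref)$distances), 10)
  ## simulated digest: every locus anchor coincides with a fragment
  ## template start (the EcoRI-proximal end)
  sim <- tiny_sim(seed = 131, n_per_site = 2, error_rate = 0)
  dm <- demultiplex(sim$reads, sim$sheet)
  pt <- partition_reads(dm$reads, sim$ref)
  rc <- build_reference_catalog(pt$symbiont)
  win <- symrad:::fragment_template_window(sim$frags, sim$template_len)
  expect_true(all(paste(rc$loci$scaffold, rc$loci$start) %in%
                    paste(win$scaffold, win$start)))
})
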