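mk_bin <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(id = paste0("r", seq_len(r$n), "_", r$sample, "_", r$seq),
               sample = r$sample, scaffold = r$sc %||% "sc1",
               pos = r$pos %||% 100L, strand = r$strand %||% "+",
               seq = r$seq, stringsAsFactors = FALSE)[rep(1, r$n), ]
  }))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("reference catalog applies the min stack depth rule", {
  bin <- rbind(
    mk_bin(list(sample = "s1", seq = "AAA", n = 5)),
    mk_bin(list(sample = "s1", seq = "AAT", n = 2)),
    mk_bin(list(sample = "s2", seq = "AAT", n = 3)))
  catg <- build_reference_catalog(bin, min_stack_depth = 3)
  expect_equal(nrow(catg$loci), 1)
  calls <- catg$calls
  expect_equal(calls$hap_seq[calls$sample == "s1"], "AAA")
  expect_equal(calls$depth[calls$sample == "s1"], 5)
  expect_equal(calls$hap_seq[calls$sample == "s2"], "AAT")
  ## grouping by anchor equals brute-force grouping on a simulated bin
  sim <- tiny_sim(seed = 91, n_per_site = 2, error_rate = 0)
  dm <- demultiplex(sim$reads, sim$sheet)
  pt <- partition_reads(dm$reads, sim$ref)
  cat2 <- build_reference_catalog(pt$symbiont)
  key_pkg <- length(unique(paste(cat2$loci$scaffold, cat2$loci$start,
                                 cat2$loci$strand)))
  key_brute <- length(unique(paste(pt$symbiont$scaffold, pt$symbiont$pos,
                                   pt$symbiont$strand)))
  expect_equal(key_pkg, key_brute)
})

test_that("error-free catalog haplotypes equal truth strain alleles", {
  sim <- tiny_sim(seed = 101, n_per_site = 3, error_rate = 0,
                  lambda_sym = 40)
  dm <- demultiplex(sim$reads, sim$sheet)
  pt <- partition_reads(dm$reads, sim$ref)
  catg <- build_reference_catalog(pt$symbiont)
  tpl <- symrad:::build_symbiont_templates(sim$ref, sim$pools, sim$frags,
                                           sim$template_len)
  ## every called haplotype is a true strain template at that fragment
  win <- symrad:::fragment_template_window(sim$frags, sim$template_len)
  frag_of_locus <- win$frag_id[match(
    paste(catg$loci$scaffold, catg$loci$start),
    paste(win$scaffold, win$start))]
  for (i in seq_len(nrow(catg$loci))) {
    fr <- frag_of_locus[i]
    if (is.na(fr)) next
    truth_haps <- unique(tpl$seq[tpl$frag_id == fr])
    called <- catg$calls$hap_seq[catg$calls$locus == catg$loci$locus[i]]
    expect_true(all(called %in% truth_haps))
  }
})

test_that("haplotype matrix respects depth thresholds and missingness", {
  calls <- data.frame(
    locus = c("L1", "L1", "L1", "L2"),
    sample = c("s1", "s1", "s2", "s1"),
    hap_seq = c("AA", "AT", "AA", "GG"),
    depth = c(6L, 10L, 3L, 12L), stringsAsFactors = FALSE)
  catg <- symrad:::new_rad_catalog(
    data.frame(locus = c("L1", "L2")), calls, "reference")
  hm <- call_symbiont_haplotypes(catg, min_hap_depth = 6)
  ## depth 6 at threshold 6 is present (boundary)
  expect_equal(unclass(hm)["s1", "L1:h1"], 1L)
  ## s2's only L1 stack is below 6 -> locus missing, both columns NA
  expect_true(all(is.na(unclass(hm)["s2", c("L1:h1", "L1:h2")])))
  ## s2 never reaches L2 -> missing
  expect_true(is.na(unclass(hm)["s2", "L2:h1"]))
  ## threshold 10: haplotypes below 10 everywhere lose their column
  hm10 <- call_symbiont_haplotypes(catg, min_hap_depth = 10)
  expect_false("AA" %in% column_key(hm10)$seq)
  expect_true("AT" %in% column_key(hm10)$seq)
  ## monotonicity: presences never increase with the threshold
  for (th in c(5, 6, 8, 10, 12)) {
    hth <- call_symbiont_haplotypes(catg, min_hap_depth = th)
    if (th > 5) expect_lte(sum(unclass(hth) == 1L, na.rm = TRUE), prev)
    prev <- sum(unclass(hth) == 1L, na.rm = TRUE)
  }
  expect_warning(call_symbiont_haplotypes(catg, min_hap_depth = 99),
                 "empty")
})

test_that("de novo catalog merges within and across samples by mismatch", {
  s1 <- strrep("ACGT", 20)                       # 80 bp
  s2 <- paste0("T", substring(s1, 2))            # 1 mm from s1
  s3 <- paste0("TTT", substring(s1, 4))          # 3 mm from s1
  reads <- data.frame(
    sample = c(rep("a", 5), rep("a", 4), rep("b", 6), rep("a", 5)),
    seq = c(rep(s1, 5), rep(s2, 4), rep(s1, 6), rep(s3, 5)),
    stringsAsFactors = FALSE)
  catg <- build_denovo_catalog(reads, max_within_mismatch = 2,
                               max_catalog_mismatch = 1, min_stack_depth = 3)
  ## s1+s2 merge within sample a (1 mm); s3 is 3 mm away -> own locus
  expect_equal(nrow(catg$loci), 2)
  ## both samples called at the shared locus
  shared <- catg$loci$locus[catg$loci$consensus == s1]
  expect_setequal(catg$calls$sample[catg$calls$locus == shared], c("a", "b"))
  ## sample a keeps two haplotypes (s1 and s2) at the shared locus
  expect_setequal(catg$calls$hap_seq[catg$calls$locus == shared &
                                       catg$calls$sample == "a"],
                  c(s1, s2))
  ## two sequences 3 apart with M = 2 stay distinct loci
  expect_equal(sort(catg$loci$consensus), sort(c(s1, s3)))
})

test_that("simulated host loci are recovered as single catalog loci", {
  sim <- tiny_sim(seed = 111, n_per_site = 3, error_rate = 0.001,
                  lambda_host = 30)
  dm <- demultiplex(sim$reads, sim$sheet)
  pt <- partition_reads(dm$reads, sim$ref)
  catg <- build_denovo_catalog(pt$host)
  truth_tpl <- unique(c(sim$host_loci$ref_template,
                        sim$host_loci$alt_template))
  ## >= 95% of truth templates appear as called haplotypes of one locus
  hit <- vapply(sim$host_loci$frag_id, function(f) {
    i <- match(f, sim$host_loci$frag_id)
    loci <- unique(catg$calls$locus[
      catg$calls$hap_seq %in% c(sim$host_loci$ref_template[i],
                                sim$host_loci$alt_template[i])])
    length(loci) == 1
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("call_host_snps picks the leftmost SNP and applies filters", {
  mkcat <- function(calls) symrad:::new_rad_catalog(
    data.frame(locus = unique(calls$locus)), calls, "denovo")
  pops <- setNames(rep(c("p1", "p2"), each = 2), c("a", "b", "c", "d"))
  ## alleles differ at column 5 only
  h1 <- "ACGTAACGT"; h2 <- "ACGTTACGT"
  calls <- expand.grid(sample = c("a", "b", "c", "d"),
                       hap_seq = c(h1, h2), stringsAsFactors = FALSE)
  calls$locus <- "L1"; calls$depth <- 10L
  snps <- call_host_snps(mkcat(calls), pops, maf_min = 0.05)
  expect_equal(attr(snps, "snp_key")$snp_col, 5)
  expect_true(all(unclass(snps) == 1L))  # everyone heterozygous
  ## monomorphic locus dropped
  mono <- calls[calls$hap_seq == h1, ]
  expect_equal(ncol(call_host_snps(mkcat(mono), pops)), 0)
  ## homozygote from a single haplotype
  het <- calls[!(calls$sample == "a" & calls$hap_seq == h2), ]
  s2 <- call_host_snps(mkcat(het), pops, maf_min = 0.05)
  g <- unclass(s2)[, "L1"]
  expect_equal(unname(g[c("a", "b")]), c(0L, 1L))
  ## MAF floor: minor allele 1/8 chromosomes at maf_min 0.2 -> dropped
  one_het <- calls[calls$hap_seq == h1 | calls$sample == "a", ]
  expect_equal(ncol(call_host_snps(mkcat(one_het), pops, maf_min = 0.2)), 0)
  ## presence-per-population floor
  absent_pop <- calls[calls$sample != "c" & calls$sample != "d", ]
  expect_equal(ncol(call_host_snps(mkcat(absent_pop), pops,
                                   presence_min_per_pop = 0.7)), 0)
  ## >2 haplotypes -> missing
  tri <- rbind(calls, data.frame(sample = "a", hap_seq = "ACGTCACGT",
                                 locus = "L1", depth = 10L))
  expect_message(s3 <- call_host_snps(mkcat(tri), pops,
                                      presence_min_per_pop = 0.5),
                 ">2 haplotypes")
  expect_true(is.na(unclass(s3)["a", "L1"]))
})

test_that("filter cascade matches the brute-force oracle on the toy matrix", {
  hm <- read_hap_matrix(system.file("extdata", "hapmatrix_toy.tsv",
                                    package = "symrad"))
  meta <- read.delim(system.file("extdata", "meta_toy.tsv",
                                 package = "symrad"))
  fc <- filter_cascade(hm, meta)
  orc <- oracle_cascade(unclass(hm), column_key(hm), meta)
  rep <- fc$report
  expect_equal(rep$n_loci[rep$stage == "presence_all"], orc$stage1)
  expect_equal(rep$n_loci[rep$stage == "presence_pop"], orc$stage2)
  for (d in names(orc$datasets)) {
    got <- rep[rep$stage == "missing15" & rep$dataset == d, ]
    expect_equal(got$n_samples, unname(orc$datasets[[d]]["n_samples"]),
                 label = paste("samples in", d))
    expect_equal(got$n_loci, unname(orc$datasets[[d]]["n_loci"]),
                 label = paste("loci in", d))
  }
  ## hand-derived expectations frozen from the fixture design
  expect_equal(rep$n_loci[rep$stage == "presence_all"], 5)
  expect_equal(rep$n_loci[rep$stage == "presence_pop"], 4)
  expect_setequal(names(fc$datasets), c("2013", "2014", "S"))
  expect_equal(nrow(fc$datasets[["2013"]]), 3)
  expect_equal(nrow(fc$datasets[["2014"]]), 3)
  expect_equal(nrow(fc$datasets[["S"]]), 4)
  ## monotonicity: no stage adds loci or samples
  expect_true(all(diff(rep$n_loci[rep$dataset == "all"]) <= 0))
})

test_that("all-complete matrices pass the cascade unchanged", {
  m <- matrix(1L, 8, 3,
              dimnames = list(letters[1:8],
                              c("L1:h1", "L2:h1", "L3:h1")))
  key <- data.frame(column = colnames(m), locus = c("L1", "L2", "L3"),
                    hap = 1L)
  hm <- symrad:::new_hap_matrix(m, key)
  meta <- data.frame(sample = letters[1:8],
                     location = rep(c("X", "Y"), 4),
                     year = rep(c(2013L, 2014L), each = 4))
  fc <- filter_cascade(hm, meta)
  expect_equal(ncol(fc$full), 3)
  expect_equal(nrow(fc$datasets[["2013"]]), 4)
  expect_equal(ncol(fc$datasets[["2014"]]), 3)
})

test_that("cascade halts when a population empties", {
  m <- matrix(1L, 4, 3,
              dimnames = list(letters[1:4], c("L1:h1", "L2:h1", "L3:h1")))
  m[3, 2:3] <- NA  # c keeps one locus of three (67% missing)
  m[4, ] <- NA     # d loses every locus
  key <- data.frame(column = colnames(m), locus = c("L1", "L2", "L3"),
                    hap = 1L)
  hm <- symrad:::new_hap_matrix(m, key)
  meta <- data.frame(sample = letters[1:4],
                     location = c("X", "X", "Y", "Y"),
                     year = 2014L)
  ## both Y individuals exceed the 15% missing ceiling -> Y empties
  expect_error(filter_cascade(hm, meta, presence_all = 0.5,
                              presence_pop = 0), "emptied")
})

test_that("matrices and VCF export round-trip", {
  sim <- tiny_sim(seed = 121, n_per_site = 2)
  dm <- demultiplex(sim$reads, sim$sheet)
  pt <- partition_reads(dm$reads, sim$ref)
  hm <- call_symbiont_haplotypes(build_reference_catalog(pt$symbiont),
                                 samples = sim$sheet$sample)
  p <- tempfile(fileext = ".tsv")
  write_hap_matrix(hm, p)
  back <- read_hap_matrix(p)
  expect_equal(unclass(back)[, ], unclass(hm)[, ])
  expect_equal(column_key(back)$locus, column_key(hm)$locus)

  snps <- call_host_snps(build_denovo_catalog(pt$host),
                         setNames(sim$sheet$location, sim$sheet$sample),
                         maf_min = 0.01, presence_min_per_pop = 0.3)
  vp <- tempfile(fileext = ".vcf")
  write_genotype_vcf(snps, vp)
  ln <- readLines(vp)
  expect_true(any(startsWith(ln, "##fileformat")))
  body <- ln[!startsWith(ln, "#")]
  expect_equal(length(body), ncol(snps))
})
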