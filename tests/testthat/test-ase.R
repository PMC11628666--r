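toy_variants <- function() {
  # five sites exercising each site-level filter rule
  sites <- data.frame(
    chrom = "Z", pos = c(100L, 200L, 300L, 400L, 500L),
    ref = c("A", "C", "AT", "G", "T"), alt = c("G", "T", "A", "A", "C"),
    qual = c(1000, 998, 1000, 1000, 1200),
    dp_info = c(700, 700, 700, 600, 650),
    indel = c(FALSE, FALSE, TRUE, FALSE, FALSE)
  )
  mk <- function(x) matrix(x, 5, 2, dimnames = list(NULL, c("s1", "s2")))
  variant_table(sites, gt = mk("0/1"), dp = mk(20), gq = mk(99),
                ad_ref = mk(10), ad_alt = mk(10))
}

test_that("variant filtering applies the QUAL/indel/depth/GQ rules", {
  v <- filter_variants(toy_variants())
  # QUAL 998 fails, the indel fails, site DP 600 fails -> 2 of 5 retained
  expect_equal(nrow(v$sites), 2)
  expect_equal(v$sites$pos, c(100L, 500L))
  # sample-level: DP below threshold blanks the genotype but keeps the site
  vt <- toy_variants()
  vt$dp[1, 1] <- 7
  f <- filter_variants(vt)
  expect_true(is.na(f$gt[1, "s1"]))
  expect_false(is.na(f$gt[1, "s2"]))
  expect_true(is.na(f$ad_ref[1, "s1"]))  # depths cannot leak into pooling
  # require_complete then drops the incomplete site
  fc <- filter_variants(vt, require_complete = TRUE)
  expect_equal(fc$sites$pos, 500L)
})

test_that("variant-to-gene mapping respects the coordinate conventions", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "Z",
                      start = c(100L, 150L), end = c(200L, 260L))
  v <- data.frame(chrom = "Z", pos = c(101L, 200L, 201L, 160L))
  pairs <- map_variants_to_genes(v, genes)
  # P = s+1 is the first covered base; P = e the last; P = e+1 outside
  expect_true(any(pairs$pos == 101 & pairs$gene_id == "g1"))
  expect_true(any(pairs$pos == 200 & pairs$gene_id == "g1"))
  expect_false(any(pairs$pos == 201 & pairs$gene_id == "g1"))
  # a variant inside two overlapping genes pairs twice
  expect_equal(sort(pairs$gene_id[pairs$pos == 160]), c("g1", "g2"))
})

test_that("tag-allele assignment uses pooled homokaryotype depths only", {
  sites <- data.frame(chrom = "Z", pos = c(10L, 20L, 30L), ref = "A", alt = "G",
                      qual = 1000, dp_info = 700, indel = FALSE)
  mk <- function(...) {
    m <- rbind(...)
    dimnames(m) <- list(NULL, c("aa1", "bb1", "ab1"))
    m
  }
  # site 1: fully fixed (AA all ref, BB all alt); site 2: AA ref fraction 0.6;
  # site 3: fixed but shallow in BB
  v <- variant_table(sites,
    gt = mk(c("0/0", "1/1", "0/1"), c("0/0", "1/1", "0/1"), c("0/0", "1/1", "0/1")),
    dp = mk(c(50, 50, 50), c(50, 50, 50), c(50, 10, 50)),
    gq = mk(c(99, 99, 99), c(99, 99, 99), c(99, 99, 99)),
    ad_ref = mk(c(50, 0, 25), c(30, 10, 25), c(50, 0, 25)),
    ad_alt = mk(c(0, 50, 25), c(20, 40, 25), c(0, 10, 25)))
  kt <- c(aa1 = "AA", bb1 = "BB", ab1 = "AB")
  tags <- assign_tag_alleles(v, kt, fixation = 0.9, min_group_depth = 20)
  expect_true(tags$informative[1])
  expect_equal(tags$a_allele[1], "ref")
  expect_false(tags$informative[2])  # 0.6 below fixation
  expect_false(tags$informative[3])  # BB pooled depth 10 < 20
})

test_that("simulated diagnostic SNPs are assigned to the correct haplotype", {
  correct <- total <- 0
  for (s in 1:2) {
    sim <- cached_sim(s)
    v <- filter_variants(sim$variants$testis)
    kt <- setNames(sim$meta$karyotype, sim$meta$sample_id)
    tags <- assign_tag_alleles(v, kt)
    tr <- sim$truth$diagnostic_snps
    idx <- match(paste(tr$chrom, tr$pos), paste(tags$chrom, tags$pos))
    ok <- tags$informative[idx] & tags$a_allele[idx] == tr$a_allele
    correct <- correct + sum(ok, na.rm = TRUE)
    total <- total + nrow(tr)
    # nothing outside the inversion regions should look diagnostic
    expect_equal(sum(tags$informative[-idx]), 0)
  }
  expect_gte(correct / total, 0.99)
})

test_that("the A-allele proportion is a depth-weighted SNP aggregate", {
  sites <- data.frame(chrom = "Z", pos = c(10L, 20L), ref = "A", alt = "G",
                      qual = 1000, dp_info = 700, indel = FALSE)
  mk <- function(x) matrix(x, 2, 1, dimnames = list(NULL, "ab1"))
  v <- variant_table(sites, gt = mk("0/1"), dp = mk(10), gq = mk(99),
                     ad_ref = mk(c(8, 2)), ad_alt = mk(c(2, 8)))
  tags <- data.frame(chrom = "Z", pos = c(10L, 20L), gene_id = "g1",
                     a_allele = "ref", informative = TRUE)
  ase <- ase_proportion(tags, v)
  expect_equal(ase$p_a, 0.5)  # (8 + 2) / 20
  expect_equal(ase$total_depth, 20)
  # all depth on the A allele
  v2 <- variant_table(sites, gt = mk("0/1"), dp = mk(10), gq = mk(99),
                      ad_ref = mk(c(10, 10)), ad_alt = mk(c(0, 0)))
  expect_equal(ase_proportion(tags, v2)$p_a, 1)
})

test_that("p_A is invariant to splitting SNP depths and flips under relabeling", {
  sites3 <- data.frame(chrom = "Z", pos = c(10L, 20L, 30L), ref = "A", alt = "G",
                       qual = 1000, dp_info = 700, indel = FALSE)
  mk3 <- function(x) matrix(x, 3, 1, dimnames = list(NULL, "ab1"))
  # one SNP with depths (6,4) split into two SNPs with the same totals
  v_split <- variant_table(sites3, gt = mk3("0/1"), dp = mk3(10), gq = mk3(99),
                           ad_ref = mk3(c(3, 3, 2)), ad_alt = mk3(c(2, 2, 8)))
  tags12 <- data.frame(chrom = "Z", pos = c(10L, 20L, 30L), gene_id = "g1",
                       a_allele = "ref", informative = TRUE)
  sites2 <- sites3[c(1, 3), ]
  mk2 <- function(x) matrix(x, 2, 1, dimnames = list(NULL, "ab1"))
  v_one <- variant_table(sites2, gt = mk2("0/1"), dp = mk2(c(12, 10)), gq = mk2(99),
                         ad_ref = mk2(c(6, 2)), ad_alt = mk2(c(4, 8)))
  tags2 <- data.frame(chrom = "Z", pos = c(10L, 30L), gene_id = "g1",
                      a_allele = "ref", informative = TRUE)
  expect_equal(ase_proportion(tags12, v_split)$p_a, ase_proportion(tags2, v_one)$p_a)
  # swapping every A/B label maps p_A to 1 - p_A
  tags_sw <- tags2; tags_sw$a_allele <- "alt"
  expect_equal(ase_proportion(tags_sw, v_one)$p_a, 1 - ase_proportion(tags2, v_one)$p_a)
})

test_that("simulated homokaryotypes are near-monoallelic at tag SNPs", {
  sim <- cached_sim(1)
  v <- filter_variants(sim$variants$testis)
  kt <- setNames(sim$meta$karyotype, sim$meta$sample_id)
  genes <- sim$counts$testis$genes
  tags <- assign_tag_alleles(v, kt, map_variants_to_genes(v, genes[genes$chrom == "Z", ]))
  ase <- ase_proportion(tags, v, sim$meta)
  ase$karyotype <- kt[ase$sample_id]
  aa <- ase$p_a[ase$karyotype == "AA" & !ase$undefined]
  bb <- ase$p_a[ase$karyotype == "BB" & !ase$undefined]
  expect_gt(mean(aa), 0.95)
  expect_lt(mean(bb), 0.05)
})

test_that("a tissue-specific monoallelic gene is flagged between tissues", {
  sim <- cached_sim(1)
  g <- sim$truth$ase_truth$gene[1]
  pt <- pooled_ab_pa(sim, "testis", g)$p_a
  pl <- pooled_ab_pa(sim, "liver", g)$p_a
  expect_gt(abs(pt - pl), 0.3)
})

test_that("dominance patterns follow the delta thresholds", {
  m <- function(aa_e, ab_e, bb_e, aa_l, ab_l, bb_l) {
    matrix(c(aa_e, aa_l, ab_e, ab_l, bb_e, bb_l), 2, 3,
           dimnames = list(c("EARLY", "LATE"), c("AA", "AB", "BB")))
  }
  out <- classify_pattern(m(5, 4.9, 1, 5, 4.8, 1))
  expect_equal(out$pattern, "A_dominant")
  expect_equal(unname(out$delta), c(0.975, 0.95))
  expect_equal(classify_pattern(m(5, 3, 1, 5, 3, 1))$pattern, "intermediate")
  expect_equal(classify_pattern(m(5, 1.2, 1, 5, 1.1, 1))$pattern, "B_dominant")
  expect_equal(classify_pattern(m(5, 3, 1, 5, 4.9, 1))$pattern, "divergent_over_time")
  expect_equal(classify_pattern(m(5, 4.9, 1, 5, 1.1, 1))$pattern, "switching")
  # orientation-free: same calls when BB is the higher homokaryotype
  expect_equal(classify_pattern(m(1, 1.1, 5, 1, 1.2, 5))$pattern, "A_dominant")
  # minimum-effect guard
  expect_equal(classify_pattern(m(5, 4.9, 4.5, 5, 4.8, 4.5))$pattern, "unclassified")
  expect_error(classify_pattern(m(NA, 4.9, 1, 5, 4.8, 1)), "cell means")
})

test_that("planted dominance patterns are recovered from fitted cell means", {
  total <- hits <- 0
  for (s in 1:10) {
    sim <- cached_sim(s, cis_effect_log2fc = 3)
    r <- run_de(sim$counts$testis, sim$meta, "testis")
    means <- karyotype_group_means(r$logcpm, r$meta)
    pt <- sim$truth$pattern_truth
    pt <- pt[names(pt) %in% rownames(means)]
    got <- vapply(names(pt), function(g) classify_pattern(means[g, , ])$pattern,
                  character(1))
    total <- total + length(pt)
    hits <- hits + sum(got == pt)
  }
  expect_gte(hits / total, 0.95)
})
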