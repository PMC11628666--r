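test_that("a window holding all DE genes gets the exact hypergeometric p", {
  set.seed(51)
  gid <- paste0("g", 1:100)
  pos <- c(seq(1e5, 9e5, length.out = 10),            # the 10 DE genes, clustered
           seq(5e7, 9e7, length.out = 90))            # everything else, far away
  expressed <- data.frame(gene_id = gid, chrom = "Z", start = round(pos))
  de <- gid[1:10]
  we <- window_enrichment(de, expressed, 4e6, steps_per_window = 4, fdr = 0.01,
                          chrom_lengths = c(Z = 1e8))
  w0 <- we$windows[we$windows$start_bp == 0, ]
  expect_equal(w0$n_expressed, 10)
  expect_equal(w0$n_de, 10)
  expect_equal(w0$p, 1 / choose(100, 10))
  expect_true(w0$significant)
})

test_that("without DE genes no window is significant", {
  expressed <- data.frame(gene_id = paste0("g", 1:50), chrom = "Z",
                          start = round(seq(1e6, 9e7, length.out = 50)))
  we <- window_enrichment(character(0), expressed, 4e6)
  expect_false(any(we$windows$significant))
  expect_equal(nrow(we$regions), 0)
  expect_error(window_enrichment("absent", expressed, 4e6), "background")
})

test_that("windows tile the chromosome with the stated overlap", {
  expressed <- data.frame(gene_id = paste0("g", 1:10), chrom = "Z",
                          start = round(seq(1e6, 70e6, length.out = 10)))
  we <- window_enrichment(character(0), expressed, 4e6, steps_per_window = 4,
                          chrom_lengths = c(Z = 73e6))
  w <- we$windows
  expect_equal(unique(diff(w$start_bp)), 1e6)  # step = size / steps
  # an interior position is covered by exactly steps_per_window windows
  for (p in c(10e6, 33.3e6, 50e6)) {
    expect_equal(sum(p >= w$start_bp & p < w$end_bp), 4)
  }
  # every gene is assigned to each covering window
  expect_equal(sum(w$n_expressed), sum(vapply(expressed$start, function(p)
    sum(p >= w$start_bp & p < w$end_bp), numeric(1))))
})

test_that("planted DE clusters are detected and null windows stay quiet", {
  detected <- logical(5)
  for (s in 1:5) {
    set.seed(s)
    pos <- sort(sample.int(1e8, 2000))
    gid <- paste0("g", 1:2000)
    expressed <- data.frame(gene_id = gid, chrom = "Z", start = pos)
    incl <- which(pos >= 5e7 & pos < 5.4e7)
    de <- c(sample(gid[incl], min(15, length(incl))), sample(gid[-incl], 25))
    we <- window_enrichment(de, expressed, 4e6, 4, 0.01, chrom_lengths = c(Z = 1e8))
    detected[s] <- any(we$regions$start_bp <= 5.4e7 & we$regions$end_bp >= 5e7)
  }
  expect_true(all(detected))
  false_windows <- vapply(1:10, function(s) {
    set.seed(100 + s)
    pos <- sort(sample.int(1e8, 2000))
    gid <- paste0("g", 1:2000)
    expressed <- data.frame(gene_id = gid, chrom = "Z", start = pos)
    sum(window_enrichment(sample(gid, 40), expressed, 4e6, 4, 0.01,
                          chrom_lengths = c(Z = 1e8))$windows$significant)
  }, numeric(1))
  expect_lte(mean(false_windows > 0), 0.01)
})

test_that("the Yates-corrected chromosome bias statistic is exact on hand cases", {
  uni <- data.frame(gene_id = paste0("g", 1:10000),
                    chrom = rep(c("Z", "1"), c(1000, 9000)))
  de <- c(paste0("g", 1:10), paste0("g", 2001:2040))  # 10 on Z, 40 autosomal
  b <- chrom_bias_test(de, uni)
  expect_equal(unname(b$observed), c(10, 40))
  expect_equal(unname(b$expected), c(5, 45))
  expect_equal(b$statistic, 4.5)  # (4.5^2)/5 + (4.5^2)/45
  expect_equal(b$df, 1)
  # proportional observed counts: statistic at most the correction floor
  de0 <- c(paste0("g", 1:5), paste0("g", 2001:2045))
  b0 <- chrom_bias_test(de0, uni)
  expect_lte(b0$statistic, 0.25 / 5 + 0.25 / 45)
})

test_that("the chromosome bias test is calibrated under uniform sampling", {
  set.seed(61)
  uni <- data.frame(gene_id = paste0("g", 1:10000),
                    chrom = rep(c("Z", "1"), c(1000, 9000)))
  rej <- mean(replicate(2000, chrom_bias_test(sample(uni$gene_id, 200), uni)$p < 0.05))
  expect_gte(rej, 0.03); expect_lte(rej, 0.07)
})

test_that("Z:autosome ratios behave on constructed and null inputs", {
  # identical Z and autosomal values give exactly 1
  m <- matrix(4, 20, 6, dimnames = list(paste0("g", 1:20), paste0("s", 1:6)))
  chrom <- setNames(rep(c("Z", "1"), each = 10), rownames(m))
  groups <- list(all = colnames(m))
  za <- z_autosome_ratio(m, chrom, groups)
  expect_equal(za$ratio, 1)
  # null simulation: matching distributions keep the ratio near 1
  set.seed(62)
  m2 <- matrix(rnorm(2000 * 6, 5, 1), 2000, 6,
               dimnames = list(paste0("g", 1:2000), paste0("s", 1:6)))
  chrom2 <- setNames(rep(c("Z", "1"), each = 1000), rownames(m2))
  za2 <- z_autosome_ratio(m2, chrom2, list(all = colnames(m2)))
  expect_gt(za2$ratio, 0.9); expect_lt(za2$ratio, 1.1)
  # lowering Z expression lowers the ratio
  m3 <- m2; m3[chrom2 == "Z", ] <- m3[chrom2 == "Z", ] - 1
  za3 <- z_autosome_ratio(m3, chrom2, list(all = colnames(m3)))
  expect_lt(za3$ratio, za2$ratio)
  # scaffolds are excluded from both sides
  chrom4 <- chrom2; chrom4[1:10] <- "scaffold_12"
  za4 <- z_autosome_ratio(m2, chrom4, list(all = colnames(m2)),
                          scaffolds = "scaffold_12")
  expect_false(is.na(za4$ratio))
})
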