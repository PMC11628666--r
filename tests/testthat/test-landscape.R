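test_that("polarization re-codes the AA-majority allele as zero", {
  dos <- rbind(snp1 = c(2L, 2L, 0L, 1L),  # AA samples alt-homozygous -> flip
               snp2 = c(0L, 0L, 2L, 1L))  # ref already AA-major -> unchanged
  colnames(dos) <- c("a1", "a2", "b1", "h1")
  kt <- c(a1 = "AA", a2 = "AA", b1 = "BB", h1 = "AB")
  pol <- polarize(dos, kt, positions = c(100, 200))
  expect_equal(unname(pol["snp1", ]), c(0L, 0L, 2L, 1L))
  expect_equal(unname(pol["snp2", ]), c(0L, 0L, 2L, 1L))
  # AA mean dosage never exceeds 1 after polarization
  expect_true(all(rowMeans(pol[, c("a1", "a2")]) <= 1))
  # idempotent
  pol2 <- polarize(pol[, ], kt, positions = c(100, 200))
  expect_equal(pol2[, ], pol[, ])
  expect_error(polarize(dos, c(a1 = "BB", a2 = "BB", b1 = "BB", h1 = "AB")), "AA")
})

test_that("heterokaryotypes form the dosage-1 band inside a planted block", {
  g <- simulate_block_genotypes(block = c(20e6, 40e6), seed = 3)
  pol <- polarize(g$dosage, g$karyotypes, positions = g$positions)
  inside <- attr(pol, "positions") >= 20e6 & attr(pol, "positions") <= 40e6
  ab_mean <- mean(pol[inside, g$karyotypes == "AB"])
  expect_equal(ab_mean, 1, tolerance = 1e-9)
  expect_true(all(pol[inside, g$karyotypes == "AA"] == 0))
  expect_true(all(pol[inside, g$karyotypes == "BB"] == 2))
})

test_that("block segmentation recovers planted boundaries within a megabase", {
  for (s in 1:3) {
    g <- simulate_block_genotypes(block = c(20e6, 40e6), seed = s)
    pol <- polarize(g$dosage, g$karyotypes, positions = g$positions)
    seg <- segment_blocks(pol, g$karyotypes)
    expect_equal(nrow(seg$blocks), 1)
    expect_lt(abs(seg$blocks$start_bp - 20e6), 1e6)
    expect_lt(abs(seg$blocks$end_bp - 40e6), 1e6)
  }
})

test_that("segmentation finds nothing without differentiation and splits twin blocks", {
  g <- simulate_block_genotypes(block = NULL, seed = 4)
  # force d = 0 exactly: all samples identical
  dos <- g$dosage
  dos[] <- rep(dos[, 1], ncol(dos))
  seg <- segment_blocks(dos, g$karyotypes, positions = g$positions)
  expect_equal(nrow(seg$blocks), 0)
  expect_length(seg$breakpoints, 0)
  # two planted blocks separated by a long low-d stretch
  g1 <- simulate_block_genotypes(block = c(10e6, 25e6), seed = 5)
  g2 <- simulate_block_genotypes(block = c(55e6, 70e6), seed = 5)
  dos2 <- g1$dosage
  far <- g1$positions >= 40e6
  dos2[far, ] <- g2$dosage[far, ]
  seg2 <- segment_blocks(dos2, g1$karyotypes, positions = g1$positions)
  expect_equal(nrow(seg2$blocks), 2)
  expect_error(segment_blocks(dos2[1:5, ], g1$karyotypes,
                              positions = g1$positions[1:5]), "fewer SNPs")
})

test_that("null chromosomes essentially never produce a block", {
  n_blocks <- vapply(1:20, function(s) {
    g <- simulate_block_genotypes(block = NULL, seed = s)
    nrow(segment_blocks(g$dosage, g$karyotypes, positions = g$positions)$blocks)
  }, numeric(1))
  expect_lte(mean(n_blocks), 0.05)
})

test_that("block calls are invariant to global allele relabeling", {
  g <- simulate_block_genotypes(block = c(20e6, 40e6), seed = 6)
  seg1 <- segment_blocks(polarize(g$dosage, g$karyotypes, positions = g$positions),
                         g$karyotypes)
  seg2 <- segment_blocks(polarize(2L - g$dosage, g$karyotypes, positions = g$positions),
                         g$karyotypes)
  expect_equal(seg1$blocks, seg2$blocks)
})

test_that("pairwise r2 matches correlation structure of dosages", {
  dos <- rbind(a = c(0L, 1L, 2L, 0L, 2L),
               b = c(0L, 1L, 2L, 0L, 2L),     # identical to a
               c = c(2L, 1L, 0L, 2L, 0L),     # perfectly anti-correlated
               d = c(1L, 1L, 1L, 1L, 1L))     # degenerate
  colnames(dos) <- paste0("s", 1:5)
  r2 <- pairwise_r2(dos, positions = c(1, 2, 3, 4))
  get <- function(i, j) r2$r2[r2$i == i & r2$j == j]
  expect_equal(get(1, 2), 1)
  expect_equal(get(1, 3), 1)  # squared correlation ignores sign
  expect_true(r2$degenerate[r2$j == 4][1])
  expect_true(all(is.na(r2$r2[r2$degenerate])))
  # orthogonal vectors
  dos2 <- rbind(x = c(0L, 0L, 2L, 2L), y = c(0L, 2L, 2L, 0L))
  colnames(dos2) <- paste0("s", 1:4)
  expect_equal(pairwise_r2(dos2)$r2, 0)
  # SNPs inside the same planted block are in strong LD
  g <- simulate_block_genotypes(block = c(20e6, 40e6), seed = 7)
  inside <- which(g$positions >= 21e6 & g$positions <= 39e6)[1:5]
  r2b <- pairwise_r2(g$dosage[inside, ], positions = g$positions[inside])
  expect_true(all(r2b$r2 > 0.8))
})
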