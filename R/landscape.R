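#' Dosage matrix from genotype strings
#'
#' @param v A [variant_table()].
#' @return Integer matrix sites x samples: alt-allele dosage 0/1/2, NA for
#'   missing genotypes.
#' @export
genotype_dosage <- function(v) {
  d <- matrix(NA_integer_, nrow(v$gt), ncol(v$gt), dimnames = dimnames(v$gt))
  d[v$gt %in% c("0/0", "0|0")] <- 0L
  d[v$gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  d[v$gt %in% c("1/1", "1|1")] <- 2L
  d
}

#' Polarize genotypes toward the AA karyotype
#'
#' At each SNP the allele carried by the majority of AA-sample haplotypes
#' is re-coded as dosage 0, and every sample becomes the count of the other
#' allele. Inversion blocks then appear as bands: AA samples near 0, BB
#' samples near 2, heterokaryotypes near 1. Ties are broken toward the
#' reference allele (no flip). SNPs with no genotyped AA sample are dropped
#' with a record in the `dropped` attribute.
#'
#' @param dosage Integer matrix sites x samples (alt dosage), or a
#'   [variant_table()].
#' @param karyotypes Named vector, karyotype per sample.
#' @param positions Optional positions (taken from the variant table when
#'   one is given).
#' @return Matrix of polarized dosages with attributes `positions` and
#'   `flipped`; class `polarized_genotypes`.
#' @export
polarize <- function(dosage, karyotypes, positions = NULL) {
  if (inherits(dosage, "variant_table")) {
    positions <- dosage$sites$pos
    dosage <- genotype_dosage(dosage)
  }
  karyotypes <- check_karyotypes(karyotypes[colnames(dosage)])
  aa <- karyotypes == "AA"
  if (!any(aa)) stop("no AA samples: polarization undefined")
  n_called <- rowSums(!is.na(dosage[, aa, drop = FALSE]))
  keep <- n_called > 0
  dropped <- which(!keep)
  dosage <- dosage[keep, , drop = FALSE]
  if (!is.null(positions)) positions <- positions[keep]
  aa_mean <- rowMeans(dosage[, aa, drop = FALSE], na.rm = TRUE)
  flip <- aa_mean > 1  # alt is the AA-majority allele; tie keeps ref coded 0
  out <- dosage
  out[flip, ] <- 2L - dosage[flip, , drop = FALSE]
  attr(out, "positions") <- positions
  attr(out, "flipped") <- flip
  attr(out, "dropped") <- dropped
  class(out) <- c("polarized_genotypes", class(out))
  out
}

#' Segment the chromosome into fixed-difference blocks
#'
#' Per-SNP differentiation `d = |AF_AA - AF_BB|` from the pooled allele
#' frequencies of the homokaryotype groups, smoothed by a centered moving
#' average over `m_snps` SNPs (shrinking to the available window at the
#' chromosome ends). Maximal runs with smoothed d at or above `threshold`
#' are reported as blocks; each block boundary is the outermost SNP of the
#' run extended half-way to its neighboring SNP (or the SNP position itself
#' at the chromosome ends).
#'
#' @param polarized A [polarize()]d matrix (any consistent allele coding
#'   works: differentiation is invariant to relabeling).
#' @param karyotypes Named vector, karyotype per sample.
#' @param m_snps Moving-average window (odd recommended).
#' @param threshold Smoothed-differentiation cutoff for a block.
#' @param positions SNP positions (defaults to the attribute).
#' @return List: `snps` (position, d, smoothed), `blocks` (start_bp,
#'   end_bp, n_snps, mean_d), `breakpoints` (sorted block boundaries).
#' @export
segment_blocks <- function(polarized, karyotypes, m_snps = 11, threshold = 0.8,
                           positions = NULL) {
  positions <- positions %||% attr(polarized, "positions")
  if (is.null(positions)) stop("SNP positions are required")
  if (is.unsorted(positions)) stop("SNPs must be position-sorted")
  if (nrow(polarized) < m_snps) stop("fewer SNPs than the smoothing window")
  karyotypes <- check_karyotypes(karyotypes[colnames(polarized)])
  af <- function(sel) rowMeans(polarized[, sel, drop = FALSE], na.rm = TRUE) / 2
  d <- abs(af(karyotypes == "AA") - af(karyotypes == "BB"))
  d[is.na(d)] <- 0
  half <- (m_snps - 1) %/% 2
  n <- length(d)
  cs <- c(0, cumsum(d))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  sm <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  run <- rle(sm >= threshold)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1
  # candidate runs from the smoothed profile; edges then expanded outward
  # over contiguous SNPs whose raw d also clears the threshold, since the
  # centered moving average pulls the threshold crossing inward by about
  # half the smoothing window
  cand <- lapply(which(run$values), function(i) {
    s <- starts[i]; e <- ends[i]
    while (s > 1 && d[s - 1] >= threshold) s <- s - 1
    while (e < n && d[e + 1] >= threshold) e <- e + 1
    c(s, e)
  })
  if (length(cand) > 1) {  # expansion can make neighbours touch: merge
    cand <- Reduce(function(acc, x) {
      last <- acc[[length(acc)]]
      if (x[1] <= last[2] + 1) acc[[length(acc)]] <- c(last[1], max(last[2], x[2]))
      else acc[[length(acc) + 1]] <- x
      acc
    }, cand[-1], accumulate = FALSE, init = cand[1])
  }
  blocks <- list()
  for (se in cand) {
    s <- se[1]; e <- se[2]
    start_bp <- if (s == 1) positions[1] else (positions[s] + positions[s - 1]) / 2
    end_bp <- if (e == n) positions[n] else (positions[e] + positions[e + 1]) / 2
    blocks[[length(blocks) + 1]] <- data.frame(
      start_bp = start_bp, end_bp = end_bp, n_snps = e - s + 1,
      mean_d = mean(d[s:e])
    )
  }
  blocks <- if (length(blocks) > 0) do.call(rbind, blocks) else
    data.frame(start_bp = numeric(0), end_bp = numeric(0),
               n_snps = integer(0), mean_d = numeric(0))
  list(snps = data.frame(pos = positions, d = d, smoothed = sm),
       blocks = blocks,
       breakpoints = sort(c(blocks$start_bp, blocks$end_bp)))
}

#' Pairwise linkage disequilibrium (r-squared) between SNP dosages
#'
#' Squared Pearson correlation of dosage vectors over the samples
#' non-missing at both SNPs. Pairs involving a zero-variance SNP are
#' returned with `NA` and flagged.
#'
#' @param dosage Matrix sites x samples (polarized or raw coding; r-squared
#'   is invariant).
#' @param max_pairs Cap on the number of pairs (the first `max_pairs` in
#'   row-major order of the upper triangle).
#' @param positions Optional positions to attach.
#' @return Data frame `i`, `j`, `pos_i`, `pos_j`, `r2`, `degenerate`.
#' @export
pairwise_r2 <- function(dosage, max_pairs = Inf, positions = NULL) {
  positions <- positions %||% attr(dosage, "positions")
  n <- nrow(dosage)
  pairs <- list()
  count <- 0
  for (i in seq_len(max(n - 1, 0))) {
    for (j in seq(i + 1, n)) {
      if (count >= max_pairs) break
      ok <- !is.na(dosage[i, ]) & !is.na(dosage[j, ])
      if (sum(ok) < 2) next
      vi <- dosage[i, ok]; vj <- dosage[j, ok]
      degenerate <- sd(vi) == 0 || sd(vj) == 0
      r2 <- if (degenerate) NA_real_ else cor(vi, vj)^2
      count <- count + 1
      pairs[[count]] <- data.frame(
        i = i, j = j,
        pos_i = if (!is.null(positions)) positions[i] else NA_real_,
        pos_j = if (!is.null(positions)) positions[j] else NA_real_,
        r2 = r2, degenerate = degenerate
      )
    }
    if (count >= max_pairs) break
  }
  if (length(pairs) == 0) {
    return(data.frame(i = integer(0), j = integer(0), pos_i = numeric(0),
                      pos_j = numeric(0), r2 = numeric(0),
                      degenerate = logical(0)))
  }
  do.call(rbind, pairs)
}
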