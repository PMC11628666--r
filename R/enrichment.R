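#' Sliding-window enrichment of DE genes along the genome
#'
#' Chromosomes are tiled with windows of `window_size_bp` advancing by
#' `window_size_bp / steps_per_window`, so each position is covered by
#' `steps_per_window` windows away from the ends. A gene belongs to a
#' window when its start coordinate falls inside it. Each window is tested
#' with the hypergeometric upper tail (drawing its DE genes among its
#' expressed genes from the genome-wide totals), p-values are BH-adjusted
#' across all windows, and overlapping significant windows are merged into
#' enriched regions.
#'
#' @param de_genes Character vector of DE gene ids (must be a subset of the
#'   expressed background).
#' @param expressed Data frame of the expressed background: `gene_id`,
#'   `chrom`, `start` (bp; the same convention as the windows, 0-based).
#' @param window_size_bp Window size in basepairs (4 Mb for testis, 8 Mb
#'   for liver by default usage).
#' @param steps_per_window Steps per window.
#' @param fdr Significance cutoff on the BH-adjusted p.
#' @param chrom_lengths Optional named vector; defaults to the largest gene
#'   start + 1 per chromosome.
#' @return List with `windows` (all windows with counts, `p`, `q`,
#'   `significant`) and `regions` (merged significant windows).
#' @export
window_enrichment <- function(de_genes, expressed, window_size_bp,
                              steps_per_window = 4, fdr = 0.01,
                              chrom_lengths = NULL) {
  if (!all(de_genes %in% expressed$gene_id)) {
    stop("every DE gene must be present in the expressed background")
  }
  step <- window_size_bp / steps_per_window
  n_total <- nrow(expressed)
  k_total <- length(de_genes)
  is_de <- expressed$gene_id %in% de_genes
  win <- list()
  for (chrom in unique(expressed$chrom)) {
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[chrom]] else
      max(expressed$start[expressed$chrom == chrom]) + 1
    starts <- seq(0, max(0, len - 1), by = step)
    pos <- expressed$start[expressed$chrom == chrom]
    de <- is_de[expressed$chrom == chrom]
    idx <- findInterval(pos, starts)  # window index whose start is <= pos
    nw <- length(starts)
    n_in <- k_in <- integer(nw)
    # a gene at pos is inside windows j with starts[j] <= pos < starts[j]+size
    first <- pmax(1L, idx - steps_per_window + 1L)
    for (g in seq_along(pos)) {
      js <- first[g]:idx[g]
      js <- js[pos[g] < starts[js] + window_size_bp]
      n_in[js] <- n_in[js] + 1L
      if (de[g]) k_in[js] <- k_in[js] + 1L
    }
    win[[chrom]] <- data.frame(
      chrom = chrom, start_bp = starts, end_bp = starts + window_size_bp,
      n_expressed = n_in, n_de = k_in
    )
  }
  windows <- do.call(rbind, win)
  rownames(windows) <- NULL
  windows$p <- phyper(windows$n_de - 1, k_total, n_total - k_total,
                      windows$n_expressed, lower.tail = FALSE)
  windows$q <- p.adjust(windows$p, method = "BH")
  windows$significant <- windows$q <= fdr & windows$n_de > 0
  regions <- merge_windows(windows[windows$significant, , drop = FALSE])
  list(windows = windows, regions = regions)
}

#' @noRd
merge_windows <- function(w) {
  if (nrow(w) == 0) {
    return(data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0)))
  }
  out <- list()
  for (chrom in unique(w$chrom)) {
    s <- w[w$chrom == chrom, , drop = FALSE]
    s <- s[order(s$start_bp), , drop = FALSE]
    cur_s <- s$start_bp[1]; cur_e <- s$end_bp[1]
    for (i in seq_len(nrow(s))[-1]) {
      if (s$start_bp[i] <= cur_e) {
        cur_e <- max(cur_e, s$end_bp[i])
      } else {
        out[[length(out) + 1]] <- data.frame(chrom = chrom, start_bp = cur_s, end_bp = cur_e)
        cur_s <- s$start_bp[i]; cur_e <- s$end_bp[i]
      }
    }
    out[[length(out) + 1]] <- data.frame(chrom = chrom, start_bp = cur_s, end_bp = cur_e)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Chromosome-Z overrepresentation of DE genes (Yates-corrected chi-squared)
#'
#' One-degree-of-freedom goodness-of-fit test of the observed split of DE
#' genes between chromosome Z and the autosomes against the proportions of
#' the gene universe, with Yates continuity correction:
#' \eqn{X^2 = \sum (|O - E| - 0.5)^2 / E} over the two cells.
#'
#' @param de_genes Character vector of DE gene ids.
#' @param universe Data frame `gene_id`, `chrom` defining the background
#'   (genome or expressed set, per the `background` flag of the caller);
#'   scaffolds should already be excluded.
#' @param z_chrom Name of the Z chromosome in the annotation.
#' @return List: `observed`, `expected`, `statistic`, `df`, `p`,
#'   `low_expected` (flag when an expected cell is below 1).
#' @export
chrom_bias_test <- function(de_genes, universe, z_chrom = "Z") {
  on_z <- universe$chrom == z_chrom
  n_z <- sum(on_z); n_a <- sum(!on_z)
  de_on_z <- de_genes %in% universe$gene_id[on_z]
  o <- c(Z = sum(de_on_z), autosome = length(de_genes) - sum(de_on_z))
  e <- length(de_genes) * c(Z = n_z, autosome = n_a) / (n_z + n_a)
  low <- any(e < 1)
  if (low) warning("expected cell count below 1; chi-squared approximation is poor")
  x2 <- sum(pmax(abs(o - e) - 0.5, 0)^2 / e)
  list(observed = o, expected = e, statistic = x2, df = 1,
       p = pchisq(x2, df = 1, lower.tail = FALSE), low_expected = low)
}

#' Z : autosome median-expression ratio per sample group
#'
#' For each group of samples (conventionally karyotype x tissue x
#' timepoint), the ratio of the median log-CPM over Z-linked genes to the
#' median over autosomal genes. A chromosome-wide dosage effect (e.g.
#' meiotic sex-chromosome silencing) would push this ratio away from 1 in
#' specific groups.
#'
#' @param logcpm Matrix genes x samples, restained to expressed genes.
#' @param gene_chrom Named character vector: chromosome per gene.
#' @param groups Named list of character vectors of sample ids, or a factor
#'   over the columns of `logcpm`.
#' @param z_chrom Name of the Z chromosome.
#' @param scaffolds Chromosome names to exclude (unplaced scaffolds).
#' @return Data frame `group`, `median_z`, `median_autosome`, `ratio`
#'   (`NA` with a flag when the autosomal median is zero).
#' @export
z_autosome_ratio <- function(logcpm, gene_chrom, groups, z_chrom = "Z",
                             scaffolds = character(0)) {
  gene_chrom <- gene_chrom[rownames(logcpm)]
  keep <- !(gene_chrom %in% scaffolds)
  if (is.factor(groups) || is.character(groups)) {
    groups <- split(colnames(logcpm), groups)
  }
  zg <- keep & gene_chrom == z_chrom
  ag <- keep & gene_chrom != z_chrom
  if (!any(zg) || !any(ag)) stop("need at least one Z and one autosomal gene")
  out <- lapply(names(groups), function(g) {
    cols <- groups[[g]]
    mz <- median(logcpm[zg, cols, drop = FALSE])
    ma <- median(logcpm[ag, cols, drop = FALSE])
    data.frame(group = g, median_z = mz, median_autosome = ma,
               ratio = if (ma == 0) NA_real_ else mz / ma,
               undefined = ma == 0)
  })
  do.call(rbind, out)
}
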