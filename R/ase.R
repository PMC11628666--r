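#' Variant table with per-sample genotype fields
#'
#' A light container mirroring the FORMAT fields needed for allele-specific
#' expression: per-site metadata plus per-sample GT, DP, GQ and allelic
#' depths (AD split into ref and alt components).
#'
#' @param sites Data frame: `chrom`, `pos` (1-based), `ref`, `alt`, `qual`,
#'   `dp_info` (site INFO/DP), `indel` (logical).
#' @param gt Character matrix sites x samples ("0/0", "0/1", "1/1" or NA).
#' @param dp,gq,ad_ref,ad_alt Numeric matrices, sites x samples.
#' @return Object of class `variant_table`.
#' @export
variant_table <- function(sites, gt, dp, gq, ad_ref, ad_alt) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "qual", "dp_info", "indel") %in% names(sites)))
  n <- nrow(sites)
  for (m in list(gt, dp, gq, ad_ref, ad_alt)) {
    if (nrow(m) != n) stop("per-sample matrices must have one row per site")
  }
  if (any(ad_ref + ad_alt > dp, na.rm = TRUE)) {
    stop("AD components must not exceed DP")
  }
  o <- order(sites$chrom, sites$pos)
  structure(list(sites = sites[o, , drop = FALSE],
                 gt = gt[o, , drop = FALSE], dp = dp[o, , drop = FALSE],
                 gq = gq[o, , drop = FALSE],
                 ad_ref = ad_ref[o, , drop = FALSE],
                 ad_alt = ad_alt[o, , drop = FALSE]),
            class = "variant_table")
}

#' @exportS3Method base::print
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites x %d samples\n",
              nrow(x$sites), ncol(x$gt)))
  invisible(x)
}

#' @exportS3Method base::dim
dim.variant_table <- function(x) c(nrow(x$sites), ncol(x$gt))

#' Filter variants on site and genotype quality
#'
#' Site-level: drops sites with `QUAL < min_qual`, indels (when
#' `drop_indels`), or `INFO/DP < min_site_dp`. Sample-level: genotypes with
#' `DP < min_sample_dp` or `GQ < min_gq` are set missing (their depths too,
#' so they cannot leak into allele assignment). With `require_complete`,
#' sites with any missing genotype are then dropped (the merged-tissue mode
#' used for the genotype landscape).
#'
#' @param v A [variant_table()].
#' @param min_qual,min_site_dp,min_sample_dp,min_gq Thresholds; the
#'   defaults are the transcriptome-calling values QUAL 999, site depth
#'   640, sample depth 8, genotype quality 10.
#' @param drop_indels Drop indel records?
#' @param require_complete Drop sites with any missing genotype?
#' @return A filtered [variant_table()].
#' @export
filter_variants <- function(v, min_qual = 999, min_site_dp = 640,
                            min_sample_dp = 8, min_gq = 10,
                            drop_indels = TRUE, require_complete = FALSE) {
  keep <- v$sites$qual >= min_qual & v$sites$dp_info >= min_site_dp
  if (drop_indels) keep <- keep & !v$sites$indel
  sub <- function(m) m[keep, , drop = FALSE]
  sites <- v$sites[keep, , drop = FALSE]
  gt <- sub(v$gt); dp <- sub(v$dp); gq <- sub(v$gq)
  ad_ref <- sub(v$ad_ref); ad_alt <- sub(v$ad_alt)
  bad <- is.na(dp) | dp < min_sample_dp | is.na(gq) | gq < min_gq
  gt[bad] <- NA_character_
  dp[bad] <- NA_real_; gq[bad] <- NA_real_
  ad_ref[bad] <- NA_real_; ad_alt[bad] <- NA_real_
  if (require_complete) {
    complete <- rowSums(is.na(gt)) == 0
    sites <- sites[complete, , drop = FALSE]
    gt <- gt[complete, , drop = FALSE]; dp <- dp[complete, , drop = FALSE]
    gq <- gq[complete, , drop = FALSE]
    ad_ref <- ad_ref[complete, , drop = FALSE]
    ad_alt <- ad_alt[complete, , drop = FALSE]
  }
  variant_table(sites, gt, dp, gq, ad_ref, ad_alt)
}

#' Map variants to genes by genomic overlap
#'
#' A variant at 1-based position P pairs with a gene interval \[s, e) in
#' 0-based half-open coordinates iff `s <= P - 1 < e`. Variants inside
#' several overlapping genes pair with each of them.
#'
#' @param v A [variant_table()] (or data frame with `chrom`, `pos`).
#' @param genes Data frame `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return Data frame `chrom`, `pos`, `gene_id`, one row per pair.
#' @export
map_variants_to_genes <- function(v, genes) {
  sites <- if (inherits(v, "variant_table")) v$sites else v
  vgr <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start + 1, genes$end))
  hits <- GenomicRanges::findOverlaps(vgr, ggr)
  data.frame(
    chrom = sites$chrom[S4Vectors::queryHits(hits)],
    pos = sites$pos[S4Vectors::queryHits(hits)],
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE
  )
}

#' Assign A and B haplotype alleles at SNPs from homokaryotype depths
#'
#' Pools allelic depths across the AA samples and across the BB samples at
#' each SNP. A SNP is informative when one allele reaches the fixation
#' fraction in the AA pool while staying at or below one minus that
#' fraction in the BB pool, with both pooled depths at least
#' `min_group_depth`; that allele is the A-haplotype allele and the other
#' is the B-haplotype allele. Heterokaryotype samples never influence the
#' assignment. SNPs without AA or BB coverage are marked unassignable.
#'
#' @param v A filtered [variant_table()].
#' @param karyotypes Named vector, karyotype per sample (column) of `v`.
#' @param pairs Optional variant-to-gene pairing from
#'   [map_variants_to_genes()]; when given, `gene_id` is attached (SNPs in
#'   several genes yield several rows).
#' @param fixation Minimum pooled major-allele fraction in AA (and maximum
#'   minor fraction in BB).
#' @param min_group_depth Minimum pooled depth per homokaryotype group.
#' @return Data frame (tag-SNP table): `chrom`, `pos`, `gene_id` (NA when
#'   unpaired), `a_allele` ("ref"/"alt"/NA), `aa_frac`, `bb_frac`
#'   (A-allele fractions in the pooled groups), `aa_depth`, `bb_depth`,
#'   `informative`.
#' @export
assign_tag_alleles <- function(v, karyotypes, pairs = NULL, fixation = 0.9,
                               min_group_depth = 20) {
  karyotypes <- check_karyotypes(karyotypes[colnames(v$gt)])
  aa <- karyotypes == "AA"; bb <- karyotypes == "BB"
  pool <- function(m, sel) rowSums(m[, sel, drop = FALSE], na.rm = TRUE)
  aa_ref <- pool(v$ad_ref, aa); aa_alt <- pool(v$ad_alt, aa)
  bb_ref <- pool(v$ad_ref, bb); bb_alt <- pool(v$ad_alt, bb)
  aa_tot <- aa_ref + aa_alt; bb_tot <- bb_ref + bb_alt
  frac_aa_ref <- ifelse(aa_tot > 0, aa_ref / aa_tot, NA_real_)
  frac_bb_ref <- ifelse(bb_tot > 0, bb_ref / bb_tot, NA_real_)
  covered <- aa_tot > 0 & bb_tot > 0
  ref_is_a <- covered & frac_aa_ref >= fixation & frac_bb_ref <= 1 - fixation
  alt_is_a <- covered & (1 - frac_aa_ref) >= fixation & (1 - frac_bb_ref) <= 1 - fixation
  deep <- aa_tot >= min_group_depth & bb_tot >= min_group_depth
  informative <- (ref_is_a | alt_is_a) & deep
  a_allele <- ifelse(!covered, NA_character_,
                     ifelse(ref_is_a, "ref", ifelse(alt_is_a, "alt", NA_character_)))
  out <- data.frame(
    chrom = v$sites$chrom, pos = v$sites$pos,
    a_allele = a_allele,
    aa_frac = ifelse(a_allele == "alt", 1 - frac_aa_ref, frac_aa_ref),
    bb_frac = ifelse(a_allele == "alt", 1 - frac_bb_ref, frac_bb_ref),
    aa_depth = aa_tot, bb_depth = bb_tot,
    informative = informative, unassignable = !covered,
    stringsAsFactors = FALSE
  )
  if (!is.null(pairs)) {
    key <- paste(out$chrom, out$pos)
    pk <- paste(pairs$chrom, pairs$pos)
    idx <- match(pk, key)
    paired <- cbind(pairs["gene_id"], out[idx, , drop = FALSE])
    rownames(paired) <- NULL
    paired
  } else {
    out$gene_id <- NA_character_
    out
  }
}

#' Per-gene, per-sample A-allele expression proportion
#'
#' For each gene with informative tag SNPs and each sample,
#' `p_A = sum(depth of A allele) / sum(total depth)` over the informative
#' SNPs of the gene. Samples with zero informative depth are flagged
#' undefined rather than dropped.
#'
#' @param tags Tag-SNP table from [assign_tag_alleles()] with `gene_id`.
#' @param v The [variant_table()] carrying the allelic depths.
#' @param meta Optional metadata with `sample_id` and `tissue`.
#' @return Data frame: `gene_id`, `sample_id`, `tissue`, `p_a`,
#'   `total_depth`, `n_snps`, `undefined`.
#' @export
ase_proportion <- function(tags, v, meta = NULL) {
  tags <- tags[tags$informative & !is.na(tags$gene_id), , drop = FALSE]
  key <- paste(v$sites$chrom, v$sites$pos)
  samples <- colnames(v$ad_ref)
  out <- list()
  for (g in unique(tags$gene_id)) {
    tg <- tags[tags$gene_id == g, , drop = FALSE]
    rows <- match(paste(tg$chrom, tg$pos), key)
    a_dep <- ifelse(matrix(tg$a_allele == "ref", length(rows), length(samples)),
                    v$ad_ref[rows, , drop = FALSE], v$ad_alt[rows, , drop = FALSE])
    tot <- v$ad_ref[rows, , drop = FALSE] + v$ad_alt[rows, , drop = FALSE]
    a_sum <- colSums(a_dep, na.rm = TRUE)
    t_sum <- colSums(tot, na.rm = TRUE)
    out[[g]] <- data.frame(
      gene_id = g, sample_id = samples,
      tissue = if (!is.null(meta)) meta$tissue[match(samples, meta$sample_id)] else NA_character_,
      p_a = ifelse(t_sum > 0, a_sum / t_sum, NA_real_),
      total_depth = t_sum, n_snps = nrow(tg),
      undefined = t_sum == 0,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify the heterokaryotype dominance pattern of a gene
#'
#' The dominance score per development group is
#' \deqn{\delta = (\mu_{AB} - \mu_{BB}) / (\mu_{AA} - \mu_{BB})}
#' on mean log-CPM, so \eqn{\delta = 1} means the heterokaryotype matches
#' AA and \eqn{\delta = 0} means it matches BB, regardless of which
#' homokaryotype is higher. Per group the call is A-like
#' (\eqn{\delta \ge 1 - \tau}), B-like (\eqn{\delta \le \tau}) or
#' intermediate; the two group calls combine into the pattern classes. The
#' gene is `unclassified` when the homokaryotype separation is below
#' `min_effect_log2` in either group.
#'
#' @param means Matrix 2 x 3 of mean log-CPM, rows `EARLY`/`LATE`, columns
#'   `AA`/`AB`/`BB` (or a named vector like `AA.EARLY`).
#' @param tau Closeness margin for calling A-like / B-like.
#' @param min_effect_log2 Minimum |mu_AA - mu_BB| per group.
#' @return List: `pattern`, `delta` (per group), `group_call`.
#' @export
classify_pattern <- function(means, tau = 0.25, min_effect_log2 = 1.0) {
  if (!is.matrix(means)) {
    m <- matrix(NA_real_, 2, 3, dimnames = list(STAGE_GROUPS, KARYOTYPES))
    for (grp in STAGE_GROUPS) for (k in KARYOTYPES) {
      m[grp, k] <- means[[paste(k, grp, sep = ".")]]
    }
    means <- m
  }
  if (anyNA(means)) stop("all six karyotype x group cell means are required")
  delta <- calls <- setNames(rep(NA_real_, 2), STAGE_GROUPS)
  calls <- setNames(rep(NA_character_, 2), STAGE_GROUPS)
  for (grp in STAGE_GROUPS) {
    sep <- means[grp, "AA"] - means[grp, "BB"]
    if (abs(sep) < min_effect_log2) {
      return(list(pattern = "unclassified", delta = delta, group_call = calls))
    }
    d <- (means[grp, "AB"] - means[grp, "BB"]) / sep
    delta[grp] <- d
    calls[grp] <- if (d >= 1 - tau) "A" else if (d <= tau) "B" else "intermediate"
  }
  a <- calls["EARLY"]; b <- calls["LATE"]
  pattern <-
    if (a == "A" && b == "A") "A_dominant"
    else if (a == "B" && b == "B") "B_dominant"
    else if (a == "intermediate" && b == "intermediate") "intermediate"
    else if (a == "intermediate" || b == "intermediate") "divergent_over_time"
    else "switching"
  list(pattern = pattern, delta = delta, group_call = calls)
}

#' Mean log-CPM per karyotype x stage-group cell for every gene
#'
#' @param logcpm Matrix genes x samples.
#' @param meta Metadata with `sample_id`, `karyotype`, `stage_group`.
#' @return Array genes x 2 groups x 3 karyotypes, plus dimnames.
#' @export
karyotype_group_means <- function(logcpm, meta) {
  meta <- meta[match(colnames(logcpm), meta$sample_id), , drop = FALSE]
  out <- array(NA_real_, dim = c(nrow(logcpm), 2, 3),
               dimnames = list(rownames(logcpm), STAGE_GROUPS, KARYOTYPES))
  for (grp in STAGE_GROUPS) for (k in KARYOTYPES) {
    sel <- meta$stage_group == grp & check_karyotypes(meta$karyotype) == k
    if (any(sel)) out[, grp, k] <- rowMeans(logcpm[, sel, drop = FALSE])
  }
  out
}
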