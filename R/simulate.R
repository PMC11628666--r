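#' Default study design: karyotype x timepoint cell counts
#'
#' Twelve AA, ten AB and ten BB juvenile males spread over the four testis
#' developmental timepoints (32 birds in total); each bird contributes one
#' testis and one liver sample.
#'
#' @return Data frame with columns `karyotype`, `timepoint`, `n_birds`.
#' @export
default_design <- function() {
  data.frame(
    karyotype = rep(c("AA", "AB", "BB"), each = 4),
    timepoint = rep(1:4, times = 3),
    n_birds   = c(3, 3, 3, 3,  2, 3, 2, 3,  2, 2, 3, 3)
  )
}

#' Default inversion regions on chromosome Z (basepairs, 0-based half-open)
#' @return Data frame with `start_bp`, `end_bp`.
#' @export
default_inversion_regions <- function() {
  data.frame(
    start_bp = c(22.5e6, 33.5e6, 64.0e6),
    end_bp   = c(27.9e6, 39.9e6, 68.9e6)
  )
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic dataset: the design
#' (karyotype x timepoint cell sizes, applied to both tissues), gene content
#' per chromosome, negative-binomial count model, planted cis (inside the
#' inversion on Z) and trans (autosomal) karyotype effects, allele-specific
#' expression cases, diagnostic-SNP density and fixation, and sequencing
#' depth at SNPs.
#'
#' @param seed Master seed; all component substreams are derived from it.
#' @param n_autosomal_genes,n_z_genes Gene counts on the autosomes / on Z.
#' @param chromosome_lengths Named vector of chromosome lengths in bp; must
#'   contain `"Z"`.
#' @param inversion_regions Data frame (`start_bp`, `end_bp`), 0-based
#'   half-open, non-overlapping, within Z.
#' @param design Data frame (`karyotype`, `timepoint`, `n_birds`).
#' @param nb_mean_range Range of baseline negative-binomial means per gene.
#' @param nb_dispersion NB dispersion phi (variance = mu + phi mu^2).
#' @param stage_effect_log2_sd SD of the per-gene log2 EARLY-to-LATE
#'   developmental effect in testis (liver has none).
#' @param cis_effect_log2fc,trans_effect_log2fc Planted AA-vs-BB log2 fold
#'   changes for cis and trans DE genes.
#' @param n_cis_de,n_trans_de Numbers of planted cis / trans DE genes.
#' @param ase_genes `NULL` (plant one tissue-specific monoallelic case
#'   automatically: A-proportion 0.95 in testis, 0.5 in liver, on the first
#'   cis gene) or a data frame (`gene`, `tissue`, `p_a`).
#' @param snp_density_per_mb Expected SNPs per Mb on Z.
#' @param fixation_level Pooled major-allele read fraction for diagnostic
#'   SNPs in homokaryotypes.
#' @param mean_allelic_depth Mean per-sample read depth at a SNP (Poisson).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_autosomal_genes = 1200L,
                       n_z_genes = 400L,
                       chromosome_lengths = c("1" = 118e6, "2" = 150e6, "Z" = 73e6),
                       inversion_regions = default_inversion_regions(),
                       design = default_design(),
                       nb_mean_range = c(20, 500),
                       nb_dispersion = 0.1,
                       stage_effect_log2_sd = 1.0,
                       cis_effect_log2fc = 2.0,
                       trans_effect_log2fc = 1.5,
                       n_cis_de = 50L,
                       n_trans_de = 50L,
                       ase_genes = NULL,
                       snp_density_per_mb = 2.0,
                       fixation_level = 0.98,
                       mean_allelic_depth = 50) {
  cfg <- list(
    seed = seed, n_autosomal_genes = n_autosomal_genes, n_z_genes = n_z_genes,
    chromosome_lengths = chromosome_lengths, inversion_regions = inversion_regions,
    design = design, nb_mean_range = nb_mean_range, nb_dispersion = nb_dispersion,
    stage_effect_log2_sd = stage_effect_log2_sd,
    cis_effect_log2fc = cis_effect_log2fc, trans_effect_log2fc = trans_effect_log2fc,
    n_cis_de = n_cis_de, n_trans_de = n_trans_de, ase_genes = ase_genes,
    snp_density_per_mb = snp_density_per_mb, fixation_level = fixation_level,
    mean_allelic_depth = mean_allelic_depth
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @noRd
validate_sim_config <- function(cfg) {
  if (length(cfg$seed) != 1 || is.na(cfg$seed)) config_error("seed", "must be a single integer")
  if (cfg$n_autosomal_genes < 0) config_error("n_autosomal_genes", "must be >= 0")
  if (cfg$n_z_genes < 0) config_error("n_z_genes", "must be >= 0")
  if (!"Z" %in% names(cfg$chromosome_lengths)) {
    config_error("chromosome_lengths", "must include chromosome 'Z'")
  }
  if (any(cfg$chromosome_lengths <= 0)) config_error("chromosome_lengths", "lengths must be positive")
  ir <- cfg$inversion_regions
  if (nrow(ir) > 0) {
    if (any(ir$start_bp < 0) || any(ir$end_bp > cfg$chromosome_lengths[["Z"]])) {
      config_error("inversion_regions", "regions must lie within chromosome Z")
    }
    if (any(ir$end_bp <= ir$start_bp)) config_error("inversion_regions", "end_bp must exceed start_bp")
    o <- order(ir$start_bp)
    if (nrow(ir) > 1 && any(ir$start_bp[o][-1] < ir$end_bp[o][-nrow(ir)])) {
      config_error("inversion_regions", "regions must be non-overlapping")
    }
  }
  d <- cfg$design
  if (!all(c("karyotype", "timepoint", "n_birds") %in% names(d))) {
    config_error("design", "needs columns karyotype, timepoint, n_birds")
  }
  check_karyotypes(d$karyotype)
  if (any(d$n_birds < 0)) config_error("design", "n_birds must be >= 0")
  if (!all(d$timepoint %in% 1:4)) config_error("design", "timepoint must be 1..4")
  if (length(cfg$nb_mean_range) != 2 || any(cfg$nb_mean_range <= 0) ||
      diff(cfg$nb_mean_range) < 0) {
    config_error("nb_mean_range", "must be two increasing positive values")
  }
  if (cfg$nb_dispersion <= 0) config_error("nb_dispersion", "must be > 0")
  if (cfg$n_cis_de < 0) config_error("n_cis_de", "must be >= 0")
  if (cfg$n_trans_de < 0) config_error("n_trans_de", "must be >= 0")
  if (cfg$n_trans_de > cfg$n_autosomal_genes) config_error("n_trans_de", "exceeds autosomal gene count")
  if (!is.null(cfg$ase_genes)) {
    if (!all(c("gene", "tissue", "p_a") %in% names(cfg$ase_genes))) {
      config_error("ase_genes", "needs columns gene, tissue, p_a")
    }
    if (any(cfg$ase_genes$p_a < 0 | cfg$ase_genes$p_a > 1)) {
      config_error("ase_genes", "p_a must lie in [0, 1]")
    }
    if (!all(cfg$ase_genes$tissue %in% TISSUES)) config_error("ase_genes", "tissue must be testis or liver")
  }
  if (cfg$snp_density_per_mb <= 0) config_error("snp_density_per_mb", "must be > 0")
  if (cfg$fixation_level < 0 || cfg$fixation_level > 1) {
    config_error("fixation_level", "must lie in [0, 1]")
  }
  if (cfg$mean_allelic_depth <= 0) config_error("mean_allelic_depth", "must be > 0")
  invisible(cfg)
}

#' Count matrix with gene annotation
#'
#' @param counts Integer matrix, genes x samples, with row and column names.
#' @param genes Data frame with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `biotype`, covering every row of `counts`.
#' @return Object of class `count_matrix`.
#' @export
count_matrix <- function(counts, genes) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts))) stop("counts must have gene row names")
  if (anyDuplicated(rownames(counts))) stop("duplicated gene ids in counts")
  if (anyDuplicated(colnames(counts))) stop("duplicated sample ids in counts")
  if (!all(rownames(counts) %in% genes$gene_id)) {
    stop("gene annotation must cover every gene row")
  }
  genes <- genes[match(rownames(counts), genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(counts = counts, genes = genes), class = "count_matrix")
}

#' @exportS3Method base::print
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples on chromosome(s) %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$genes$chrom), collapse = ", ")))
  invisible(x)
}

#' @exportS3Method base::dim
dim.count_matrix <- function(x) dim(x$counts)

#' @noRd
pattern_delta <- function(pattern) {
  switch(pattern,
    A_dominant         = c(0.95, 0.95),
    B_dominant         = c(0.05, 0.05),
    intermediate       = c(0.50, 0.50),
    divergent_over_time = c(0.50, 0.95),
    switching          = c(0.95, 0.05),
    stop("unknown dominance pattern: ", pattern)
  )
}

PATTERN_CLASSES <- c("A_dominant", "B_dominant", "intermediate",
                     "divergent_over_time", "switching")

#' Simulate histology section counts for one bird
#'
#' Emits elongating-spermatid (ES) and spermatogonium (SP) counts per section
#' that are consistent with the stage's histological definition: `inactive`
#' and `accelerating_I` birds have no elongating spermatids; for
#' `accelerating_II` the pooled maturation index falls in \[-0.7, 0.1\] and
#' for `active` in (0.1, 0.7\].
#'
#' @param stage One of `inactive`, `accelerating_I`, `accelerating_II`,
#'   `active`.
#' @param n_sections Number of sections (conventionally 5).
#' @param seed Seed for this bird's substream.
#' @return Data frame with `section_id`, `es`, `sp` and attribute
#'   `has_division`.
#' @export
simulate_histology <- function(stage, n_sections = 5L, seed = 1L) {
  if (!stage %in% STAGES) stop("unknown stage label: ", stage)
  empty <- data.frame(section_id = integer(0), es = integer(0), sp = integer(0))
  attr(empty, "has_division") <- stage != "inactive"
  if (n_sections == 0) return(empty)
  set.seed(seed)
  if (stage %in% c("inactive", "accelerating_I")) {
    sp <- rpois(n_sections, if (stage == "inactive") 25 else 35) + 1L
    es <- rep(0L, n_sections)
  } else {
    target_mi <- if (stage == "accelerating_II") runif(1, -0.6, 0.0) else runif(1, 0.15, 0.65)
    total <- 150L + rpois(1, 50)
    es_total <- as.integer(round(total * (1 + target_mi) / 2))
    sp_total <- total - es_total
    es <- as.integer(rmultinom(1, es_total, rep(1, n_sections)))
    sp <- as.integer(rmultinom(1, sp_total, rep(1, n_sections)))
  }
  out <- data.frame(section_id = seq_len(n_sections), es = es, sp = sp)
  attr(out, "has_division") <- stage != "inactive"
  out
}

#' @noRd
simulate_genes <- function(cfg) {
  set.seed(derive_seed(cfg$seed, "genes"))
  chroms <- names(cfg$chromosome_lengths)
  autosomes <- setdiff(chroms, "Z")
  lens <- cfg$chromosome_lengths
  n_auto_per <- if (length(autosomes) > 0) {
    as.vector(rmultinom(1, cfg$n_autosomal_genes, lens[autosomes] / sum(lens[autosomes])))
  } else integer(0)
  rows <- list()
  place <- function(chrom, n) {
    if (n == 0) return(NULL)
    start <- sort(sample.int(lens[[chrom]] - 60000L, n))
    width <- sample(5000:50000, n, replace = TRUE)
    data.frame(chrom = chrom, start = start, end = pmin(start + width, lens[[chrom]]))
  }
  for (i in seq_along(autosomes)) rows[[autosomes[i]]] <- place(autosomes[i], n_auto_per[i])
  rows[["Z"]] <- place("Z", cfg$n_z_genes)
  genes <- do.call(rbind, rows)
  rownames(genes) <- NULL
  genes$gene_id <- sprintf("gene%05d", seq_len(nrow(genes)))
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
  genes$biotype <- sample(c("protein_coding", "lncRNA"), nrow(genes),
                          replace = TRUE, prob = c(0.8, 0.2))
  genes[, c("gene_id", "chrom", "start", "end", "strand", "biotype")]
}

#' @noRd
in_regions <- function(pos0, regions) {
  # pos0: 0-based coordinate; regions 0-based half-open
  if (nrow(regions) == 0) return(rep(FALSE, length(pos0)))
  out <- rep(FALSE, length(pos0))
  for (i in seq_len(nrow(regions))) {
    out <- out | (pos0 >= regions$start_bp[i] & pos0 < regions$end_bp[i])
  }
  out
}

#' Simulate the full inversion-karyotype dataset
#'
#' Generates, from one master seed, everything the downstream analysis
#' consumes: per-tissue count matrices with negative-binomial noise and
#' planted karyotype effects (cis genes inside the Z inversion regions,
#' trans genes on the autosomes, heterokaryotype positions following the
#' planted dominance patterns), a per-tissue variant table with
#' inversion-diagnostic SNPs (near-fixed differences between AA and BB
#' inside the inversion regions, unstructured polymorphism elsewhere on Z)
#' and binomial allelic depths, histology section counts consistent with
#' each bird's planted stage, sample metadata, and a truth record.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `counts` (list of [count_matrix()] per
#'   tissue), `variants` (list of `variant_table` per tissue), `histology`,
#'   `meta`, `truth`.
#' @export
simulate_dataset <- function(cfg) {
  validate_sim_config(cfg)
  genes <- simulate_genes(cfg)

  # --- birds and metadata -------------------------------------------------
  set.seed(derive_seed(cfg$seed, "design"))
  d <- cfg$design[cfg$design$n_birds > 0, , drop = FALSE]
  bird_rows <- d[rep(seq_len(nrow(d)), d$n_birds), c("karyotype", "timepoint")]
  bird_rows$karyotype <- check_karyotypes(bird_rows$karyotype)
  n_birds <- nrow(bird_rows)
  bird_rows$bird_id <- sprintf("b%02d", seq_len(n_birds))
  bird_rows$family <- sprintf("F%d", 1 + (seq_len(n_birds) - 1L) %% 9L)
  bird_rows$stage <- STAGES[bird_rows$timepoint]
  bird_rows$stage_group <- pool_stage_groups(bird_rows$stage)
  rownames(bird_rows) <- NULL

  meta <- do.call(rbind, lapply(TISSUES, function(tis) {
    m <- bird_rows
    m$tissue <- tis
    m$sample_id <- paste(m$bird_id, tis, sep = "_")
    m
  }))
  meta <- meta[, c("sample_id", "bird_id", "karyotype", "tissue", "timepoint",
                   "stage", "stage_group", "family")]
  rownames(meta) <- NULL

  # --- planted effects ----------------------------------------------------
  set.seed(derive_seed(cfg$seed, "effects"))
  z_in_region <- genes$chrom == "Z" & in_regions(genes$start, cfg$inversion_regions)
  cis_pool <- genes$gene_id[z_in_region]
  if (cfg$n_cis_de > length(cis_pool)) {
    config_error("n_cis_de", sprintf(
      "requested %d cis DE genes but only %d genes lie inside the inversion regions",
      cfg$n_cis_de, length(cis_pool)))
  }
  cis_genes <- if (cfg$n_cis_de > 0) sort(sample(cis_pool, cfg$n_cis_de)) else character(0)
  auto_pool <- genes$gene_id[genes$chrom != "Z"]
  trans_genes <- if (cfg$n_trans_de > 0) sort(sample(auto_pool, cfg$n_trans_de)) else character(0)

  pattern <- setNames(rep(NA_character_, nrow(genes)), genes$gene_id)
  if (length(cis_genes) > 0) {
    pattern[cis_genes] <- rep(PATTERN_CLASSES, length.out = length(cis_genes))
  }

  ase <- cfg$ase_genes
  if (is.null(ase)) {
    ase <- if (length(cis_genes) > 0) {
      data.frame(gene = cis_genes[1], tissue = c("testis", "liver"), p_a = c(0.95, 0.5))
    } else {
      data.frame(gene = character(0), tissue = character(0), p_a = numeric(0))
    }
  }
  if (!all(ase$gene %in% genes$gene_id)) config_error("ase_genes", "unknown gene id")
  ase_ids <- unique(ase$gene)
  if (length(ase_ids) > 1) {
    gi <- genes[match(ase_ids, genes$gene_id), ]
    gi <- gi[order(gi$chrom, gi$start), ]
    same <- gi$chrom[-1] == gi$chrom[-nrow(gi)]
    if (any(same & gi$start[-1] < gi$end[-nrow(gi)])) {
      config_error("ase_genes",
        "allele-specific-expression genes overlap; a SNP shared by two genes cannot carry two allelic proportions")
    }
  }

  base_log2 <- runif(nrow(genes), log2(cfg$nb_mean_range[1]), log2(cfg$nb_mean_range[2]))
  names(base_log2) <- genes$gene_id
  stage_eff <- rnorm(nrow(genes), 0, cfg$stage_effect_log2_sd)
  names(stage_eff) <- genes$gene_id

  # log2 cell means per tissue: genes x (karyotype.group)
  cells <- as.vector(outer(KARYOTYPES, STAGE_GROUPS, paste, sep = "."))
  make_mu <- function(tissue) {
    mu <- matrix(rep(base_log2, length(cells)), ncol = length(cells),
                 dimnames = list(genes$gene_id, cells))
    if (tissue == "testis") {
      late <- grepl("\\.LATE$", cells)
      mu[, late] <- mu[, late] + stage_eff
    }
    add_effect <- function(g, fc, delta_e, delta_l) {
      for (grp in STAGE_GROUPS) {
        delta <- if (grp == "EARLY") delta_e else delta_l
        aa <- paste0("AA.", grp); ab <- paste0("AB.", grp); bb <- paste0("BB.", grp)
        mu[g, aa] <<- mu[g, aa] + fc / 2
        mu[g, bb] <<- mu[g, bb] - fc / 2
        mu[g, ab] <<- mu[g, bb] + delta * (mu[g, aa] - mu[g, bb])
      }
    }
    for (g in cis_genes) {
      dl <- if (tissue == "testis") pattern_delta(pattern[[g]]) else c(0.5, 0.5)
      add_effect(g, cfg$cis_effect_log2fc, dl[1], dl[2])
    }
    for (g in trans_genes) add_effect(g, cfg$trans_effect_log2fc, 0.5, 0.5)
    mu
  }
  mu_by_tissue <- lapply(setNames(TISSUES, TISSUES), make_mu)

  # --- truth: DE genes by contrast ---------------------------------------
  contrast_truth <- function(mu, pairs, groups) {
    out <- list()
    for (p in pairs) {
      ks <- strsplit(p, "-", fixed = TRUE)[[1]]
      if (is.null(groups)) {
        diff <- rowMeans(mu[, paste0(ks[1], ".", STAGE_GROUPS), drop = FALSE]) -
                rowMeans(mu[, paste0(ks[2], ".", STAGE_GROUPS), drop = FALSE])
        out[[p]] <- rownames(mu)[abs(diff) > 1e-9]
      } else {
        for (grp in groups) {
          diff <- mu[, paste0(ks[1], ".", grp)] - mu[, paste0(ks[2], ".", grp)]
          out[[paste0(p, ".", grp)]] <- rownames(mu)[abs(diff) > 1e-9]
        }
      }
    }
    out
  }
  pairs <- c("AA-AB", "AA-BB", "AB-BB")
  de_truth <- list(
    testis = contrast_truth(mu_by_tissue$testis, pairs, STAGE_GROUPS),
    liver  = contrast_truth(mu_by_tissue$liver, pairs, NULL)
  )

  # --- counts -------------------------------------------------------------
  counts <- list()
  for (tis in TISSUES) {
    set.seed(derive_seed(cfg$seed, paste0("counts_", tis)))
    m <- meta[meta$tissue == tis, , drop = FALSE]
    depth_factor <- exp(rnorm(nrow(m), 0, 0.15))
    mu <- mu_by_tissue[[tis]]
    cell <- paste(m$karyotype, m$stage_group, sep = ".")
    y <- matrix(0L, nrow(genes), nrow(m), dimnames = list(genes$gene_id, m$sample_id))
    for (i in seq_len(nrow(m))) {
      mui <- 2^mu[, cell[i]] * depth_factor[i]
      y[, i] <- rnbinom(nrow(genes), mu = mui, size = 1 / cfg$nb_dispersion)
    }
    counts[[tis]] <- count_matrix(y, genes)
  }
  meta$lib_size <- NA_real_
  for (tis in TISSUES) {
    idx <- match(colnames(counts[[tis]]$counts), meta$sample_id)
    meta$lib_size[idx] <- colSums(counts[[tis]]$counts)
  }

  # --- variants on Z ------------------------------------------------------
  set.seed(derive_seed(cfg$seed, "variants"))
  z_len <- cfg$chromosome_lengths[["Z"]]
  n_snp <- max(2L, round(cfg$snp_density_per_mb * z_len / 1e6))
  pos <- sort(sample.int(z_len, n_snp))
  # guarantee informative SNPs inside each allele-specific-expression gene
  if (nrow(ase) > 0) {
    for (g in unique(ase$gene)) {
      gi <- genes[genes$gene_id == g, ]
      if (gi$chrom == "Z") {
        extra <- gi$start + sort(sample.int(max(gi$end - gi$start - 1L, 3L), 3L))
        pos <- sort(unique(c(pos, extra + 1L)))  # to 1-based
      }
    }
  }
  n_snp <- length(pos)
  alleles <- matrix(replicate(n_snp, sample(c("A", "C", "G", "T"), 2)), nrow = 2)
  ref <- alleles[1, ]; alt <- alleles[2, ]
  diagnostic <- in_regions(pos - 1L, cfg$inversion_regions)
  a_is_ref <- runif(n_snp) < 0.5  # which allele belongs to the A haplotype

  # bird-level genotypes: alt-allele dosage
  dosage <- matrix(NA_integer_, n_snp, n_birds,
                   dimnames = list(NULL, bird_rows$bird_id))
  af_alt <- runif(n_snp, 0.05, 0.95)  # background polymorphism
  for (b in seq_len(n_birds)) {
    k <- bird_rows$karyotype[b]
    dos <- rbinom(n_snp, 2, af_alt)
    # diagnostic SNPs: genotype determined by karyotype
    alt_per_a <- ifelse(a_is_ref, 0L, 1L)   # alt dosage contributed by an A haplotype
    n_a_hap <- switch(k, AA = 2L, AB = 1L, BB = 0L)
    dos[diagnostic] <- (alt_per_a[diagnostic] * n_a_hap +
                        (1L - alt_per_a[diagnostic]) * (2L - n_a_hap))
    dosage[, b] <- dos
  }

  # map SNPs to the allele-specific-expression genes for heterokaryotype p_A
  snp_gene <- rep(NA_character_, n_snp)
  for (g in unique(ase$gene)) {
    gi <- genes[genes$gene_id == g, ]
    hit <- gi$chrom == "Z" & (pos - 1L) >= gi$start & (pos - 1L) < gi$end
    snp_gene[hit] <- g
  }

  variants <- list()
  for (tis in TISSUES) {
    set.seed(derive_seed(cfg$seed, paste0("ad_", tis)))
    m <- meta[meta$tissue == tis, , drop = FALSE]
    ns <- nrow(m)
    ad_ref <- ad_alt <- matrix(0L, n_snp, ns, dimnames = list(NULL, m$sample_id))
    for (i in seq_len(ns)) {
      b <- m$bird_id[i]
      k <- m$karyotype[i]
      depth <- rpois(n_snp, cfg$mean_allelic_depth)
      # probability a read carries the ALT allele
      p_alt <- ifelse(dosage[, b] == 0L, 0.005,
               ifelse(dosage[, b] == 2L, 0.995, 0.5))
      if (any(diagnostic)) {
        p_a_reads <- switch(k, AA = cfg$fixation_level, BB = 1 - cfg$fixation_level, AB = 0.5)
        p_a_snp <- rep(p_a_reads, n_snp)
        if (k == "AB" && nrow(ase) > 0) {
          for (r in which(ase$tissue == tis)) {
            sel <- !is.na(snp_gene) & snp_gene == ase$gene[r]
            p_a_snp[sel] <- ase$p_a[r]
          }
        }
        pa <- ifelse(a_is_ref, 1 - p_a_snp, p_a_snp)  # alt-read probability
        p_alt[diagnostic] <- pa[diagnostic]
      }
      av <- rbinom(n_snp, depth, p_alt)
      ad_alt[, i] <- av
      ad_ref[, i] <- depth - av
    }
    dp <- ad_ref + ad_alt
    gt <- matrix(c("0/0", "0/1", "1/1")[dosage[, m$bird_id, drop = FALSE] + 1L],
                 n_snp, ns, dimnames = list(NULL, m$sample_id))
    sites <- data.frame(
      chrom = "Z", pos = pos, ref = ref, alt = alt,
      qual = 3000, dp_info = rowSums(dp), indel = FALSE
    )
    variants[[tis]] <- variant_table(
      sites = sites, gt = gt, dp = dp,
      gq = matrix(99L, n_snp, ns, dimnames = list(NULL, m$sample_id)),
      ad_ref = ad_ref, ad_alt = ad_alt
    )
  }

  # --- histology ----------------------------------------------------------
  hist_rows <- lapply(seq_len(n_birds), function(b) {
    h <- simulate_histology(bird_rows$stage[b], 5L,
                            derive_seed(cfg$seed, paste0("hist_", bird_rows$bird_id[b])))
    if (nrow(h) == 0) return(NULL)
    data.frame(bird_id = bird_rows$bird_id[b], h)
  })
  histology <- do.call(rbind, hist_rows)
  rownames(histology) <- NULL
  division <- setNames(bird_rows$stage != "inactive", bird_rows$bird_id)

  truth <- list(
    de_genes_by_contrast = de_truth,
    ase_truth = ase,
    diagnostic_snps = data.frame(
      chrom = "Z", pos = pos[diagnostic],
      a_allele = ifelse(a_is_ref[diagnostic], "ref", "alt")
    ),
    breakpoints = sort(unique(c(cfg$inversion_regions$start_bp,
                                cfg$inversion_regions$end_bp))),
    pattern_truth = pattern[!is.na(pattern)],
    cis_genes = cis_genes, trans_genes = trans_genes,
    division = division,
    mu_log2 = mu_by_tissue
  )

  list(counts = counts, variants = variants, histology = histology,
       meta = meta, truth = truth)
}

#' Simulate a genotype matrix with one planted fixed-difference block
#'
#' A focused generator for the genotype-landscape operations: SNPs at
#' regular spacing along one chromosome, background polymorphism shared by
#' all karyotypes (binomial dosages at a common allele frequency), and —
#' inside the planted block — inversion-diagnostic genotypes (homokaryotypes
#' fixed for opposite alleles, heterokaryotypes heterozygous). Allele
#' orientation is randomised per SNP so polarization is actually exercised.
#'
#' @param n_aa,n_ab,n_bb Samples per karyotype.
#' @param chrom_len Chromosome length in bp.
#' @param spacing_bp Distance between consecutive SNPs.
#' @param block `NULL` (null chromosome) or `c(start_bp, end_bp)`.
#' @param seed Seed.
#' @return List: `dosage` (alt-allele dosage matrix, SNPs x samples),
#'   `karyotypes` (named), `positions`.
#' @export
simulate_block_genotypes <- function(n_aa = 12, n_ab = 10, n_bb = 10,
                                     chrom_len = 73e6, spacing_bp = 5e5,
                                     block = NULL, seed = 1L) {
  set.seed(seed)
  positions <- seq(round(spacing_bp / 2), chrom_len, by = spacing_bp)
  n <- length(positions)
  kt <- setNames(rep(c("AA", "AB", "BB"), c(n_aa, n_ab, n_bb)),
                 sprintf("s%02d", seq_len(n_aa + n_ab + n_bb)))
  af <- runif(n, 0.05, 0.95)
  dosage <- sapply(seq_along(kt), function(i) rbinom(n, 2, af))
  colnames(dosage) <- names(kt)
  if (!is.null(block)) {
    inside <- positions >= block[1] & positions <= block[2]
    a_dose <- ifelse(runif(n) < 0.5, 0L, 2L)  # random allele orientation
    for (i in seq_along(kt)) {
      dosage[inside, i] <- switch(kt[[i]],
        AA = a_dose[inside], BB = 2L - a_dose[inside],
        AB = rep(1L, sum(inside)))
    }
  }
  list(dosage = dosage, karyotypes = kt, positions = positions)
}
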