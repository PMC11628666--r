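#' Read a gene x sample count table (TSV, gene ids in the first column)
#'
#' @param path TSV file; first column `gene_id`, remaining columns samples.
#' @return Integer matrix with gene row names.
#' @export
read_counts <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(d[[1]])) stop("duplicated gene ids in ", path)
  m <- as.matrix(d[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m))) stop("duplicated sample ids in ", path)
  rownames(m) <- d[[1]]
  storage.mode(m) <- "integer"
  if (any(m < 0, na.rm = TRUE)) stop("negative counts in ", path)
  m
}

#' @rdname read_counts
#' @param counts Matrix to write.
#' @export
write_counts <- function(counts, path) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  d <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate the sample metadata table
#'
#' Requires `sample_id`, `karyotype` (AA / AB / BB after merging the
#' derived haplotype spellings), `tissue` (testis / liver), `timepoint`
#' (1..4); extra columns pass through.
#'
#' @param path TSV file.
#' @return Data frame.
#' @export
read_metadata <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "karyotype", "tissue", "timepoint")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0) stop("metadata misses column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(m$sample_id)) stop("duplicated sample ids in metadata")
  m$karyotype <- check_karyotypes(m$karyotype)
  if (!all(m$tissue %in% TISSUES)) {
    stop("unknown tissue label(s): ", paste(setdiff(m$tissue, TISSUES), collapse = ", "))
  }
  if (!all(m$timepoint %in% 1:4)) stop("timepoint must be 1..4")
  m
}

#' @rdname read_metadata
#' @param meta Data frame to write.
#' @export
write_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation from BED6 or GFF3
#'
#' BED is 0-based half-open; GFF3 is 1-based closed. Both are returned in
#' the package's internal convention: 0-based half-open `start` / `end`.
#'
#' @param path File ending in `.bed`, `.gff`, `.gff3` or `.gtf`.
#' @return Data frame `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `biotype`.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  ids <- if (!is.null(gr$name)) gr$name else
    if (!is.null(gr$ID)) gr$ID else
    if (!is.null(gr$gene_id)) gr$gene_id else
    stop("annotation must carry gene identifiers (BED name or GFF3 ID/gene_id)")
  if (anyDuplicated(ids)) stop("duplicated gene ids in ", path)
  data.frame(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = if (!is.null(gr$biotype)) as.character(gr$biotype) else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Write gene annotation as BED6 / GFF3
#'
#' @param genes Internal annotation data frame (0-based half-open).
#' @param path Output file.
#' @export
write_annotation_bed <- function(genes, path) {
  bed <- data.frame(genes$chrom, format(genes$start, scientific = FALSE, trim = TRUE),
                    format(genes$end, scientific = FALSE, trim = TRUE),
                    genes$gene_id, ".", genes$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_bed
#' @export
write_annotation_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tinvex\tgene\t%s\t%s\t.\t%s\t.\tID=%s;biotype=%s",
                     genes$chrom,
                     format(genes$start + 1, scientific = FALSE, trim = TRUE),
                     format(genes$end, scientific = FALSE, trim = TRUE),
                     genes$strand, genes$gene_id, genes$biotype))
  writeLines(lines, path)
  invisible(path)
}

#' Write a variant table as VCF 4.2 with GT:DP:GQ:AD
#'
#' @param v A [variant_table()].
#' @param path Output `.vcf` file (uncompressed text).
#' @export
write_vcf <- function(v, path) {
  samples <- colnames(v$gt)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Raw read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  fmt <- function(i) {
    gt <- v$gt[i, ]
    cell <- ifelse(is.na(gt), "./.:.:.:.",
                   paste0(gt, ":", v$dp[i, ], ":", v$gq[i, ], ":",
                          v$ad_ref[i, ], ",", v$ad_alt[i, ]))
    paste(c(v$sites$chrom[i], v$sites$pos[i], ".", v$sites$ref[i],
            v$sites$alt[i], v$sites$qual[i], "PASS",
            paste0("DP=", v$sites$dp_info[i]), "GT:DP:GQ:AD", cell),
          collapse = "\t")
  }
  writeLines(c(header, vapply(seq_len(nrow(v$sites)), fmt, character(1))), path)
  invisible(path)
}

#' Read a VCF 4.2 with GT:DP:GQ:AD into a variant table
#'
#' @param path VCF file (plain or bgzipped; parsed with vcfR).
#' @return A [variant_table()].
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  info_dp <- suppressWarnings(as.numeric(sub(".*DP=([0-9]+).*", "\\1", fix$INFO)))
  num <- function(field) {
    m <- vcfR::extract.gt(vcf, element = field, as.numeric = TRUE)
    m
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ad <- vcfR::extract.gt(vcf, element = "AD")
  split_ad <- function(k) {
    out <- suppressWarnings(as.numeric(vapply(strsplit(ad, ",", fixed = TRUE),
                                              function(x) x[k] %||% NA_character_,
                                              character(1))))
    matrix(out, nrow(ad), ncol(ad), dimnames = dimnames(ad))
  }
  sites <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)), dp_info = info_dp,
    indel = nchar(fix$REF) > 1 | nchar(fix$ALT) > 1,
    stringsAsFactors = FALSE
  )
  variant_table(sites, gt = gt, dp = num("DP"), gq = num("GQ"),
                ad_ref = split_ad(1), ad_alt = split_ad(2))
}

#' Write a simulated dataset to a directory in interchange formats
#'
#' Counts as TSV per tissue, metadata and histology as TSV, gene annotation
#' as BED6 and GFF3, variants as VCF 4.2 per tissue, truth as JSON.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tis in names(sim$counts)) {
    write_counts(sim$counts[[tis]], file.path(dir, paste0("counts_", tis, ".tsv")))
    write_vcf(sim$variants[[tis]], file.path(dir, paste0("variants_", tis, ".vcf")))
  }
  write_metadata(sim$meta, file.path(dir, "metadata.tsv"))
  write.table(sim$histology, file.path(dir, "histology.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  genes <- sim$counts[[1]]$genes
  write_annotation_bed(genes, file.path(dir, "genes.bed"))
  write_annotation_gff3(genes, file.path(dir, "genes.gff3"))
  truth <- sim$truth
  truth$mu_log2 <- NULL  # matrices are working state, not interchange
  # named atomic vectors serialise as bare arrays; keep the names
  truth$division <- as.list(truth$division)
  truth$pattern_truth <- as.list(truth$pattern_truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Default analysis parameters for the pipeline
#' @return Named list of thresholds with the documented defaults.
#' @export
default_params <- function() {
  list(alpha = 0.05, k_clusters = 10, prefilter_min = 10, prefilter_total = 320,
       window_testis = 4e6, window_liver = 8e6, steps_per_window = 4,
       window_fdr = 0.01, fixation = 0.9, min_group_depth = 20,
       tau = 0.25, min_effect_log2 = 1.0, m_snps = 11, block_threshold = 0.8)
}

#' Differential-expression stage for one tissue
#'
#' Prefilter, TMM, log-CPM, precision weights, moderated contrast fit and
#' the global significance rule, bundled for reuse by the pipeline and the
#' analysis scripts.
#'
#' @param cm A [count_matrix()].
#' @param meta Metadata restricted to (or filterable to) the tissue.
#' @param tissue `"testis"` or `"liver"`.
#' @param params See [default_params()].
#' @return List: `de` (decided [fit_moderated()] table), `retained`,
#'   `logcpm`, `weights`, `factors`, `design`, `contrasts`.
#' @export
run_de <- function(cm, meta, tissue, params = default_params()) {
  meta <- meta[meta$tissue == tissue, , drop = FALSE]
  meta <- meta[match(colnames(cm$counts), meta$sample_id), , drop = FALSE]
  cells <- table(paste(meta$karyotype, meta$stage_group, sep = "."))
  retained <- prefilter_genes(cm, params$prefilter_min, params$prefilter_total,
                              group_sizes = as.integer(cells))
  y <- cm$counts[retained, , drop = FALSE]
  f <- tmm_factors(y)
  eff <- colSums(y) * f
  lc <- log_cpm(y, eff)
  design <- design_cell_means(meta)
  w <- mean_variance_weights(lc, design)
  contrasts <- build_contrasts(tissue, cells = colnames(design))
  de <- global_decide(fit_moderated(lc, w, design, contrasts), alpha = params$alpha)
  list(de = de, retained = retained, logcpm = lc, weights = w, factors = f,
       design = design, contrasts = contrasts, meta = meta)
}

#' Run the full analysis pipeline on a (simulated or read-in) dataset
#'
#' Stages: developmental staging from histology; differential expression
#' per tissue; genomic enrichment (windows, chromosome-Z bias, Z:autosome
#' ratio); allele-specific expression and dominance patterns; inversion
#' genotype landscape. Each stage writes its tables under `out_dir` and is
#' recorded in a JSON run manifest; stages can be skipped by name.
#'
#' @param data A dataset shaped like [simulate_dataset()]'s result.
#' @param out_dir Output directory.
#' @param params Thresholds, see [default_params()].
#' @param skip Character vector of stage names to skip (among `staging`,
#'   `de`, `enrichment`, `ase`, `landscape`).
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic given the data).
#' @return List of stage results, invisibly; side effect: files under
#'   `out_dir` and `manifest.json`.
#' @export
run_pipeline <- function(data, out_dir, params = default_params(),
                         skip = character(0), seed = NA_integer_) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages_run <- character(0)
  res <- list()
  tsv <- function(d, name) {
    write.table(d, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  run_stage <- function(name, fn) {
    if (name %in% skip) return(invisible(NULL))
    out <- tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
    stages_run <<- c(stages_run, name)
    res[[name]] <<- out
    out
  }

  run_stage("staging", function() {
    st <- stage_birds(data$histology, division = data$truth$division)
    tsv(st, "staging.tsv")
    st
  })

  run_stage("de", function() {
    out <- list()
    for (tis in TISSUES) {
      r <- run_de(data$counts[[tis]], data$meta, tis, params)
      tsv(r$de, paste0("de_", tis, ".tsv"))
      de_genes <- attr(r$de, "de_genes")
      if (length(de_genes) >= params$k_clusters) {
        cl <- cluster_de_genes(r$logcpm[de_genes, , drop = FALSE],
                               k = params$k_clusters)
        tsv(data.frame(gene_id = names(cl), cluster = cl),
            paste0("clusters_", tis, ".tsv"))
        r$clusters <- cl
      }
      out[[tis]] <- r
    }
    out
  })

  if (is.null(res$de)) skip <- union(skip, "enrichment")  # depends on de
  run_stage("enrichment", function() {
    de_res <- res$de
    out <- list()
    for (tis in TISSUES) {
      r <- de_res[[tis]]
      genes <- data$counts[[tis]]$genes
      expressed <- genes[genes$gene_id %in% r$retained,
                         c("gene_id", "chrom", "start")]
      size <- if (tis == "testis") params$window_testis else params$window_liver
      we <- window_enrichment(attr(r$de, "de_genes"), expressed, size,
                              params$steps_per_window, params$window_fdr)
      tsv(we$windows, paste0("windows_", tis, ".tsv"))
      write_regions_bed(we$regions, file.path(out_dir, paste0("enriched_regions_", tis, ".bed")))
      bias <- do.call(rbind, lapply(unique(r$de$contrast), function(ct) {
        dg <- unique(r$de$gene[r$de$contrast == ct & r$de$decision != "ns"])
        b <- chrom_bias_test(dg, genes[, c("gene_id", "chrom")])
        data.frame(tissue = tis, contrast = ct, n_de_z = b$observed[["Z"]],
                   n_de_autosome = b$observed[["autosome"]],
                   x2 = b$statistic, p = b$p)
      }))
      tsv(bias, paste0("chrom_bias_", tis, ".tsv"))
      groups <- paste(r$meta$karyotype, tis, r$meta$timepoint, sep = ".")
      za <- z_autosome_ratio(r$logcpm, setNames(genes$chrom, genes$gene_id), groups)
      tsv(za, paste0("z_autosome_ratio_", tis, ".tsv"))
      out[[tis]] <- list(windows = we, bias = bias, za = za)
    }
    out
  })

  run_stage("ase", function() {
    de_res <- res$de
    out <- list()
    for (tis in TISSUES) {
      v <- filter_variants(data$variants[[tis]])
      genes <- data$counts[[tis]]$genes
      pairs <- map_variants_to_genes(v, genes[genes$chrom == "Z", ])
      kt <- setNames(data$meta$karyotype, data$meta$sample_id)
      tags <- assign_tag_alleles(v, kt, pairs, params$fixation,
                                 params$min_group_depth)
      ase <- ase_proportion(tags, v, data$meta)
      tsv(tags, paste0("tag_snps_", tis, ".tsv"))
      if (!is.null(ase)) tsv(ase, paste0("ase_", tis, ".tsv"))
      out[[tis]] <- list(tags = tags, ase = ase)
    }
    if (!is.null(de_res)) {
      r <- de_res$testis
      means <- karyotype_group_means(r$logcpm, r$meta)
      de_genes <- attr(r$de, "de_genes")
      pat <- do.call(rbind, lapply(de_genes, function(g) {
        cl <- classify_pattern(means[g, , ], params$tau, params$min_effect_log2)
        data.frame(gene_id = g, pattern = cl$pattern,
                   delta_early = cl$delta[["EARLY"]],
                   delta_late = cl$delta[["LATE"]])
      }))
      if (!is.null(pat)) tsv(pat, "dominance_patterns.tsv")
      out$patterns <- pat
    }
    out
  })

  run_stage("landscape", function() {
    v <- filter_variants(data$variants$testis, require_complete = TRUE)
    kt <- setNames(data$meta$karyotype, data$meta$sample_id)
    pol <- polarize(v, kt)
    seg <- segment_blocks(pol, kt, params$m_snps, params$block_threshold)
    tsv(data.frame(pos = attr(pol, "positions"), pol, check.names = FALSE),
        "polarized_genotypes.tsv")
    write_regions_bed(data.frame(chrom = "Z", start_bp = seg$blocks$start_bp,
                                 end_bp = seg$blocks$end_bp),
                      file.path(out_dir, "blocks.bed"))
    tsv(data.frame(breakpoint_bp = seg$breakpoints), "breakpoints.tsv")
    seg
  })

  manifest <- list(
    package = "invex",
    version = as.character(utils::packageVersion("invex")),
    seed = seed, stages = stages_run, params = params,
    outputs = list.files(out_dir)
  )
  manifest$digests <- as.list(tools::md5sum(
    file.path(out_dir, setdiff(manifest$outputs, "manifest.json"))))
  names(manifest$digests) <- basename(names(manifest$digests))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' @noRd
write_regions_bed <- function(regions, path) {
  if (nrow(regions) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  chrom <- if ("chrom" %in% names(regions)) regions$chrom else "Z"
  bed <- data.frame(chrom,
                    format(regions$start_bp, scientific = FALSE, trim = TRUE),
                    format(regions$end_bp, scientific = FALSE, trim = TRUE))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
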