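#!/usr/bin/env Rscript
# Where do the DE genes sit? Sliding-window hypergeometric enrichment
# (4 Mb testis / 8 Mb liver, 4 steps, FDR .01), Yates chi-squared test of
# chromosome-Z overrepresentation per contrast, and Z:autosome expression
# ratios per karyotype x timepoint group.
suppressMessages(library(invex))
data_dir <- "results/data"; out_dir <- "results/enrichment"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

meta <- read_metadata(file.path(data_dir, "metadata.tsv"))
genes <- read_annotation(file.path(data_dir, "genes.bed"))
for (tis in c("testis", "liver")) {
  y <- read_counts(file.path(data_dir, paste0("counts_", tis, ".tsv")))
  r <- run_de(count_matrix(y, genes), meta, tis)
  de_genes <- attr(r$de, "de_genes")
  expressed <- genes[genes$gene_id %in% r$retained, c("gene_id", "chrom", "start")]
  size <- if (tis == "testis") 4e6 else 8e6
  we <- window_enrichment(de_genes, expressed, size, 4, 0.01)
  write.table(we$windows, file.path(out_dir, paste0("windows_", tis, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d/%d windows enriched; merged regions:\n", tis,
              sum(we$windows$significant), nrow(we$windows)))
  if (nrow(we$regions)) print(we$regions) else cat("  none\n")
  bias <- chrom_bias_test(de_genes, genes[, c("gene_id", "chrom")])
  cat(sprintf("%s: DE genes on Z %d vs expected %.1f, X2 = %.1f (p = %.2g)\n",
              tis, bias$observed[["Z"]], bias$expected[["Z"]],
              bias$statistic, bias$p))
  groups <- paste(r$meta$karyotype, r$meta$timepoint, sep = ".")
  za <- z_autosome_ratio(r$logcpm, setNames(genes$chrom, genes$gene_id), groups)
  write.table(za, file.path(out_dir, paste0("z_autosome_", tis, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: Z:autosome median-logCPM ratio %.2f .. %.2f across groups\n",
              tis, min(za$ratio), max(za$ratio)))
}
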