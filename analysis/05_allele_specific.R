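#!/usr/bin/env Rscript
# Allele-specific expression at inversion-diagnostic SNPs: variant filtering,
# A/B allele assignment from the homokaryotype pools, per-gene A-allele
# proportions, and heterokaryotype dominance-pattern classes.
suppressMessages(library(invex))
data_dir <- "results/data"; out_dir <- "results/ase"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

meta <- read_metadata(file.path(data_dir, "metadata.tsv"))
genes <- read_annotation(file.path(data_dir, "genes.bed"))
kt <- setNames(meta$karyotype, meta$sample_id)
for (tis in c("testis", "liver")) {
  v <- filter_variants(read_vcf(file.path(data_dir, paste0("variants_", tis, ".vcf"))))
  pairs <- map_variants_to_genes(v, genes[genes$chrom == "Z", ])
  tags <- assign_tag_alleles(v, kt, pairs)
  ase <- ase_proportion(tags, v, meta)
  write.table(tags, file.path(out_dir, paste0("tag_snps_", tis, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ase, file.path(out_dir, paste0("ase_", tis, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  inf <- tags[tags$informative, ]
  cat(sprintf("%s: %d informative tag SNPs in %d genes\n", tis,
              nrow(inf), length(unique(inf$gene_id))))
  ab <- meta$sample_id[meta$karyotype == "AB" & meta$tissue == tis]
  pa <- ase[ase$sample_id %in% ab & !ase$undefined, ]
  agg <- tapply(pa$p_a * pa$total_depth, pa$gene_id, sum) /
    tapply(pa$total_depth, pa$gene_id, sum)
  show <- head(sort(agg), 3)
  cat(sprintf("%s heterokaryotype pooled A-proportions (3 lowest of %d genes): %s\n",
              tis, length(agg), paste(sprintf("%s=%.2f", names(show), show), collapse = " ")))
}
# dominance patterns on the testis DE genes
y <- read_counts(file.path(data_dir, "counts_testis.tsv"))
r <- run_de(count_matrix(y, genes), meta, "testis")
means <- karyotype_group_means(r$logcpm, r$meta)
de_genes <- attr(r$de, "de_genes")
pat <- do.call(rbind, lapply(de_genes, function(g) {
  cl <- classify_pattern(means[g, , ])
  data.frame(gene_id = g, pattern = cl$pattern,
             delta_early = cl$delta[["EARLY"]], delta_late = cl$delta[["LATE"]])
}))
write.table(pat, file.path(out_dir, "dominance_patterns.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("dominance patterns among testis DE genes:\n")
print(table(pat$pattern))
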