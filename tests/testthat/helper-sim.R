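# memoised default simulations so several test files can share one dataset
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(seed = 1, ...) {
  key <- paste0("s", seed, "_", paste(deparse(list(...)), collapse = ""))
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_dataset(sim_config(seed = seed, ...))
  }
  .sim_cache[[key]]
}

# pooled A-allele proportion over the AB heterokaryotypes for one gene
pooled_ab_pa <- function(sim, tissue, gene) {
  v <- filter_variants(sim$variants[[tissue]])
  kt <- setNames(sim$meta$karyotype, sim$meta$sample_id)
  genes <- sim$counts[[tissue]]$genes
  pairs <- map_variants_to_genes(v, genes[genes$chrom == "Z", ])
  tags <- assign_tag_alleles(v, kt, pairs)
  ase <- ase_proportion(tags, v, sim$meta)
  ab <- sim$meta$sample_id[sim$meta$karyotype == "AB" & sim$meta$tissue == tissue]
  a <- ase[ase$gene_id == gene & ase$sample_id %in% ab & !ase$undefined, , drop = FALSE]
  list(p_a = sum(a$p_a * a$total_depth) / sum(a$total_depth),
       depth = sum(a$total_depth))
}

# greedily pick k non-overlapping planted cis genes from a simulated dataset
pick_cis_genes <- function(sim, k = 3) {
  g <- sim$counts$testis$genes
  g <- g[match(sim$truth$cis_genes, g$gene_id), ]
  g <- g[order(g$start), ]
  chosen <- integer(0)
  last_end <- -Inf
  for (i in seq_len(nrow(g))) {
    if (g$start[i] >= last_end) {
      chosen <- c(chosen, i)
      last_end <- g$end[i]
      if (length(chosen) == k) break
    }
  }
  g$gene_id[chosen]
}
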