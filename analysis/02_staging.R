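#!/usr/bin/env Rscript
# Stage each bird from its histology sections: pooled maturation index,
# stage call, and the EARLY/LATE pooling used by the expression design.
suppressMessages(library(invex))
data_dir <- "results/data"; out_dir <- "results/staging"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

hist <- read.delim(file.path(data_dir, "histology.tsv"))
meta <- read_metadata(file.path(data_dir, "metadata.tsv"))
# spermatocyte division is a histology call the generator records in truth
truth <- jsonlite::read_json(file.path(data_dir, "truth.json"), simplifyVector = TRUE)
st <- stage_birds(hist, division = truth$division)
write.table(st, file.path(out_dir, "staging.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

tab <- table(st$stage)[c("inactive", "accelerating_I", "accelerating_II", "active")]
cat("stage counts:", paste(names(tab), tab, sep = "="), "\n")
planted <- meta$stage[match(st$bird_id, meta$bird_id)]
cat(sprintf("agreement with planted stages: %.0f%%\n", 100 * mean(st$stage == planted)))
cat("maturation index range:", sprintf("%.2f .. %.2f (finite values)\n",
    min(st$mi, na.rm = TRUE), max(st$mi, na.rm = TRUE)))
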