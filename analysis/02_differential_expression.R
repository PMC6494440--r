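#!/usr/bin/env Rscript

# Stage 2 -- differential expression over the six-genotype design:
# expression filter (CPM >= 1 in >= 1 sample), TMM normalization, moderated
# group-means linear models on log2-CPM, per-contrast tables and directional
# signatures at FDR <= 0.05.

suppressPackageStartupMessages(library(netkda))
outdir <- "results/de"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

counts <- load_counts("results/data/counts.tsv", "results/data/metadata.tsv")
de <- run_de(counts)
message(sprintf("%d of %d genes pass the expression filter",
                nrow(de$filtered$counts), nrow(counts$counts)))
for (nm in names(de$tables)) {
  write.table(de$tables[[nm]], file.path(outdir, paste0("de_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  s <- de$signatures[[nm]]
  message(sprintf("%-14s %3d up / %3d down DEGs", nm,
                  length(s$up), length(s$down)))
}
coll <- collect_signatures(de)
write_gmt(coll$signatures, file.path(outdir, "signatures.gmt"))
message("signatures written to ", file.path(outdir, "signatures.gmt"))
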