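#!/usr/bin/env Rscript

# Stage 3 -- direction-aware signature intersection: every pair of
# directional signatures is tested for overlap enrichment (one-sided FET +
# fold enrichment) within the expressed-gene universe, BH-adjusted across
# the family. The planted reversal (up in amyloid, down after driver
# knockout) should dominate.

suppressPackageStartupMessages(library(netkda))
dir.create("results/overlap", showWarnings = FALSE, recursive = TRUE)

counts <- load_counts("results/data/counts.tsv", "results/data/metadata.tsv")
de <- run_de(counts)
coll <- collect_signatures(de)
ov <- overlap_matrix(coll)
write.table(ov, "results/overlap/overlap.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
top <- ov[1, ]
message(sprintf(
  "top pair: %s ~ %s | %d shared genes | %.1f-fold | adj. p = %.3g",
  top$set1, top$set2, top$overlap, top$fold_enrichment, top$adjusted_p))

truth <- jsonlite::read_json("results/data/truth_counts.json",
                             simplifyVector = TRUE)
planted <- truth$planted_up_in_APP
shared <- intersect(coll$signatures[[top$set1]], coll$signatures[[top$set2]])
message(sprintf("%d of the %d shared genes are planted module genes",
                length(intersect(shared, planted)), length(shared)))
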