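#!/usr/bin/env Rscript

# Stage 1 -- generate the synthetic study data with planted ground truth:
# a 24-sample six-genotype count matrix (planted amyloid-induced module,
# reverted by driver knockout), a planted-driver causal network, and a
# latent-factor co-expression matrix. Everything downstream reads the files
# written here.

suppressPackageStartupMessages(library(netkda))
seed <- as.integer(Sys.getenv("NETKDA_SEED", "1"))
outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
cfg <- simulation_config(seed = seed)
hdr <- paste("seed:", seed)

sim <- simulate_counts(cfg)
write_counts(sim$counts, file.path(outdir, "counts.tsv"),
             file.path(outdir, "metadata.tsv"), hdr)
jsonlite::write_json(sim$truth, file.path(outdir, "truth_counts.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message(sprintf("counts: %d genes x %d samples; %d planted module genes",
                nrow(sim$counts$counts), ncol(sim$counts$counts),
                length(sim$truth$planted_up_in_APP)))

net <- simulate_causal_network(cfg)
write_network(net$network, file.path(outdir, "network.tsv"), hdr)
jsonlite::write_json(net$truth, file.path(outdir, "truth_network.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message(sprintf("network: %d nodes, %d edges; driver %s with layers %s",
                length(net$network$nodes), nrow(net$network$edges),
                net$truth$planted_driver,
                paste(lengths(net$truth$planted_layers), collapse = "/")))

cx <- simulate_coexpression(cfg)
tab <- data.frame(gene = rownames(cx$expression), cx$expression,
                  check.names = FALSE)
write.table(tab, file.path(outdir, "coexpression.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(gene = names(cx$truth), module = unname(cx$truth)),
            file.path(outdir, "coexpression_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("co-expression: %d genes x %d samples",
                nrow(cx$expression), ncol(cx$expression)))
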