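read_tsv_table <- function(path, ...) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_tsv_table <- function(x, path, header_lines = character(0),
                            row_names = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = row_names,
                     col.names = if (row_names) NA else TRUE)
  invisible(path)
}

#' Write a count matrix and its sample metadata
#'
#' @param x A `count_matrix`.
#' @param counts_path TSV path for counts (first column `gene`).
#' @param metadata_path TSV path for metadata (`sample_id`, `genotype`).
#' @param header_lines Optional comment lines (e.g. seed, config hash).
#' @return Invisibly, the two paths.
#' @export
write_counts <- function(x, counts_path, metadata_path,
                         header_lines = character(0)) {
  stopifnot(inherits(x, "count_matrix"))
  tab <- data.frame(gene = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_table(tab, counts_path, header_lines)
  meta <- data.frame(sample_id = colnames(x$counts),
                     genotype = as.character(x$genotype),
                     stringsAsFactors = FALSE)
  write_tsv_table(meta, metadata_path, header_lines)
  invisible(c(counts_path, metadata_path))
}

#' Load a count matrix with genotype metadata
#'
#' The counts TSV carries gene symbols in the first column and one column
#' per sample; the metadata TSV needs `sample_id` and `genotype` columns
#' covering every sample. Lines starting with `#` are ignored.
#'
#' @param counts_path,metadata_path File paths.
#' @return A validated [count_matrix()].
#' @export
load_counts <- function(counts_path, metadata_path) {
  tab <- read_tsv_table(counts_path)
  if (ncol(tab) < 2L) stop("counts file needs a gene column plus samples")
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes)) {
    stop("duplicated gene symbol(s) in counts: ",
         paste(utils::head(unique(genes[duplicated(genes)]), 5),
               collapse = ", "))
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m) || any(m != round(m)) || any(m < 0)) {
    stop("counts must be non-negative integers")
  }
  rownames(m) <- genes
  meta <- read_tsv_table(metadata_path)
  if (!all(c("sample_id", "genotype") %in% names(meta))) {
    stop("metadata needs sample_id and genotype columns")
  }
  missing <- setdiff(colnames(m), meta$sample_id)
  if (length(missing)) {
    stop("metadata missing sample(s): ", paste(missing, collapse = ", "))
  }
  genotype <- stats::setNames(meta$genotype, meta$sample_id)[colnames(m)]
  count_matrix(m, genotype)
}

#' Load a directed network edge list
#'
#' `edge_tsv` expects 2-3 columns (source, target, optional cohort);
#' `sif` expects the simple-interaction dialect (source, relation, target).
#' Self-loops are dropped with a warning reporting how many.
#'
#' @param path File path.
#' @param dialect `"edge_tsv"` or `"sif"`.
#' @param name Network label; defaults to the file name.
#' @return A [causal_network()].
#' @export
load_network <- function(path, dialect = c("edge_tsv", "sif"), name = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t| +")
  nf <- lengths(parts)
  min_cols <- if (dialect == "sif") 3L else 2L
  bad <- which(nf < min_cols)
  if (length(bad)) {
    stop("malformed network line ", bad[1], ": '", lines[bad[1]], "'")
  }
  if (dialect == "sif") {
    edges <- data.frame(from = vapply(parts, `[`, "", 1),
                        to = vapply(parts, `[`, "", 3),
                        cohort = name, stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = vapply(parts, `[`, "", 1),
                        to = vapply(parts, `[`, "", 2),
                        cohort = vapply(parts, function(p) {
                          if (length(p) >= 3) p[3] else name
                        }, ""), stringsAsFactors = FALSE)
  }
  loops <- edges$from == edges$to
  if (any(loops)) {
    warning("dropped ", sum(loops), " self-loop(s) from ", basename(path))
    edges <- edges[!loops, , drop = FALSE]
  }
  if (nrow(edges) == 0L) stop("no edges left in ", path)
  causal_network(edges, name = name)
}

#' Write a network edge list as TSV
#'
#' @param network A `causal_network`.
#' @param path Output path.
#' @param header_lines Optional comment lines.
#' @return Invisibly, the path.
#' @export
write_network <- function(network, path, header_lines = character(0)) {
  stopifnot(inherits(network, "causal_network"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(network$edges, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write gene sets in GMT format
#'
#' One set per line: name, description, then the genes, tab-separated.
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Per-set description (recycled). Default "na".
#' @return Invisibly, the path.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) < 2L)) stop("malformed GMT line in ", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1)
  if (anyDuplicated(names(sets))) stop("duplicated set names in ", path)
  sets
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(config[order(names(unclass(config)))]),
                   collapse = ""), tmp)
  unname(tools::md5sum(tmp))
}

#' Pipeline configuration
#'
#' Bundles input paths (or NULL to simulate), the statistical and simulation
#' configurations, the contrast list, and the output directory.
#'
#' @param counts_path,metadata_path Paths to count and metadata TSVs; when
#'   NULL, counts are simulated from `sim`.
#' @param network_paths Character vector of edge-list paths (unioned); when
#'   NULL and `simulate_network` is TRUE a planted-driver network is
#'   simulated; when NULL otherwise the key-driver stage is skipped.
#' @param driver_gene Seed gene for the layered-neighborhood report; default
#'   the simulated planted driver (required for file-based networks).
#' @param simulate_network Simulate the causal network when no paths are
#'   given. Default TRUE.
#' @param stats A [stats_config()].
#' @param sim A [simulation_config()].
#' @param contrasts Named list of genotype pairs; NULL for the defaults.
#' @param outdir Output directory (created if needed).
#' @param seed Seed recorded in outputs and forwarded to `sim`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_path = NULL, metadata_path = NULL,
                            network_paths = NULL, driver_gene = NULL,
                            simulate_network = TRUE,
                            stats = stats_config(),
                            sim = NULL, contrasts = NULL,
                            outdir = "netkda_out", seed = 1) {
  if (is.null(sim)) sim <- simulation_config(seed = seed)
  structure(list(counts_path = counts_path, metadata_path = metadata_path,
                 network_paths = network_paths, driver_gene = driver_gene,
                 simulate_network = simulate_network, stats = stats,
                 sim = sim, contrasts = contrasts, outdir = outdir,
                 seed = seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load -> differential expression -> signature
#' overlap -> key-driver analysis -> co-expression modules, writing every
#' stage table under `config$outdir` plus a machine-readable `manifest.json`
#' recording the seed, a config hash, and per-stage input/output counts.
#' A rerun with the same config is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(unclass(config)[setdiff(names(unclass(config)),
                                              "outdir")])
  hdr <- c(paste("seed:", config$seed), paste("config:", hash))
  out <- function(...) file.path(config$outdir, paste0(...))
  manifest <- list(seed = config$seed, config_hash = hash, stages = list())
  stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    res
  }

  # -- stage 1: data -----------------------------------------------------
  truth <- NULL
  if (is.null(config$counts_path)) {
    simres <- stage("simulate", function() simulate_counts(config$sim))
    counts <- simres$counts
    truth <- simres$truth
    write_counts(counts, out("counts.tsv"), out("metadata.tsv"), hdr)
    jsonlite::write_json(truth, out("truth_counts.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    counts <- stage("load", function() {
      load_counts(config$counts_path, config$metadata_path)
    })
  }
  manifest$stages$data <- list(status = "ok", genes = nrow(counts$counts),
                               samples = ncol(counts$counts),
                               simulated = is.null(config$counts_path))

  # -- stage 2: differential expression ---------------------------------
  de <- stage("de", function() {
    run_de(counts, contrasts = config$contrasts,
           fdr_threshold = config$stats$fdr_threshold)
  })
  for (nm in names(de$tables)) {
    write_tsv_table(de$tables[[nm]], out("de_", nm, ".tsv"), hdr)
  }
  collection <- collect_signatures(de)
  write_gmt(collection$signatures, out("signatures.gmt"))
  manifest$stages$de <- list(
    status = "ok",
    genes_expressed = nrow(de$filtered$counts),
    deg_counts = lapply(de$signatures, function(s) {
      list(up = length(s$up), down = length(s$down))
    }))

  # -- stage 3: signature overlap ---------------------------------------
  ov <- stage("overlap", function() overlap_matrix(collection))
  write_tsv_table(ov, out("overlap.tsv"), hdr)
  manifest$stages$overlap <- list(status = "ok", pairs = nrow(ov))

  # -- stage 4: key-driver analysis -------------------------------------
  kda <- NULL
  if (!is.null(config$network_paths)) {
    nets <- lapply(config$network_paths, load_network)
    network <- union_network(nets)
    driver <- config$driver_gene
    net_truth <- NULL
  } else if (config$simulate_network) {
    netres <- stage("simulate_network", function() {
      simulate_causal_network(config$sim)
    })
    network <- netres$network
    net_truth <- netres$truth
    driver <- if (is.null(config$driver_gene)) net_truth$planted_driver
              else config$driver_gene
    write_network(network, out("network.tsv"), hdr)
    jsonlite::write_json(net_truth, out("truth_network.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    network <- NULL
  }
  if (is.null(network)) {
    manifest$stages$kda <- list(status = "skipped",
                                reason = "no network provided")
  } else {
    kda <- stage("kda", function() {
      sig_name <- if ("APPko_vs_APP" %in% names(de$signatures))
        "APPko_vs_APP" else names(de$signatures)[1]
      sig <- de$signatures[[sig_name]]
      universe <- intersect(network$nodes, rownames(de$filtered$counts))
      down <- intersect(sig$down, universe)
      signature <- if (length(down)) down else
        intersect(union(sig$up, sig$down), universe)
      nb <- if (!is.null(driver) && driver %in% network$nodes) {
        downstream_layers(network, driver, max_depth = 4)
      }
      list(signature_name = sig_name,
           layers = nb,
           layer_table = if (!is.null(nb) && length(signature))
             layer_enrichment(nb, signature, universe) else NULL,
           ranking = if (length(signature))
             rank_key_drivers(network, signature, universe) else NULL)
    })
    if (!is.null(kda$layers)) {
      sets <- stats::setNames(kda$layers$layers,
                              paste0(kda$layers$seed, "_L",
                                     seq_along(kda$layers$layers)))
      write_gmt(sets, out("neighborhood.gmt"))
    }
    if (!is.null(kda$layer_table)) {
      write_tsv_table(kda$layer_table, out("layer_enrichment.tsv"), hdr)
    }
    if (!is.null(kda$ranking)) {
      write_tsv_table(as.data.frame(kda$ranking), out("driver_ranking.tsv"),
                      hdr)
    }
    manifest$stages$kda <- list(
      status = "ok", nodes = length(network$nodes),
      edges = nrow(network$edges),
      signature = kda$signature_name,
      top_driver = if (!is.null(kda$ranking)) kda$ranking$gene[1] else NA)
  }

  # -- stage 5: co-expression modules -----------------------------------
  modres <- stage("modules", function() {
    cx <- simulate_coexpression(config$sim)
    tom <- topological_overlap(correlation_adjacency(cx$expression))
    part <- detect_modules(tom)
    sig <- names(cx$truth)[cx$truth == "module_1"]
    list(partition = part,
         enrichment = module_enrichment(part, sig),
         truth = cx$truth)
  })
  write_tsv_table(data.frame(gene = names(modres$partition$labels),
                             module = unname(modres$partition$labels),
                             stringsAsFactors = FALSE),
                  out("module_partition.tsv"), hdr)
  write_tsv_table(modres$enrichment, out("module_enrichment.tsv"), hdr)
  manifest$stages$modules <- list(
    status = "ok",
    n_modules = sum(names(modres$partition$sizes) != "unassigned"))

  # -- stage 6: report ----------------------------------------------------
  manifest$stages$report <- list(status = "ok")
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(counts = counts, truth = truth, de = de, overlap = ov,
                 kda = kda, modules = modres, manifest = manifest))
}
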