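#' Simulation configuration
#'
#' Defaults emulate the study design the workflow targets: 24 RNA-seq
#' samples over six genotypes (4/3/4/4/4/5), a 100-gene module upregulated
#' 4-fold (log2FC 2) by the amyloid genotype with 80% of the shift removed
#' by driver knockout (half of that in heterozygotes), negative-binomial
#' counts at dispersion 0.1 and 8-12 million reads per sample; a 1000-node
#' planted-driver causal network whose first four downstream layers
#' (25/50/100/150 nodes) concentrate the planted module; and a
#' latent-factor co-expression design of five 60-gene modules plus 200
#' background genes over 50 samples.
#'
#' @param n_genes Number of genes in the count simulation. Default 5000.
#' @param group_sizes Named integer vector of per-genotype sample counts.
#' @param planted_module_size Genes in the planted amyloid-induced module
#'   (0 for a global-null simulation). Default 100.
#' @param planted_log2fc Log2 fold change of planted genes in the amyloid
#'   genotype vs wild type. Default 2.
#' @param reversal_fraction Fraction of the planted shift removed by driver
#'   knockout on the amyloid background, in [0, 1]. Default 0.8.
#' @param het_effect Heterozygote gene-dose: fraction of the knockout
#'   reversal seen in `APP_PSEN1_het` (0 reproduces a silent-het design).
#'   Default 0.5.
#' @param nb_dispersion Negative-binomial dispersion (0 gives Poisson).
#'   Default 0.1.
#' @param library_size_range Uniform range of per-sample sequencing depth.
#'   Default c(8e6, 12e6).
#' @param n_network_nodes Nodes in the simulated causal network. Default 1000.
#' @param layer_sizes Sizes of the planted driver's downstream layers.
#'   Default c(25, 50, 100, 150).
#' @param layer_planted_fraction Fraction of each layer drawn from the
#'   planted module. Default c(0.6, 0.45, 0.3, 0.2).
#' @param extra_parent_rate Poisson rate of additional previous-layer parents
#'   per layer node (each has at least one). Default 0.5.
#' @param background_parent_rate Poisson rate of parents per background
#'   node. Default 1.2.
#' @param coexpr_modules,coexpr_module_size,coexpr_background Number of
#'   co-expression modules, genes per module, unstructured background genes.
#'   Defaults 5, 60, 200.
#' @param coexpr_samples Samples in the co-expression simulation. Default 50.
#' @param loading_range Uniform range of per-gene factor loadings
#'   (`c(0, 0)` removes all module structure). Default c(0.7, 0.95).
#' @param coexpr_noise_sd Residual noise standard deviation. Default 0.5.
#' @param seed RNG seed making every generator deterministic.
#'
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 5000,
                              group_sizes = c(WT = 4, Tyrobp_het = 3,
                                              Tyrobp_ko = 4, APP_PSEN1 = 4,
                                              APP_PSEN1_het = 4,
                                              APP_PSEN1_ko = 5),
                              planted_module_size = 100,
                              planted_log2fc = 2.0,
                              reversal_fraction = 0.8,
                              het_effect = 0.5,
                              nb_dispersion = 0.1,
                              library_size_range = c(8e6, 12e6),
                              n_network_nodes = 1000,
                              layer_sizes = c(25, 50, 100, 150),
                              layer_planted_fraction = c(0.6, 0.45, 0.3, 0.2),
                              extra_parent_rate = 0.5,
                              background_parent_rate = 1.2,
                              coexpr_modules = 5,
                              coexpr_module_size = 60,
                              coexpr_background = 200,
                              coexpr_samples = 50,
                              loading_range = c(0.7, 0.95),
                              coexpr_noise_sd = 0.5,
                              seed = 1) {
  stopifnot(n_genes >= 1, all(group_sizes >= 2), length(group_sizes) >= 2,
            planted_module_size >= 0, planted_module_size <= n_genes,
            reversal_fraction >= 0, reversal_fraction <= 1,
            het_effect >= 0, het_effect <= 1,
            nb_dispersion >= 0, length(library_size_range) == 2L,
            library_size_range[1] > 0,
            library_size_range[2] >= library_size_range[1],
            n_network_nodes >= sum(layer_sizes) + 1,
            length(layer_sizes) >= 1,
            length(layer_planted_fraction) == length(layer_sizes),
            all(layer_planted_fraction >= 0 & layer_planted_fraction <= 1),
            coexpr_samples >= 3, length(loading_range) == 2L,
            loading_range[1] >= 0, loading_range[2] >= loading_range[1],
            coexpr_noise_sd > 0,
            is.numeric(seed), length(seed) == 1L, seed == round(seed))
  if (is.null(names(group_sizes))) {
    names(group_sizes) <- genotype_levels()[seq_along(group_sizes)]
  }
  cfg <- as.list(environment())
  structure(cfg, class = "simulation_config")
}

gene_names <- function(n) sprintf("gene_%05d", seq_len(n))

# Planted module membership is the first draw of the RNG stream so that the
# count and network generators agree on it for a shared config.
draw_planted <- function(config) {
  set.seed(config$seed)
  genes <- gene_names(config$n_genes)
  if (config$planted_module_size == 0) return(character(0))
  sort(sample(genes, config$planted_module_size))
}

#' True per-genotype log2 fold changes of the planted module
#'
#' Relative to wild type: 0 in the driver-only genotypes, the full planted
#' shift in `APP_PSEN1`, the shift minus the (dose-scaled) reversal in the
#' crossed genotypes.
#'
#' @param config A `simulation_config`.
#' @return Named numeric vector over [genotype_levels()].
#' @export
planted_genotype_log2fc <- function(config) {
  L <- config$planted_log2fc
  r <- config$reversal_fraction
  h <- config$het_effect
  c(WT = 0, Tyrobp_het = 0, Tyrobp_ko = 0,
    APP_PSEN1 = L,
    APP_PSEN1_het = L * (1 - r * h),
    APP_PSEN1_ko = L * (1 - r))
}

#' Simulate genotype-structured RNA-seq counts with a planted module
#'
#' Baseline relative abundances are log-normal; planted module genes are
#' shifted by the per-genotype log2 fold changes of
#' [planted_genotype_log2fc()]; counts are negative-binomial around
#' depth-scaled means. Deterministic given the config (which carries the
#' seed).
#'
#' @param config A `simulation_config`.
#' @return List with `counts` (a [count_matrix()]) and `truth` (planted gene
#'   set, reverted subset, per-genotype true log2FC, seed).
#' @export
simulate_counts <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  genes <- gene_names(config$n_genes)
  planted <- draw_planted(config)  # seeds the stream
  w <- exp(stats::rnorm(config$n_genes, mean = 0, sd = 1.5))
  names(w) <- genes
  lfc <- planted_genotype_log2fc(config)
  genotype <- rep(names(config$group_sizes), config$group_sizes)
  samples <- paste0(genotype, "_", unlist(lapply(config$group_sizes, seq_len)))
  libs <- stats::runif(length(samples), config$library_size_range[1],
                       config$library_size_range[2])
  counts <- matrix(0, config$n_genes, length(samples),
                   dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    wj <- w
    g <- genotype[j]
    shift <- if (g %in% names(lfc)) lfc[[g]] else 0
    wj[planted] <- wj[planted] * 2^shift
    mu <- libs[j] * wj / sum(wj)
    counts[, j] <- if (config$nb_dispersion > 0) {
      stats::rnbinom(config$n_genes, mu = mu, size = 1 / config$nb_dispersion)
    } else {
      stats::rpois(config$n_genes, lambda = mu)
    }
  }
  truth <- list(planted_up_in_APP = planted,
                reverted_by_ko = planted,
                true_log2fc = lfc,
                seed = config$seed)
  list(counts = count_matrix(counts, stats::setNames(genotype, samples)),
       truth = truth)
}

#' Simulate a planted-driver directed causal network
#'
#' Builds an acyclic digraph over a subset of the gene namespace in which a
#' designated driver node's first downstream layers have configured sizes
#' and are enriched for the planted module: each layer draws the configured
#' fraction of its members from the planted genes, every layer-k node has at
#' least one parent in layer k-1 (plus Poisson extras), and background nodes
#' attach only to earlier background nodes or to the deepest layer, so the
#' planted layer structure is exactly the driver's breadth-first layering.
#'
#' @param config A `simulation_config`.
#' @return List with `network` (a [causal_network()]) and `truth`
#'   (`planted_driver`, `planted_layers`, planted module genes in the
#'   network, seed).
#' @export
simulate_causal_network <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  genes <- gene_names(config$n_genes)
  planted <- draw_planted(config)  # same first draw as simulate_counts
  n_layer <- sum(config$layer_sizes)
  stopifnot(config$n_network_nodes <= config$n_genes)
  nonplanted <- setdiff(genes, planted)
  driver <- sample(nonplanted, 1)
  pool_planted <- sample(planted)
  pool_bg <- sample(setdiff(nonplanted, driver))
  layers <- vector("list", length(config$layer_sizes))
  for (k in seq_along(config$layer_sizes)) {
    sz <- config$layer_sizes[k]
    n_pl <- min(round(sz * config$layer_planted_fraction[k]),
                length(pool_planted))
    take_pl <- utils::head(pool_planted, n_pl)
    pool_planted <- setdiff(pool_planted, take_pl)
    take_bg <- utils::head(pool_bg, sz - n_pl)
    pool_bg <- setdiff(pool_bg, take_bg)
    layers[[k]] <- sample(c(take_pl, take_bg))
  }
  n_bg <- config$n_network_nodes - 1 - n_layer
  background <- utils::head(sample(c(pool_planted, pool_bg)), n_bg)
  from <- character(0); to <- character(0)
  # driver -> every first-layer node
  from <- c(from, rep(driver, length(layers[[1]])))
  to <- c(to, layers[[1]])
  for (k in seq_along(layers)[-1]) {
    for (v in layers[[k]]) {
      n_par <- 1 + stats::rpois(1, config$extra_parent_rate)
      par <- sample(layers[[k - 1]], min(n_par, length(layers[[k - 1]])))
      from <- c(from, par); to <- c(to, rep(v, length(par)))
    }
  }
  deepest <- layers[[length(layers)]]
  for (i in seq_along(background)) {
    pool <- c(deepest, background[seq_len(i - 1)])
    n_par <- stats::rpois(1, config$background_parent_rate)
    if (n_par > 0 && length(pool) > 0) {
      par <- sample(pool, min(n_par, length(pool)))
      from <- c(from, par); to <- c(to, rep(background[i], length(par)))
    }
  }
  nodes <- c(driver, unlist(layers), background)
  net <- causal_network(data.frame(from = from, to = to,
                                   cohort = "synthetic",
                                   stringsAsFactors = FALSE),
                        name = "synthetic", nodes = nodes)
  truth <- list(planted_driver = driver,
                planted_layers = lapply(layers, sort),
                planted_module = planted,
                planted_in_network = intersect(planted, net$nodes),
                seed = config$seed)
  list(network = net, truth = truth)
}

#' Simulate latent-factor co-expression data with planted modules
#'
#' Module genes load on one shared Gaussian factor each
#' (expression = loading x factor + noise); factors of different modules are
#' independent and background genes are pure noise.
#'
#' @param config A `simulation_config`.
#' @return List with `expression` (genes x samples matrix) and `truth`
#'   (named character vector gene -> planted module label, background genes
#'   labelled "background").
#' @export
simulate_coexpression <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  m <- config$coexpr_modules
  sz <- config$coexpr_module_size
  nb <- config$coexpr_background
  n <- m * sz + nb
  ns <- config$coexpr_samples
  genes <- sprintf("cx_%04d", seq_len(n))
  labels <- c(rep(paste0("module_", seq_len(m)), each = sz),
              rep("background", nb))
  names(labels) <- genes
  factors <- matrix(stats::rnorm(m * ns), m, ns)
  loading <- stats::runif(n, config$loading_range[1], config$loading_range[2])
  expr <- matrix(stats::rnorm(n * ns, sd = config$coexpr_noise_sd), n, ns,
                 dimnames = list(genes, paste0("s", seq_len(ns))))
  for (i in seq_len(m * sz)) {
    expr[i, ] <- expr[i, ] + loading[i] * factors[ceiling(i / sz), ]
  }
  expr[(m * sz + seq_len(nb)), ] <-
    expr[(m * sz + seq_len(nb)), ] * (1 / config$coexpr_noise_sd)
  list(expression = expr, truth = labels)
}
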