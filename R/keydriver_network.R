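#' Construct a directed causal gene network
#'
#' A directed graph over gene symbols with a cohort tag per edge (which
#' source network(s) contributed the edge). Self-loops are rejected here;
#' use [load_network()] to drop them with a warning when reading files.
#'
#' @param edges Data frame (or matrix) whose first two columns are source and
#'   target gene symbols; an optional `cohort` column tags edge provenance.
#' @param name Network label.
#' @param nodes Optional character vector of nodes; extended to include all
#'   edge endpoints.
#'
#' @return Object of class `causal_network`: list with `nodes`, `edges`
#'   (data frame `from`, `to`, `cohort`) and `name`. Duplicate edges collapse
#'   with their cohort tags merged (comma-joined, sorted, unique).
#' @export
causal_network <- function(edges, name = "network", nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("edges needs at least source and target columns")
  cohort <- if ("cohort" %in% names(edges)) as.character(edges$cohort)
            else if (ncol(edges) >= 3L) as.character(edges[[3]])
            else rep(name, nrow(edges))
  edges <- data.frame(from = as.character(edges[[1]]),
                      to = as.character(edges[[2]]),
                      cohort = cohort, stringsAsFactors = FALSE)
  if (any(edges$from == edges$to)) {
    stop("self-loop(s) present: ",
         paste(utils::head(edges$from[edges$from == edges$to], 5),
               collapse = ", "))
  }
  edges <- merge_edge_tags(edges)
  nodes <- sort(unique(c(as.character(nodes), edges$from, edges$to)))
  structure(list(nodes = nodes, edges = edges, name = name),
            class = "causal_network")
}

merge_edge_tags <- function(edges) {
  key <- paste(edges$from, edges$to, sep = "\r")
  tags <- vapply(split(edges$cohort, key), function(tg) {
    paste(sort(unique(unlist(strsplit(tg, ",", fixed = TRUE)))),
          collapse = ",")
  }, character(1))
  first <- !duplicated(key)
  out <- edges[first, c("from", "to"), drop = FALSE]
  out$cohort <- unname(tags[paste(out$from, out$to, sep = "\r")])
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.causal_network <- function(x, ...) {
  cat("causal_network '", x$name, "': ", length(x$nodes), " nodes, ",
      nrow(x$edges), " directed edges\n", sep = "")
  invisible(x)
}

#' Union of directed causal networks
#'
#' Node set and edge set unions across cohorts; duplicate edges collapse
#' with cohort tags merged. Oppositely directed arcs from different cohorts
#' are both retained. The result is a general digraph (it may contain cycles
#' even when every input is acyclic) and is treated as such downstream.
#'
#' @param networks List of `causal_network` objects (length >= 1).
#' @param name Label for the union. Default "union".
#' @return A `causal_network`.
#' @export
union_network <- function(networks, name = "union") {
  if (inherits(networks, "causal_network")) networks <- list(networks)
  stopifnot(length(networks) >= 1,
            all(vapply(networks, inherits, logical(1), "causal_network")))
  edges <- do.call(rbind, lapply(networks, function(g) g$edges))
  nodes <- unique(unlist(lapply(networks, function(g) g$nodes)))
  causal_network(edges, name = name, nodes = nodes)
}

adjacency_list <- function(network) {
  split(network$edges$to, factor(network$edges$from, levels = network$nodes))
}

#' Layered downstream neighborhood of a seed gene
#'
#' Breadth-first search over outgoing edges: layer i holds the nodes whose
#' shortest directed distance from the seed is exactly i. Cycles cause no
#' revisit and the seed is never a member of any layer.
#'
#' @param network A `causal_network`.
#' @param seed Gene symbol present in the network.
#' @param max_depth Number of layers (>= 1). Default 4.
#' @param adj Optional precomputed adjacency list (internal use, for scoring
#'   many seeds on one network).
#'
#' @return Object of class `layered_neighborhood`: list with `seed`,
#'   `layers` (list of disjoint character vectors, possibly empty) and
#'   `max_depth`.
#' @export
downstream_layers <- function(network, seed, max_depth = 4, adj = NULL) {
  stopifnot(inherits(network, "causal_network"),
            length(seed) == 1L, max_depth >= 1)
  if (!seed %in% network$nodes) stop("seed gene not in network: ", seed)
  if (is.null(adj)) adj <- adjacency_list(network)
  layers <- vector("list", max_depth)
  seen <- new.env(parent = emptyenv())
  assign(seed, TRUE, envir = seen)
  frontier <- seed
  for (d in seq_len(max_depth)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[!vapply(nxt, exists, logical(1), envir = seen)]
    for (v in nxt) assign(v, TRUE, envir = seen)
    layers[[d]] <- sort(nxt)
    frontier <- nxt
    if (length(frontier) == 0L) {
      for (k in seq_len(max_depth)) {
        if (k > d) layers[[k]] <- character(0)
      }
      break
    }
  }
  layers <- lapply(layers, function(l) if (is.null(l)) character(0) else l)
  structure(list(seed = seed, layers = layers, max_depth = max_depth),
            class = "layered_neighborhood")
}

#' @export
print.layered_neighborhood <- function(x, ...) {
  cat("downstream neighborhood of", x$seed, ":",
      paste(vapply(x$layers, length, integer(1)), collapse = "/"),
      "genes in layers 1 -", x$max_depth, "\n")
  invisible(x)
}

#' Per-layer signature enrichment of a downstream neighborhood
#'
#' Scores each layer of a seed gene's downstream neighborhood against a
#' signature by overlap enrichment within a stated universe. With
#' `cumulative = TRUE` layer k is replaced by the union of layers 1..k.
#' Layers and the signature are restricted to the universe before testing.
#'
#' @param neighborhood A `layered_neighborhood`.
#' @param signature Character vector of signature genes.
#' @param universe Character vector; the background gene space.
#' @param cumulative Use cumulative layer unions. Default FALSE (per-layer).
#'
#' @return Data frame with one row per layer: `layer`, `layer_size`,
#'   `overlap`, `fold_enrichment`, `p`, `adjusted_p` (BH across the layers).
#' @export
layer_enrichment <- function(neighborhood, signature, universe,
                             cumulative = FALSE) {
  stopifnot(inherits(neighborhood, "layered_neighborhood"))
  universe <- unique(as.character(universe))
  if (length(universe) < 2L) stop("universe must contain at least 2 genes")
  signature <- intersect(unique(as.character(signature)), universe)
  sets <- lapply(neighborhood$layers, intersect, y = universe)
  if (cumulative) {
    acc <- character(0)
    sets <- lapply(sets, function(l) acc <<- union(acc, l))
  }
  rows <- lapply(seq_along(sets), function(k) {
    r <- overlap_enrichment(sets[[k]], signature, universe)
    data.frame(layer = k, layer_size = r$set1_size, overlap = r$overlap,
               n_signature = r$set2_size, N = r$universe_size,
               fold_enrichment = r$fold_enrichment, p = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- bh_adjust(out$p)
  out
}

#' Genome-wide key-driver ranking
#'
#' Every node with a non-empty downstream neighborhood within `max_depth`
#' is a candidate driver. Each candidate's cumulative neighborhood (union of
#' layers 1..max_depth, restricted to the universe) is scored against the
#' signature by overlap enrichment; p-values are BH-adjusted across the
#' candidates and ranks assigned by adjusted p ascending, fold enrichment
#' descending, then neighborhood size descending (deterministic, final tie
#' broken alphabetically).
#'
#' @param network A `causal_network`.
#' @param signature Character vector (non-empty after restriction to the
#'   universe).
#' @param universe Background gene space; default the network's node set.
#' @param max_depth Neighborhood depth. Default 4.
#'
#' @return Data frame of class `driver_ranking`: `gene`,
#'   `neighborhood_size`, `overlap`, `fold_enrichment`, `p`, `adjusted_p`,
#'   `rank`, ordered by rank.
#' @export
rank_key_drivers <- function(network, signature, universe = NULL,
                             max_depth = 4) {
  stopifnot(inherits(network, "causal_network"), max_depth >= 1)
  if (is.null(universe)) universe <- network$nodes
  universe <- unique(as.character(universe))
  signature <- intersect(unique(as.character(signature)), universe)
  if (length(signature) == 0L) {
    stop("signature is empty after restriction to the universe")
  }
  adj <- adjacency_list(network)
  sources <- unique(network$edges$from)
  rows <- lapply(sources, function(g) {
    nb <- downstream_layers(network, g, max_depth = max_depth, adj = adj)
    neigh <- intersect(unlist(nb$layers, use.names = FALSE), universe)
    if (length(neigh) == 0L) return(NULL)
    r <- overlap_enrichment(neigh, signature, universe)
    data.frame(gene = g, neighborhood_size = length(neigh),
               overlap = r$overlap, fold_enrichment = r$fold_enrichment,
               p = r$p_value, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no candidate has a non-empty neighborhood")
  out <- do.call(rbind, rows)
  out$adjusted_p <- bh_adjust(out$p)
  ord <- order(out$adjusted_p, -out$fold_enrichment,
               -out$neighborhood_size, out$gene)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("driver_ranking", "data.frame")
  out
}
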