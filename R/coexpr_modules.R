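#' Unsigned weighted co-expression adjacency
#'
#' a_ij = |pearson(g_i, g_j)|^beta with unit diagonal. The soft threshold
#' beta sharpens the contrast between strong and weak correlations.
#'
#' @param expression Numeric matrix, genes x samples (>= 3 samples).
#' @param beta Soft-threshold exponent, >= 1. Default 6.
#' @return Symmetric matrix in [0, 1] with dimnames from the gene rownames.
#' @export
correlation_adjacency <- function(expression, beta = 6) {
  expression <- as.matrix(expression)
  stopifnot(ncol(expression) >= 3, is.numeric(beta), length(beta) == 1L,
            beta >= 1)
  v <- apply(expression, 1, stats::var)
  if (any(v == 0 | !is.finite(v))) {
    bad <- rownames(expression)[v == 0 | !is.finite(v)]
    stop("zero-variance gene(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  a <- abs(stats::cor(t(expression)))^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij), with
#' connectivities k_i = sum_{u != i} a_iu and unit diagonal. Two genes score
#' high when they share neighbors even if their direct connection is modest.
#'
#' @param adjacency Symmetric matrix with entries in [0, 1], unit diagonal.
#' @return Symmetric matrix in [0, 1], unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  adjacency <- as.matrix(adjacency)
  if (any(adjacency < 0 | adjacency > 1)) {
    stop("adjacency entries must lie in [0, 1]")
  }
  a <- adjacency
  diag(a) <- 0
  shared <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (shared + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect co-expression modules by hierarchical clustering of the TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity 1 - TOM with
#' a static tree cut; clusters smaller than `min_size` are labelled
#' "unassigned". Module labels are "M1", "M2", ... in decreasing size order.
#'
#' @param tom Topological overlap matrix (from [topological_overlap()]).
#' @param min_size Minimum module size. Default 30.
#' @param cut_height Static cut height on the 1 - TOM dendrogram, in (0, 1].
#'   Default 0.95.
#'
#' @return Object of class `module_partition`: list with `labels` (named
#'   character vector gene -> module), `sizes`, and `parameters`.
#' @export
detect_modules <- function(tom, min_size = 30, cut_height = 0.95) {
  tom <- as.matrix(tom)
  stopifnot(nrow(tom) == ncol(tom), min_size >= 1,
            cut_height > 0, cut_height <= 1)
  if (any(tom < 0 | tom > 1)) stop("TOM entries must lie in [0, 1]")
  genes <- rownames(tom)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(tom)))
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  # repair sub-epsilon height inversions from tied merges
  hc$height <- cummax(hc$height)
  raw <- stats::cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  keep <- keep[order(-sizes[keep], as.integer(keep))]
  labels <- rep("unassigned", length(raw))
  for (i in seq_along(keep)) {
    labels[raw == as.integer(keep[i])] <- paste0("M", i)
  }
  names(labels) <- genes
  structure(list(labels = labels,
                 sizes = table(labels),
                 parameters = list(min_size = min_size,
                                   cut_height = cut_height)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("module_partition:", sum(x$labels != "unassigned"), "genes in",
      sum(names(x$sizes) != "unassigned"), "modules;",
      sum(x$labels == "unassigned"), "unassigned\n")
  print(x$sizes)
  invisible(x)
}

#' Module-signature enrichment
#'
#' Overlap enrichment of every detected module (the "unassigned" remainder
#' is excluded) against a signature, BH-adjusted across modules.
#'
#' @param partition A `module_partition`.
#' @param signature Character vector of signature genes.
#' @param universe Background gene space; default all partitioned genes.
#'
#' @return Data frame with one row per module: `module`, `size`, `overlap`,
#'   `fold_enrichment`, `p`, `adjusted_p`, ordered by adjusted p.
#' @export
module_enrichment <- function(partition, signature, universe = NULL) {
  stopifnot(inherits(partition, "module_partition"))
  if (is.null(universe)) universe <- names(partition$labels)
  universe <- unique(as.character(universe))
  signature <- intersect(unique(as.character(signature)), universe)
  modules <- setdiff(unique(partition$labels), "unassigned")
  if (length(modules) == 0L) {
    return(data.frame(module = character(0), size = integer(0),
                      overlap = integer(0), fold_enrichment = numeric(0),
                      p = numeric(0), adjusted_p = numeric(0)))
  }
  rows <- lapply(modules, function(m) {
    genes <- intersect(names(partition$labels)[partition$labels == m],
                       universe)
    r <- overlap_enrichment(genes, signature, universe)
    data.frame(module = m, size = length(genes), overlap = r$overlap,
               fold_enrichment = r$fold_enrichment, p = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- bh_adjust(out$p)
  out <- out[order(out$adjusted_p, -out$fold_enrichment), , drop = FALSE]
  rownames(out) <- NULL
  out
}
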