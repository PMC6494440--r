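enrichment_result <- function(overlap, n1, n2, N, p, fe, adjusted_p = NA_real_) {
  structure(list(overlap = overlap, set1_size = n1, set2_size = n2,
                 universe_size = N, fold_enrichment = fe, p_value = p,
                 adjusted_p = adjusted_p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "overlap %d of %d x %d in N = %d | FE = %.3g | p = %.3g | adj. p = %.3g\n",
    x$overlap, x$set1_size, x$set2_size, x$universe_size,
    x$fold_enrichment, x$p_value, x$adjusted_p))
  invisible(x)
}

#' Direction-aware overlap enrichment of two gene sets
#'
#' Intersects two gene sets within a stated universe and reports the overlap
#' count, fold enrichment (observed/expected), one-sided Fisher's exact
#' (hypergeometric upper-tail) p-value, and all counts needed to recompute
#' them.
#'
#' @param sigA,sigB Character vectors of gene identifiers; must be subsets of
#'   `universe`.
#' @param universe Character vector defining the background gene space
#'   (length >= 2).
#'
#' @return An `enrichment_result` (adjusted p is NA here; it is filled in by
#'   [overlap_matrix()] across a family of tests).
#' @export
overlap_enrichment <- function(sigA, sigB, universe) {
  sigA <- unique(as.character(sigA))
  sigB <- unique(as.character(sigB))
  universe <- unique(as.character(universe))
  if (length(universe) < 2L) stop("universe must contain at least 2 genes")
  badA <- setdiff(sigA, universe)
  badB <- setdiff(sigB, universe)
  if (length(badA) || length(badB)) {
    bad <- utils::head(unique(c(badA, badB)), 10)
    stop("gene set not contained in universe; offending genes: ",
         paste(bad, collapse = ", "),
         if (length(c(badA, badB)) > 10) " ..." else "")
  }
  ov <- length(intersect(sigA, sigB))
  n1 <- length(sigA); n2 <- length(sigB); N <- length(universe)
  p <- if (n1 == 0 || n2 == 0) 1 else hypergeom_tail(ov, n1, n2, N)
  fe <- if (n1 == 0 || n2 == 0) 0 else fold_enrichment(ov, n1, n2, N)
  enrichment_result(ov, n1, n2, N, p, fe)
}

#' A named collection of direction-tagged signatures over one universe
#'
#' @param signatures Named list of character vectors (e.g.
#'   `APP_vs_WT_UP`, `APPko_vs_APP_DN`).
#' @param universe Character vector containing every signature gene.
#' @param species_tag Optional label (e.g. "mouse", "human").
#'
#' @return Object of class `signature_collection`.
#' @export
signature_collection <- function(signatures, universe, species_tag = "") {
  stopifnot(is.list(signatures), length(signatures) >= 1)
  if (is.null(names(signatures)) || anyDuplicated(names(signatures)) ||
      any(names(signatures) == "")) {
    stop("signatures must have unique non-empty names")
  }
  universe <- unique(as.character(universe))
  signatures <- lapply(signatures, function(s) unique(as.character(s)))
  outside <- unlist(lapply(signatures, setdiff, y = universe))
  if (length(outside)) {
    stop("signature gene(s) outside the universe: ",
         paste(utils::head(unique(outside), 10), collapse = ", "))
  }
  structure(list(signatures = signatures, universe = universe,
                 species_tag = species_tag),
            class = "signature_collection")
}

#' Collect the directional signatures of a DE run into a collection
#'
#' Turns the `signatures` element of [run_de()] output into a
#' `signature_collection` with names `<contrast>_UP` / `<contrast>_DN`, over
#' the universe of expressed genes.
#'
#' @param de Output of [run_de()].
#' @param species_tag Optional label.
#' @return A `signature_collection`.
#' @export
collect_signatures <- function(de, species_tag = "mouse") {
  sets <- list()
  for (nm in names(de$signatures)) {
    sets[[paste0(nm, "_UP")]] <- de$signatures[[nm]]$up
    sets[[paste0(nm, "_DN")]] <- de$signatures[[nm]]$down
  }
  signature_collection(sets, rownames(de$filtered$counts), species_tag)
}

#' Pairwise overlap-enrichment table
#'
#' One enrichment test per requested ordered pair of signatures, with
#' Benjamini-Hochberg adjustment across exactly the requested family;
#' duplicated pairs collapse to one row. Output is sorted by adjusted p
#' (ties by fold enrichment, descending).
#'
#' @param collection A `signature_collection`.
#' @param pairs List of length-2 character vectors of signature names; when
#'   NULL, all unordered pairs of distinct signatures.
#'
#' @return Data frame with columns `set1`, `set2`, `overlap`, `n1`, `n2`,
#'   `N`, `fold_enrichment`, `p`, `adjusted_p`.
#' @export
overlap_matrix <- function(collection, pairs = NULL) {
  stopifnot(inherits(collection, "signature_collection"))
  nms <- names(collection$signatures)
  if (is.null(pairs)) {
    idx <- utils::combn(seq_along(nms), 2)
    pairs <- lapply(seq_len(ncol(idx)), function(j) nms[idx[, j]])
  }
  key <- vapply(pairs, function(p) paste(p, collapse = "\r"), character(1))
  pairs <- pairs[!duplicated(key)]
  rows <- lapply(pairs, function(pr) {
    if (length(pr) != 2L || !all(pr %in% nms)) {
      stop("unknown signature name(s): ",
           paste(setdiff(pr, nms), collapse = ", "))
    }
    r <- overlap_enrichment(collection$signatures[[pr[1]]],
                            collection$signatures[[pr[2]]],
                            collection$universe)
    data.frame(set1 = pr[1], set2 = pr[2], overlap = r$overlap,
               n1 = r$set1_size, n2 = r$set2_size, N = r$universe_size,
               fold_enrichment = r$fold_enrichment, p = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- bh_adjust(out$p)
  out[order(out$adjusted_p, -out$fold_enrichment), , drop = FALSE]
}

#' Map a gene set across species by symbol
#'
#' Default policy is case-insensitive symbol identity (mouse "Trem2" maps to
#' human "TREM2"); an explicit two-column mapping table can be supplied
#' instead. Genes mapping to more than one target and genes without a target
#' are dropped and counted.
#'
#' @param signature Character vector of gene symbols.
#' @param mapping NULL for the case-fold policy, or a data frame/matrix whose
#'   first column is the source symbol and second the target symbol.
#'
#' @return Character vector of mapped symbols with attributes `n_dropped`
#'   (unmapped or ambiguous inputs) and `dropped` (their symbols).
#' @export
map_orthologs <- function(signature, mapping = NULL) {
  signature <- unique(as.character(signature))
  if (is.null(mapping)) {
    mapped <- toupper(signature)
    dropped <- character(0)
  } else {
    mapping <- as.data.frame(mapping)[, 1:2]
    names(mapping) <- c("from", "to")
    mapping <- unique(mapping)
    ambiguous <- mapping$from[duplicated(mapping$from)]
    mapping <- mapping[!(mapping$from %in% ambiguous), , drop = FALSE]
    hit <- match(signature, mapping$from)
    dropped <- signature[is.na(hit)]
    mapped <- mapping$to[hit[!is.na(hit)]]
  }
  mapped <- unique(mapped)
  attr(mapped, "n_dropped") <- length(dropped)
  attr(mapped, "dropped") <- dropped
  mapped
}
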