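#' Genotype labels of the six-group cross design
#'
#' Wild type, driver heterozygous and knockout, the amyloid model, and the
#' amyloid model crossed onto each driver genotype.
#'
#' @return Character vector of the six genotype levels, in design order.
#' @export
genotype_levels <- function() {
  c("WT", "Tyrobp_het", "Tyrobp_ko",
    "APP_PSEN1", "APP_PSEN1_het", "APP_PSEN1_ko")
}

#' The six reported pairwise contrasts
#'
#' Each element is `c(test, reference)`; log2 fold changes are
#' mean(test) - mean(reference).
#'
#' @return Named list of genotype pairs.
#' @export
default_contrasts <- function() {
  list(
    het_vs_WT     = c("Tyrobp_het", "WT"),
    ko_vs_WT      = c("Tyrobp_ko", "WT"),
    APP_vs_WT     = c("APP_PSEN1", "WT"),
    APPko_vs_APP  = c("APP_PSEN1_ko", "APP_PSEN1"),
    APPko_vs_WT   = c("APP_PSEN1_ko", "WT"),
    APPko_vs_ko   = c("APP_PSEN1_ko", "Tyrobp_ko")
  )
}

#' Construct a validated count matrix
#'
#' @param counts Integer matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames).
#' @param genotype Character or factor of per-sample genotype labels, one per
#'   column of `counts` (recycled names checked against colnames when named).
#'
#' @return An object of class `count_matrix`: list with `counts`,
#'   `genotype` (factor), and `library_sizes` (column sums).
#' @export
count_matrix <- function(counts, genotype) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stop("counts must have unique gene rownames")
  }
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts))) {
    stop("counts must have unique sample colnames")
  }
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be finite non-negative integers")
  }
  storage.mode(counts) <- "double"
  if (!is.null(names(genotype))) {
    if (!setequal(names(genotype), colnames(counts))) {
      missing <- setdiff(colnames(counts), names(genotype))
      stop("genotype missing for sample(s): ", paste(missing, collapse = ", "))
    }
    genotype <- genotype[colnames(counts)]
  }
  if (length(genotype) != ncol(counts)) {
    stop("need one genotype per sample: ", length(genotype), " labels for ",
         ncol(counts), " samples")
  }
  lev <- if (all(genotype %in% genotype_levels())) genotype_levels() else
    unique(as.character(genotype))
  genotype <- factor(as.character(genotype), levels = intersect(lev, genotype))
  structure(list(counts = counts,
                 genotype = stats::setNames(genotype, colnames(counts)),
                 library_sizes = colSums(counts)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  print(table(x$genotype))
  invisible(x)
}

#' Counts per million
#'
#' CPM on raw library sizes (no normalization factors); used by the
#' expression filter.
#'
#' @param counts Numeric matrix of counts.
#' @param library_sizes Column totals; computed from `counts` when NULL.
#' @return Matrix of the same shape.
#' @export
cpm_raw <- function(counts, library_sizes = NULL) {
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  t(t(counts) / library_sizes) * 1e6
}

#' Filter to expressed genes
#'
#' Retains genes with at least 1 count per million in at least one sample,
#' CPM computed on raw library sizes. Library sizes are not recomputed after
#' filtering (they remain the sequencing depths of the original samples).
#'
#' @param x A `count_matrix`.
#' @param min_cpm CPM threshold (inclusive). Default 1.
#' @param min_samples Minimum number of samples at or above the threshold.
#'   Default 1.
#'
#' @return A `count_matrix` restricted to expressed genes, with the original
#'   library sizes preserved.
#' @export
filter_expressed <- function(x, min_cpm = 1, min_samples = 1) {
  stopifnot(inherits(x, "count_matrix"), nrow(x$counts) >= 1)
  keep <- rowSums(cpm_raw(x$counts, x$library_sizes) >= min_cpm) >= min_samples
  if (!any(keep)) stop("no genes pass the expression filter")
  out <- x
  out$counts <- x$counts[keep, , drop = FALSE]
  out
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values scaling factors: per-sample factors from the
#' doubly trimmed (30% on M, 5% on A), precision-weighted mean of per-gene
#' log ratios against a reference sample (the sample whose upper-quartile
#' CPM is closest to the mean), rescaled to geometric mean 1. Computed by
#' edgeR's TMM implementation.
#'
#' @param x A `count_matrix` (ideally already filtered to expressed genes).
#' @param reference Optional column index or sample name forcing the
#'   reference sample.
#'
#' @return List of class `normalization_factors` with `tmm_factor` (named,
#'   geometric mean 1) and `effective_library_size`
#'   (library size x factor).
#' @export
tmm_factors <- function(x, reference = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (ncol(x$counts) < 2L) stop("TMM needs at least 2 samples")
  ref <- NULL
  if (!is.null(reference)) {
    ref <- if (is.character(reference)) match(reference, colnames(x$counts))
           else as.integer(reference)
    if (is.na(ref) || ref < 1 || ref > ncol(x$counts)) {
      stop("unknown reference sample")
    }
  }
  f <- edgeR::calcNormFactors(x$counts, lib.size = x$library_sizes,
                              method = "TMM", refColumn = ref,
                              logratioTrim = 0.3, sumTrim = 0.05,
                              doWeighting = TRUE)
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("TMM failed: no shared nonzero genes with the reference")
  }
  f <- f / exp(mean(log(f)))
  structure(list(tmm_factor = stats::setNames(f, colnames(x$counts)),
                 effective_library_size = x$library_sizes * f),
            class = "normalization_factors")
}

#' Log2 counts per million on effective library sizes
#'
#' @param x A `count_matrix`.
#' @param norm A `normalization_factors` object from [tmm_factors()]; when
#'   NULL all factors are taken as 1.
#' @param prior_count Pseudo-count stabilizing low counts. Default 0.5.
#' @return Matrix of log2-CPM values, same shape as the counts.
#' @export
log_cpm <- function(x, norm = NULL, prior_count = 0.5) {
  stopifnot(inherits(x, "count_matrix"))
  lib <- if (is.null(norm)) x$library_sizes else norm$effective_library_size
  edgeR::cpm(x$counts, lib.size = lib, log = TRUE, prior.count = prior_count)
}

#' Residualize expression on covariates
#'
#' Least-squares residuals of each gene on a covariate design (intercept
#' always included). Used to remove confounders such as batch, post-mortem
#' interval, sex, and RNA integrity before network construction.
#'
#' @param expression Numeric matrix, genes x samples.
#' @param covariates Data frame with one row per sample (columns may be
#'   numeric or factor), or NULL/zero-column for intercept-only
#'   (mean-centering).
#'
#' @return Residual matrix of the same shape.
#' @export
residualize_covariates <- function(expression, covariates = NULL) {
  expression <- as.matrix(expression)
  n <- ncol(expression)
  if (is.null(covariates) || NCOL(covariates) == 0L) {
    design <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) {
      stop("covariates has ", nrow(covariates), " rows for ", n, " samples")
    }
    design <- stats::model.matrix(~ ., data = covariates)
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  res <- t(qr.resid(qrd, t(expression)))
  dimnames(res) <- dimnames(expression)
  res
}

#' Fit per-gene group-means models with empirical-Bayes moderation
#'
#' Fits a group-means linear model to each gene's log2-CPM profile and
#' moderates the residual variances by shrinking toward a common prior:
#' the prior degrees of freedom d0 and prior variance s0^2 are estimated by
#' moment-matching the log residual variances to a scaled F distribution
#' (digamma/trigamma equations), and the posterior variance is
#' (d0 s0^2 + d_g s_g^2) / (d0 + d_g).
#'
#' @param logexpr Numeric matrix of log2-CPM, genes x samples.
#' @param genotype Factor/character of per-sample group labels; every level
#'   present must have >= 2 samples.
#' @param moderation `"ebayes"` (estimate d0 from the data), `"none"`
#'   (d0 = 0: ordinary least-squares t), or `"infinite"` (d0 = Inf: all
#'   genes share s0^2).
#'
#' @return An object of class `moderated_fit` with per-gene coefficients
#'   (group means), residual variances `s2` and df `df_residual`, prior
#'   `d0`/`s02`, posterior variances `s2_post`, total df `df_total`, and the
#'   per-group sample sizes.
#' @export
fit_moderated_model <- function(logexpr, genotype,
                                moderation = c("ebayes", "none", "infinite")) {
  moderation <- match.arg(moderation)
  logexpr <- as.matrix(logexpr)
  genotype <- droplevels(factor(genotype))
  if (length(genotype) != ncol(logexpr)) {
    stop("need one group label per sample")
  }
  n_per <- table(genotype)
  if (length(n_per) < 2L) stop("need at least 2 groups")
  if (any(n_per < 2L)) {
    stop("group(s) with fewer than 2 samples: ",
         paste(names(n_per)[n_per < 2], collapse = ", "))
  }
  design <- stats::model.matrix(~ 0 + genotype)
  colnames(design) <- levels(genotype)
  fit <- limma::lmFit(logexpr, design)
  s2 <- fit$sigma^2
  dg <- fit$df.residual
  if (moderation == "ebayes") {
    fd <- limma::fitFDist(s2, df1 = dg)
    d0 <- fd$df2
    s02 <- fd$scale
  } else if (moderation == "none") {
    d0 <- 0
    s02 <- NA_real_
  } else {
    d0 <- Inf
    fd <- limma::fitFDist(s2, df1 = dg)
    s02 <- fd$scale
  }
  if (is.finite(d0)) {
    s2_post <- if (d0 > 0) (d0 * s02 + dg * s2) / (d0 + dg) else s2
  } else {
    s2_post <- rep(s02, length(s2))
  }
  structure(list(coefficients = fit$coefficients,
                 s2 = s2, df_residual = dg,
                 d0 = d0, s02 = s02,
                 s2_post = s2_post, df_total = d0 + dg,
                 n_per_group = as.integer(n_per),
                 groups = levels(genotype),
                 moderation = moderation),
            class = "moderated_fit")
}

#' Per-contrast differential-expression table
#'
#' Moderated t-test for one genotype pair: log2FC is the difference of group
#' means, the moderated t uses the posterior variance on d0 + d_g degrees of
#' freedom, p-values are two-sided, and the FDR is Benjamini-Hochberg within
#' the contrast.
#'
#' @param fit A `moderated_fit`.
#' @param contrast Character vector `c(test, reference)` of group labels.
#'
#' @return Data frame with columns `gene`, `log2FC`, `t`, `p`, `FDR`, sorted
#'   in the gene order of the fit; the contrast label is stored in
#'   `attr(, "contrast")`.
#' @export
contrast_table <- function(fit, contrast) {
  stopifnot(inherits(fit, "moderated_fit"), length(contrast) == 2L)
  unknown <- setdiff(contrast, fit$groups)
  if (length(unknown)) {
    stop("unknown genotype label(s): ", paste(unknown, collapse = ", "))
  }
  a <- contrast[1]; b <- contrast[2]
  na <- fit$n_per_group[match(a, fit$groups)]
  nb <- fit$n_per_group[match(b, fit$groups)]
  lfc <- fit$coefficients[, a] - fit$coefficients[, b]
  se <- sqrt(fit$s2_post * (1 / na + 1 / nb))
  tt <- ifelse(se > 0, lfc / se, 0)
  df <- fit$df_total
  p <- 2 * stats::pt(-abs(tt), df = df)
  p <- pmin(p, 1)
  genes <- rownames(fit$coefficients)
  if (is.null(genes)) genes <- paste0("gene", seq_along(lfc))
  out <- data.frame(gene = genes,
                    log2FC = unname(lfc), t = unname(tt), p = unname(p),
                    FDR = bh_adjust(unname(p)),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "contrast") <- paste(a, "vs", b)
  out
}

#' Call a directional signature from a DE table
#'
#' @param table A data frame from [contrast_table()].
#' @param threshold FDR cutoff (inclusive). Default 0.05.
#'
#' @return Object of class `signature`: list with `up` and `down` gene sets,
#'   the `contrast` label, and the `threshold`.
#' @export
call_signature <- function(table, threshold = 0.05) {
  stopifnot(is.data.frame(table), nrow(table) >= 1,
            all(c("gene", "log2FC", "FDR") %in% names(table)))
  hit <- table$FDR <= threshold
  structure(list(up = table$gene[hit & table$log2FC > 0],
                 down = table$gene[hit & table$log2FC < 0],
                 contrast = attr(table, "contrast"),
                 threshold = threshold),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat("signature", if (!is.null(x$contrast)) paste0("[", x$contrast, "]"),
      ": ", length(x$up), " up, ", length(x$down), " down (FDR <= ",
      x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Run the full differential-expression stage
#'
#' Filter to expressed genes, compute TMM factors, fit the moderated model
#' on log2-CPM, and produce one DE table and directional signature per
#' contrast.
#'
#' @param x A `count_matrix`.
#' @param contrasts Named list of genotype pairs; default the six reported
#'   contrasts present in the data.
#' @param fdr_threshold Signature FDR cutoff. Default 0.05.
#' @param moderation Passed to [fit_moderated_model()].
#'
#' @return List with `filtered` (count_matrix), `norm`, `fit`, `tables`
#'   (named list of DE tables) and `signatures` (named list of signatures).
#' @export
run_de <- function(x, contrasts = NULL, fdr_threshold = 0.05,
                   moderation = "ebayes") {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(contrasts)) {
    present <- levels(droplevels(x$genotype))
    contrasts <- Filter(function(p) all(p %in% present), default_contrasts())
  }
  filtered <- filter_expressed(x)
  norm <- tmm_factors(filtered)
  le <- log_cpm(filtered, norm)
  fit <- fit_moderated_model(le, x$genotype, moderation = moderation)
  tables <- lapply(contrasts, contrast_table, fit = fit)
  signatures <- lapply(tables, call_signature, threshold = fdr_threshold)
  list(filtered = filtered, norm = norm, fit = fit,
       tables = tables, signatures = signatures)
}
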