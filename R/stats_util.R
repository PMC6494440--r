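#' Statistical configuration
#'
#' Bundles the significance conventions used across the workflow: the
#' per-test significance level, the FDR cutoff used to call signatures, the
#' standardized effect size the animal design was powered for, and the
#' sidedness of tests.
#'
#' @param alpha Significance level, in (0, 1). Default 0.05.
#' @param fdr_threshold Benjamini-Hochberg cutoff used when calling
#'   differential-expression signatures, in (0, 1). Default 0.05.
#' @param effect_size_d Standardized mean difference (Cohen's d) used for
#'   power calculations. Default 2.5, the design effect size of the
#'   six-genotype mouse experiment.
#' @param two_sided Logical; whether tests are two-sided. Default TRUE.
#'
#' @return An object of class `stats_config`.
#' @export
stats_config <- function(alpha = 0.05, fdr_threshold = 0.05,
                         effect_size_d = 2.5, two_sided = TRUE) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  stopifnot(is.numeric(fdr_threshold), length(fdr_threshold) == 1L,
            fdr_threshold > 0, fdr_threshold < 1)
  stopifnot(is.numeric(effect_size_d), length(effect_size_d) == 1L,
            effect_size_d >= 0)
  stopifnot(is.logical(two_sided), length(two_sided) == 1L)
  structure(list(alpha = alpha, fdr_threshold = fdr_threshold,
                 effect_size_d = effect_size_d, two_sided = two_sided),
            class = "stats_config")
}

check_overlap_counts <- function(overlap, n1, n2, N) {
  for (v in list(overlap = overlap, n1 = n1, n2 = n2, N = N)) {
    stopifnot(is.numeric(v), length(v) == 1L, is.finite(v), v == round(v))
  }
  if (N < 1) stop("universe size must satisfy N >= 1, got N = ", N)
  if (n1 > N) stop("set size exceeds universe: n1 = ", n1, " > N = ", N)
  if (n2 > N) stop("set size exceeds universe: n2 = ", n2, " > N = ", N)
  if (overlap < 0) stop("overlap must satisfy overlap >= 0, got ", overlap)
  if (overlap > min(n1, n2)) {
    stop("overlap exceeds smaller set: overlap = ", overlap,
         " > min(n1, n2) = ", min(n1, n2))
  }
  invisible(TRUE)
}

#' Upper-tail hypergeometric probability of an observed overlap
#'
#' One-sided Fisher's exact test for over-representation: the probability of
#' drawing at least `overlap` marked elements when `n2` elements are drawn
#' without replacement from a universe of `N` containing `n1` marked ones.
#' The tail is accumulated in log space (logsumexp over the log pmf), so
#' extremely small enrichment p-values (down to the smallest normalized
#' double, ~1e-308) are returned without intermediate underflow.
#'
#' @param overlap Observed intersection size.
#' @param n1,n2 Sizes of the two gene sets.
#' @param N Universe size.
#' @param log.p Return the natural log of the tail probability.
#'
#' @return P(X >= overlap), X ~ Hypergeometric(N, n1, n2).
#' @export
hypergeom_tail <- function(overlap, n1, n2, N, log.p = FALSE) {
  check_overlap_counts(overlap, n1, n2, N)
  upper <- min(n1, n2)
  if (overlap == 0) return(if (log.p) 0 else 1)
  support <- overlap:upper
  lp <- stats::dhyper(support, m = n1, n = N - n1, k = n2, log = TRUE)
  lp <- lp[is.finite(lp)]
  if (length(lp) == 0L) return(if (log.p) -Inf else 0)
  mx <- max(lp)
  ltail <- mx + log(sum(exp(lp - mx)))
  ltail <- min(ltail, 0)
  if (log.p) ltail else exp(ltail)
}

#' Fold enrichment of an overlap
#'
#' Observed over expected intersection size under independent draws:
#' `overlap * N / (n1 * n2)`.
#'
#' @inheritParams hypergeom_tail
#' @return Non-negative ratio; 1 means exactly the chance expectation.
#' @export
fold_enrichment <- function(overlap, n1, n2, N) {
  check_overlap_counts(overlap, n1, n2, N)
  if (n1 < 1 || n2 < 1) stop("fold enrichment needs n1 >= 1 and n2 >= 1")
  overlap * N / (n1 * n2)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment: values sorted ascending, q_(i) = min over j >= i of
#' p_(j) * m / j, capped at 1, returned in the input order.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  stopifnot(is.numeric(p_values))
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1] with no NA")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Grubbs single-outlier test (extreme studentized deviate)
#'
#' Flags at most the single most extreme value. The statistic is
#' G = max|x - mean| / sd (n-1 denominator); the two-sided critical value is
#' ((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2)) with t the upper alpha/(2n)
#' quantile of Student-t on n-2 degrees of freedom.
#'
#' @param values Numeric vector, length >= 3, non-constant.
#' @param alpha Significance level (two-sided). Default 0.05.
#'
#' @return A list of class `outlier_result` with `flagged_index` (NA when
#'   nothing is flagged), `statistic_G`, and `critical_value`.
#' @export
grubbs_outlier <- function(values, alpha = 0.05) {
  stopifnot(is.numeric(values), is.numeric(alpha), length(alpha) == 1L,
            alpha > 0, alpha < 1)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L) stop("Grubbs test needs at least 3 values, got ", n)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("Grubbs test undefined for zero variance")
  dev <- abs(values - mean(values))
  i <- which.max(dev)
  G <- dev[i] / s
  tq <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
  structure(list(flagged_index = if (G > crit) i else NA_integer_,
                 statistic_G = G, critical_value = crit),
            class = "outlier_result")
}

#' Power of the two-sample t-test
#'
#' Exact power via the noncentral t distribution with noncentrality
#' d * sqrt(n1 n2 / (n1 + n2)) on n1 + n2 - 2 degrees of freedom.
#'
#' @param n_per_group Integer vector of length 1 or 2: per-group sample sizes.
#' @param effect_size_d Standardized mean difference (Cohen's d), >= 0.
#' @param alpha Significance level. Default 0.05.
#' @param two_sided Two-sided test. Default TRUE.
#'
#' @return Rejection probability under the alternative; equals `alpha` at
#'   d = 0.
#' @export
power_two_sample_t <- function(n_per_group, effect_size_d, alpha = 0.05,
                               two_sided = TRUE) {
  stopifnot(is.numeric(n_per_group), length(n_per_group) %in% 1:2,
            all(n_per_group == round(n_per_group)))
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, 2L)
  n1 <- n_per_group[1]; n2 <- n_per_group[2]
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per group")
  stopifnot(is.numeric(effect_size_d), length(effect_size_d) == 1L,
            effect_size_d >= 0, alpha > 0, alpha < 1)
  df <- n1 + n2 - 2
  ncp <- effect_size_d * sqrt(n1 * n2 / (n1 + n2))
  if (two_sided) {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-tc, df, ncp = ncp)
  } else {
    tc <- stats::qt(1 - alpha, df)
    stats::pt(tc, df, ncp = ncp, lower.tail = FALSE)
  }
}

#' qPCR measurement
#'
#' A pair of threshold-cycle values for a target transcript and the
#' reference (housekeeping) transcript measured in the same sample.
#'
#' @param ct_target,ct_reference Finite positive Ct values (cycles).
#' @param sample_label Optional sample name.
#' @return An object of class `qpcr_measurement`.
#' @export
qpcr_measurement <- function(ct_target, ct_reference, sample_label = "") {
  stopifnot(is.numeric(ct_target), length(ct_target) == 1L,
            is.finite(ct_target), ct_target > 0,
            is.numeric(ct_reference), length(ct_reference) == 1L,
            is.finite(ct_reference), ct_reference > 0)
  structure(list(ct_target = ct_target, ct_reference = ct_reference,
                 sample_label = as.character(sample_label)),
            class = "qpcr_measurement")
}

#' Relative expression by the delta-delta-Ct method
#'
#' 2^-ddCt with ddCt = (Ct_target - Ct_ref)_sample -
#' (Ct_target - Ct_ref)_calibrator. Assumes exact base-2 amplification
#' efficiency.
#'
#' @param sample,calibrator `qpcr_measurement` objects.
#' @return Fold change of the target relative to the calibrator sample.
#' @export
ddct_relative_expression <- function(sample, calibrator) {
  stopifnot(inherits(sample, "qpcr_measurement"),
            inherits(calibrator, "qpcr_measurement"))
  dct_s <- sample$ct_target - sample$ct_reference
  dct_c <- calibrator$ct_target - calibrator$ct_reference
  2^(-(dct_s - dct_c))
}
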