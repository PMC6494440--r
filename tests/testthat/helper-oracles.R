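# Independent oracles used across the suite. Each reimplements the checked
# quantity from first principles, never by calling the package code path.

# Exhaustive hypergeometric upper tail: enumerate every size-n2 draw from a
# universe of N containing n1 marked elements. Feasible for N <= 12.
enum_hypergeom_tail <- function(overlap, n1, n2, N) {
  draws <- utils::combn(N, n2)
  marked <- seq_len(n1)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= overlap)
}

# Hand-coded TMM factor for one sample against a reference, following the
# published recipe: M/A log-ratios on library-scaled counts, double trim
# (30% of M, 5% of A) by ranks, inverse asymptotic-variance weights.
tmm_factor_oracle <- function(obs, ref) {
  nO <- sum(obs); nR <- sum(ref)
  logR <- log2((obs / nO) / (ref / nR))
  absE <- (log2(obs / nO) + log2(ref / nR)) / 2
  v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
  loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
  keep <- rank(logR) >= loL & rank(logR) <= hiL &
    rank(absE) >= loS & rank(absE) <= hiS
  2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
}

# Full TMM oracle: reference = sample whose upper-quartile/library ratio is
# closest to the mean, factors rescaled to geometric mean 1.
tmm_oracle <- function(counts, lib = colSums(counts)) {
  f75 <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_factor_oracle(counts[, j], counts[, ref])
  }, numeric(1))
  f / exp(mean(log(f)))
}

# Normal-equations least squares residuals: R = Y - X (X'X)^-1 X' Y.
residual_oracle <- function(Y, X) {
  R <- t(t(Y) - X %*% solve(t(X) %*% X, t(X) %*% t(Y)))
  dimnames(R) <- dimnames(Y)
  R
}

# Shortest directed distance from a seed by matrix-power reachability:
# dist(v) is the smallest d with (A^d)[seed, v] > 0. Independent of the
# package's BFS code path.
shortest_dist_oracle <- function(nodes, edges, seed) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) A[cbind(edges$from, edges$to)] <- 1
  dist <- rep(Inf, n)
  names(dist) <- nodes
  dist[seed] <- 0
  r <- as.numeric(nodes == seed)
  for (d in seq_len(n)) {
    r <- as.numeric((r %*% A) > 0)
    dist[r > 0 & !is.finite(dist)] <- d
  }
  dist
}

# A small random digraph as an edge data frame (no self-loops).
random_digraph <- function(n_nodes, p_edge) {
  nodes <- paste0("n", seq_len(n_nodes))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs[stats::runif(nrow(pairs)) < p_edge, , drop = FALSE]
}

# Tiny genotype-labelled count fixture.
tiny_counts <- function(n_genes = 8, groups = c(WT = 3, APP_PSEN1 = 3),
                        seed = 42, base = 100) {
  set.seed(seed)
  n <- sum(groups)
  m <- matrix(rpois(n_genes * n, base), n_genes, n,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n))))
  count_matrix(m, setNames(rep(names(groups), groups), colnames(m)))
}
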