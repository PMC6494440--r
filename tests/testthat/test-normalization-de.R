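test_that("expression filter keeps exactly genes with CPM >= 1 somewhere", {
  m <- rbind(zero = c(0, 0), boundary = c(1, 0), below = c(0, 1),
             high = c(50, 80))
  # library sizes 1e6 and 2e6: count 1 is CPM 1 in s1 but CPM 0.5 in s2
  m <- rbind(m, filler1 = c(1e6 - 51, 0), filler2 = c(0, 2e6 - 81))
  colnames(m) <- c("s1", "s2")
  cm <- count_matrix(m, c(s1 = "WT", s2 = "APP_PSEN1"))
  expect_equal(unname(cm$library_sizes), c(1e6, 2e6))
  kept <- rownames(filter_expressed(cm)$counts)
  expect_true(all(c("boundary", "high") %in% kept))
  expect_false(any(c("zero", "below") %in% kept))
  # original sequencing depths preserved after filtering
  expect_equal(filter_expressed(cm)$library_sizes, cm$library_sizes)
  empty <- count_matrix(matrix(c(1, 1), 1, 2,
                               dimnames = list("g", c("a", "b"))),
                        c(a = "WT", b = "WT"))
  empty$counts[] <- 0
  empty$library_sizes[] <- 1e7
  expect_error(filter_expressed(empty), "no genes")
})

test_that("TMM factors are 1 for identical or depth-rescaled samples", {
  set.seed(3)
  base <- rpois(100, 300)
  m <- cbind(s1 = base, s2 = base, s3 = base)
  rownames(m) <- paste0("g", 1:100)
  cm <- count_matrix(m, c(s1 = "WT", s2 = "WT", s3 = "WT"))
  expect_equal(unname(tmm_factors(cm)$tmm_factor), rep(1, 3))

  m2 <- cbind(s1 = base, s2 = base * 2, s3 = base * 5)
  rownames(m2) <- paste0("g", 1:100)
  cm2 <- count_matrix(m2, c(s1 = "WT", s2 = "WT", s3 = "WT"))
  expect_equal(unname(tmm_factors(cm2)$tmm_factor), rep(1, 3),
               tolerance = 1e-9)
})

test_that("TMM matches the independently coded published formula", {
  set.seed(99)
  m <- matrix(rnbinom(50 * 4, mu = 200, size = 5), 50, 4,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  m[1, 2] <- 60000  # one sample spiked by a dominant gene
  cm <- count_matrix(m, setNames(rep(c("WT", "APP_PSEN1"), each = 2),
                                 colnames(m)))
  f <- tmm_factors(cm)
  expect_equal(unname(f$tmm_factor), tmm_oracle(m), tolerance = 1e-6)
  expect_equal(exp(mean(log(f$tmm_factor))), 1, tolerance = 1e-9)
  expect_equal(unname(f$effective_library_size),
               unname(cm$library_sizes * f$tmm_factor))
  # invariant to gene order
  o <- sample(nrow(m))
  cmo <- count_matrix(m[o, ], setNames(rep(c("WT", "APP_PSEN1"), each = 2),
                                       colnames(m)))
  expect_equal(tmm_factors(cmo)$tmm_factor, f$tmm_factor, tolerance = 1e-12)
})

test_that("covariate residualization matches the normal-equations oracle", {
  set.seed(11)
  Y <- matrix(rnorm(10 * 8), 10, 8)
  cov <- data.frame(batch = factor(rep(c("a", "b"), 4)),
                    rin = runif(8, 5, 9))
  R <- residualize_covariates(Y, cov)
  X <- model.matrix(~ batch + rin, cov)
  expect_equal(R, residual_oracle(Y, X), tolerance = 1e-8)
  # intercept-only design mean-centers each gene
  expect_equal(residualize_covariates(Y, NULL), Y - rowMeans(Y))
  # residualizing a gene on itself leaves ~0
  self <- residualize_covariates(Y[1, , drop = FALSE],
                                 data.frame(x = Y[1, ]))
  expect_lt(max(abs(self)), 1e-10)
  expect_error(
    residualize_covariates(Y, data.frame(a = 1:8, b = 2 * (1:8))),
    "collinear")
})

test_that("moderated fit honours the posterior-variance identity and limits", {
  set.seed(21)
  # heterogeneous gene variances so the prior df is finite and informative
  sds <- sqrt(1 / rgamma(200, shape = 2, rate = 2))
  le <- matrix(rnorm(200 * 10, mean = 6, sd = rep(sds, 10)), 200, 10,
               dimnames = list(paste0("g", 1:200), paste0("s", 1:10)))
  g <- rep(c("WT", "APP_PSEN1"), each = 5)
  fit <- fit_moderated_model(le, g)
  expect_true(is.finite(fit$d0) && fit$d0 > 0)
  expect_equal(unname(fit$s2_post),
               unname((fit$d0 * fit$s02 + fit$df_residual * fit$s2) /
                        (fit$d0 + fit$df_residual)))
  # d0 = Inf collapses every posterior variance to the common prior
  finf <- fit_moderated_model(le, g, moderation = "infinite")
  expect_true(all(finf$s2_post == finf$s02))
  # d0 = 0 disables shrinkage entirely
  f0 <- fit_moderated_model(le, g, moderation = "none")
  expect_equal(f0$s2_post, f0$s2)
  expect_error(fit_moderated_model(le[, 1:6], c(rep("a", 5), "b")),
               "fewer than 2")
})

test_that("unmoderated t equals the pooled two-sample t computed by hand", {
  x <- c(4.1, 5.0, 4.4)
  y <- c(6.2, 5.8, 6.9)
  le <- matrix(c(x, y), 1, 6,
               dimnames = list("g1", paste0("s", 1:6)))
  g <- rep(c("A", "B"), each = 3)
  tab <- contrast_table(fit_moderated_model(le, g, moderation = "none"),
                        c("B", "A"))
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_hand <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(tab$t, t_hand, tolerance = 1e-12)
  expect_equal(tab$log2FC, mean(y) - mean(x))
  expect_equal(tab$p, 2 * pt(-abs(t_hand), df = 4), tolerance = 1e-12)
})

test_that("moderated t agrees with the limma eBayes cross-check", {
  set.seed(33)
  sim <- simulate_counts(simulation_config(n_genes = 400, seed = 33))
  de <- run_de(sim$counts)
  le <- log_cpm(de$filtered, de$norm)
  design <- model.matrix(~ 0 + sim$counts$genotype)
  colnames(design) <- levels(sim$counts$genotype)
  cfit <- limma::contrasts.fit(
    limma::lmFit(le, design),
    limma::makeContrasts(APP_PSEN1 - WT, levels = design))
  eb <- limma::eBayes(cfit)
  tab <- de$tables$APP_vs_WT
  expect_equal(tab$log2FC, unname(eb$coefficients[tab$gene, 1]),
               tolerance = 1e-8)
  expect_gt(cor(tab$t, eb$t[tab$gene, 1]), 0.999)
})

test_that("contrast tables are antisymmetric and null contrasts are flat", {
  le <- matrix(rep(c(1, 2, 3, 1, 2, 3), each = 5), 5, 6,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  g <- rep(c("A", "B"), each = 3)
  fit <- fit_moderated_model(le, g)
  tab <- contrast_table(fit, c("B", "A"))
  expect_true(all(tab$t == 0))
  expect_true(all(tab$p == 1))
  set.seed(5)
  le2 <- matrix(rnorm(30, 5), 5, 6, dimnames = dimnames(le))
  fit2 <- fit_moderated_model(le2, g)
  fwd <- contrast_table(fit2, c("B", "A"))
  rev <- contrast_table(fit2, c("A", "B"))
  expect_equal(fwd$log2FC, -rev$log2FC)
  expect_equal(fwd$p, rev$p)
  expect_error(contrast_table(fit2, c("B", "C")), "unknown genotype")
})

test_that("planted 4-fold genes are estimated near log2FC = 1 bias-free scale", {
  sim <- simulate_counts(simulation_config(seed = 1))
  de <- run_de(sim$counts)
  tab <- de$tables$APP_vs_WT
  planted <- intersect(sim$truth$planted_up_in_APP, tab$gene)
  med <- median(tab$log2FC[match(planted, tab$gene)])
  expect_lt(abs(med - sim$truth$true_log2fc[["APP_PSEN1"]]), 0.25)
})

test_that("signatures partition DEGs by sign at the FDR threshold", {
  sim <- simulate_counts(simulation_config(seed = 4))
  de <- run_de(sim$counts)
  tab <- de$tables$APPko_vs_APP
  sig <- call_signature(tab, 0.05)
  expect_equal(length(sig$up) + length(sig$down), sum(tab$FDR <= 0.05))
  expect_length(intersect(sig$up, sig$down), 0)
  # all-null table gives empty sets
  flat <- data.frame(gene = "g1", log2FC = 0, t = 0, p = 1, FDR = 1)
  s0 <- call_signature(flat)
  expect_length(s0$up, 0)
  expect_length(s0$down, 0)
})

test_that("the DE pipeline is deterministic given the counts", {
  sim <- simulate_counts(simulation_config(n_genes = 300, seed = 8))
  d1 <- run_de(sim$counts)
  d2 <- run_de(sim$counts)
  expect_identical(d1$tables, d2$tables)
})

test_that("moderated null p-values are approximately uniform", {
  sim <- simulate_counts(simulation_config(planted_module_size = 0,
                                           seed = 12))
  de <- run_de(sim$counts)
  p <- de$tables$APP_vs_WT$p
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})
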