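test_that("exact two-fold counts with unit size factors give lfc = 1", {
  set.seed(2)
  b <- sample(20:200, 40)
  counts <- cbind(matrix(rep(2L * b, 6), ncol = 6),
                  matrix(rep(b, 10), ncol = 10))
  dimnames(counts) <- list(sprintf("g%02d", 1:40),
                           c(sprintf("case%02d", 1:6), sprintf("ctrl%02d", 1:10)))
  samples <- toy_samples(6, 10)
  de <- suppressWarnings(nb_wald_test(counts, samples,
                                      sf = setNames(rep(1, 16), colnames(counts)),
                                      dispersion = 0.05))
  expect_equal(de$lfc, rep(1, 40), tolerance = 1e-6)
  expect_equal(de$case_mean / de$control_mean, rep(2, 40), tolerance = 1e-12)
  expect_true(all(de$p < 0.05))
})

test_that("BH adjustment matches analytic cases and the brute-force definition", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(14)
  p <- runif(100)^2
  expect_equal(bh_adjust(p), bf_bh(p))
  # missing values propagate and are excluded from m
  pna <- c(0.01, NA, 0.04)
  adj <- bh_adjust(pna)
  expect_true(is.na(adj[2]))
  expect_equal(adj[c(1, 3)], bf_bh(c(0.01, 0.04)))
  expect_error(bh_adjust(c(0.2, 1.3)), "\\[0, 1\\]")
  # monotone when input sorted ascending
  expect_true(!is.unsorted(bh_adjust(sort(p))))
  # adjusted never below nominal
  expect_true(all(bh_adjust(p) >= p))
})

test_that("DE calling ranks by p with |lfc| then gene id tie-breaks", {
  tb <- data.frame(gene_id = c("b", "a", "d", "c"),
                   lfc = c(1, -2, 0.5, 0.5),
                   p = c(0.001, 0.001, 0.002, 0.002),
                   padj = c(0.01, 0.01, 0.02, 0.9))
  expect_identical(call_de(tb), c("a", "b", "d"))
  tb$padj <- rep(1, 4)
  expect_identical(call_de(tb), character(0))
  # ties on p and |lfc| resolve by gene id, stable across shuffles
  tb2 <- data.frame(gene_id = c("z", "y"), lfc = c(1, 1),
                    p = c(0.001, 0.001), padj = c(0.01, 0.01))
  expect_identical(call_de(tb2), call_de(tb2[2:1, ]))
  expect_identical(call_de(tb2), c("y", "z"))
})

test_that("null genes attain near-nominal Wald type-I error", {
  sim <- simulate_counts(sim_config(n_genes = 400, de_fraction = 0, seed = 19))
  pp <- suppressMessages(preprocess_counts(sim$counts, sim$samples$condition))
  de <- suppressWarnings(nb_wald_test(pp$counts, sim$samples,
                                      sf = pp$size_factors,
                                      dispersion = pp$dispersion))
  rate <- mean(de$p < 0.05, na.rm = TRUE)
  se <- sqrt(0.05 * 0.95 / sum(!is.na(de$p)))
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("strong planted effects are recovered with high recall", {
  sim <- simulate_counts(sim_config(n_genes = 500, lfc_scale = 1.5,
                                    base_mean_meanlog = log(200),
                                    base_mean_sdlog = 1, seed = 23))
  pp <- suppressMessages(preprocess_counts(sim$counts, sim$samples$condition))
  de <- suppressWarnings(nb_wald_test(pp$counts, sim$samples,
                                      sf = pp$size_factors,
                                      dispersion = pp$dispersion))
  truth <- sim$truth[match(de$gene_id, sim$truth$gene_id), ]
  recall <- mean(de$is_de[truth$is_de])
  expect_gt(recall, 0.8)
  fdr <- mean(!truth$is_de[de$is_de])
  expect_lt(fdr, 0.15)
})

test_that("power at lfc = 1, mean 100, alpha = 0.1, n = 20 vs 49 stays at its frozen level", {
  # 200 genes all with a true two-fold change; detection rate frozen from
  # an independent 500-replicate calibration at these settings
  set.seed(29)
  n1 <- 20; n2 <- 49
  mu <- c(rep(200, n1), rep(100, n2))
  counts <- t(vapply(1:200, function(i) rnbinom(n1 + n2, mu = mu, size = 10),
                     numeric(n1 + n2)))
  dimnames(counts) <- list(sprintf("g%03d", 1:200),
                           c(sprintf("case%02d", 1:n1), sprintf("ctrl%02d", 1:n2)))
  samples <- toy_samples(n1, n2)
  de <- suppressWarnings(nb_wald_test(counts, samples,
                                      sf = setNames(rep(1, n1 + n2), colnames(counts)),
                                      dispersion = 0.1))
  expect_gt(mean(de$is_de), 0.95)
})

test_that("DE calls are invariant under sample permutation", {
  sim <- simulate_counts(sim_config(n_genes = 150, seed = 37))
  pp <- suppressMessages(preprocess_counts(sim$counts, sim$samples$condition))
  de1 <- suppressWarnings(nb_wald_test(pp$counts, sim$samples,
                                       sf = pp$size_factors,
                                       dispersion = pp$dispersion))
  set.seed(1); perm <- sample(ncol(pp$counts))
  de2 <- suppressWarnings(nb_wald_test(pp$counts[, perm], sim$samples[perm, ],
                                       sf = pp$size_factors[perm],
                                       dispersion = pp$dispersion))
  expect_equal(de1$padj, de2$padj, tolerance = 1e-8)
  expect_identical(call_de(de1), call_de(de2))
})

test_that("lfc sign agrees with the group mean difference", {
  sim <- simulate_counts(sim_config(n_genes = 200, seed = 43))
  pp <- suppressMessages(preprocess_counts(sim$counts, sim$samples$condition))
  # remove covariate structure so the condition effect is the only term
  samples <- sim$samples
  samples$age_of_death <- 60
  samples$rin <- 8
  de <- suppressWarnings(suppressMessages(
    nb_wald_test(pp$counts, samples, sf = pp$size_factors,
                 dispersion = pp$dispersion)))
  both <- de$case_mean > 0 & de$control_mean > 0 & !is.na(de$lfc) &
    abs(de$lfc) > 0.05
  expect_true(all(sign(de$lfc[both]) ==
                    sign(de$case_mean[both] - de$control_mean[both])))
})

test_that("the design encodes age bins and RIN and rejects collinearity", {
  s <- data.frame(condition = rep(c("HD", "control"), c(3, 3)),
                  age_of_death = c(40, 50, 70, 80, 91, 45),
                  rin = c(8, 6, 8, 6, 8, 6))
  d <- de_design(s)
  ab <- grep("age_bin", colnames(d$model_matrix), value = TRUE)
  expect_true(length(ab) >= 1)
  expect_equal(unname(d$model_matrix[, "conditionHD"]), c(1, 1, 1, 0, 0, 0))
  # age 40 -> first bin; bins are exhaustive including 76+
  expect_error(de_design(data.frame(condition = "HD", age_of_death = -5, rin = 7)),
               "binning range|labeling")
  # condition perfectly aligned with RIN dichotomy -> collinear design
  s2 <- data.frame(condition = rep(c("HD", "control"), c(3, 3)),
                   age_of_death = rep(60, 6),
                   rin = c(8, 8.5, 9, 6, 6.5, 7))
  expect_error(suppressMessages(de_design(s2)), "collinear")
})
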