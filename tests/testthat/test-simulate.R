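test_that("null simulation has no DE genes and zero fold changes", {
  sim <- simulate_counts(sim_config(n_genes = 50, n_cases = 4, n_controls = 4,
                                    de_fraction = 0, seed = 11))
  expect_false(any(sim$truth$is_de))
  expect_identical(sim$truth$true_lfc, rep(0, 50))
  expect_false(any(sim$truth$is_exclusive))
  expect_true(all(sim$counts >= 0))
  expect_true(is.integer(sim$counts))
})

test_that("identical seeds reproduce identical counts and metadata", {
  cfg <- sim_config(n_genes = 120, seed = 7)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_counts(sim_config(n_genes = 120, seed = 8))
  expect_false(identical(a$counts, c2$counts))
})

test_that("vanishing dispersion approaches the Poisson variance-mean limit", {
  # 10,000 samples per gene, unit depths, no DE: var/mean ratio near 1
  sim <- simulate_counts(sim_config(
    n_genes = 40, n_cases = 5000, n_controls = 5000, de_fraction = 0,
    nb_dispersion = 1e-6, depth_range = c(1, 1),
    base_mean_meanlog = log(500), base_mean_sdlog = 0.3, seed = 21))
  ratio <- apply(sim$counts, 1L, var) / rowMeans(sim$counts)
  expect_true(all(abs(ratio - 1) < 0.1))
})

test_that("configured DE structure is realized: up fraction, exclusivity, lfc recovery", {
  cfg <- sim_config(n_genes = 2000, seed = 31)
  sim <- simulate_counts(cfg)
  tr <- sim$truth
  n_de <- sum(tr$is_de)
  expect_equal(n_de, round(cfg$de_fraction * cfg$n_genes))
  # fraction up within 3 binomial SE of up_fraction (exclusive genes are
  # forced up, a small known excess)
  frac_up <- mean(tr$true_lfc[tr$is_de] > 0)
  se <- sqrt(cfg$up_fraction * (1 - cfg$up_fraction) / n_de)
  expect_lt(abs(frac_up - cfg$up_fraction), 3 * se + cfg$exclusive_fraction)
  # exclusive genes are DE, up, and nearly silent in controls
  expect_true(all(tr$is_de[tr$is_exclusive]))
  expect_true(all(tr$true_lfc[tr$is_exclusive] > 0))
  ctrl <- sim$samples$condition == "control"
  norm <- sweep(sim$counts, 2L, sim$samples$depth, "/")
  expect_true(all(rowMeans(norm[tr$is_exclusive, ctrl, drop = FALSE]) < 0.5))
  # non-DE genes have zero true lfc
  expect_true(all(tr$true_lfc[!tr$is_de] == 0))
})

test_that("empirical log2 fold changes regress on truth with slope near 1", {
  sim <- simulate_counts(sim_config(
    n_genes = 300, n_cases = 20, n_controls = 20, de_fraction = 0.5,
    exclusive_fraction = 0, base_mean_meanlog = log(300),
    base_mean_sdlog = 0.5, seed = 41))
  norm <- sweep(sim$counts, 2L, sim$samples$depth, "/")
  case <- sim$samples$condition == "HD"
  emp <- log2(rowMeans(norm[, case]) / rowMeans(norm[, !case]))
  de <- sim$truth$is_de
  fit <- lm(emp[de] ~ sim$truth$true_lfc[de])
  expect_lt(abs(coef(fit)[2] - 1), 0.05)
  expect_gt(summary(fit)$r.squared, 0.9)
})

test_that("clinical covariates have the cohort's structure", {
  sim <- simulate_counts(sim_config(n_genes = 10, seed = 51))
  s <- sim$samples
  hd <- s$condition == "HD"
  expect_equal(sum(hd), 20); expect_equal(sum(!hd), 49)
  # CAG-onset negative correlation, onset before death, case-only fields
  expect_lt(cor(s$cag[hd], s$onset[hd]), 0)
  expect_true(all(s$onset[hd] <= s$age_of_death[hd]))
  expect_true(all(is.na(s$cag[!hd])))
  expect_true(all(s$hv_striatal[hd] >= 0 & s$hv_cortical[hd] >= 0))
})

test_that("simulation configuration is validated", {
  expect_error(sim_config(n_genes = 0), "positive")
  expect_error(sim_config(de_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(n_genes = 10, de_fraction = 0.01), ">= 1")
  expect_error(sim_config(depth_range = c(2, 1)), "depth_range")
  expect_error(sim_config(nb_dispersion = 0), "positive")
})

test_that("planted genesets draw from the stated rank depth", {
  ids <- sprintf("g%03d", 1:200)
  gs <- simulate_genesets(ids, n_sets = 1, set_size = 25,
                          planted = data.frame(set_name = "P",
                                               planted_depth = 25,
                                               planted_overlap = 25),
                          seed = 3)
  expect_true(all(gs$sets$P %in% ids[1:25]))
  expect_length(gs$sets$P, 25)
})

test_that("non-planted sets overlap the top-n prefix at the chance rate", {
  ids <- sprintf("g%03d", 1:200)
  k <- 20; n_top <- 50
  overlaps <- vapply(1:1000, function(s) {
    gs <- simulate_genesets(ids, n_sets = 1, set_size = k, seed = s)
    length(intersect(gs$sets[[1]], ids[1:n_top]))
  }, numeric(1))
  expected <- k * n_top / length(ids)          # hypergeometric mean = 5
  sd1 <- sqrt(n_top * (k / 200) * (1 - k / 200) * (200 - n_top) / 199)
  expect_lt(abs(mean(overlaps) - expected), 3 * sd1 / sqrt(1000))
})

test_that("geneset simulation is deterministic and validated", {
  ids <- sprintf("g%03d", 1:100)
  a <- simulate_genesets(ids, n_sets = 5, set_size = c(10, 20), seed = 9)
  b <- simulate_genesets(ids, n_sets = 5, set_size = c(10, 20), seed = 9)
  expect_identical(a$sets, b$sets)
  expect_error(simulate_genesets(ids, 1, set_size = 5,
                                 planted = data.frame(set_name = "P",
                                                      planted_depth = 10,
                                                      planted_overlap = 8)),
               "planted_overlap")
  expect_error(simulate_genesets(ids, 1, set_size = 50,
                                 planted = data.frame(set_name = "P",
                                                      planted_depth = 500,
                                                      planted_overlap = 10)),
               "planted_depth")
})
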