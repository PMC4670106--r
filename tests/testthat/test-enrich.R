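test_that("nested subsets step by 25 and append the remainder", {
  r100 <- sprintf("g%04d", 1:100)
  expect_equal(as.integer(names(nested_subsets(r100, 25))), c(25, 50, 75, 100))
  expect_equal(as.integer(names(nested_subsets(r100[1:30], 25))), c(25, 30))
  expect_equal(as.integer(names(nested_subsets(r100[1:10], 25))), 10)
  big <- sprintf("g%04d", 1:5480)
  sizes <- as.integer(names(nested_subsets(big, 25)))
  expect_equal(sizes[1:2], c(25, 50))
  expect_equal(utils::tail(sizes, 2), c(5475, 5480))
  expect_equal(length(sizes), 5480 %/% 25 + 1)
  # strictly nested prefixes
  subs <- nested_subsets(r100[1:30], 25)
  expect_identical(subs[[1]], subs[[2]][1:25])
  expect_error(nested_subsets(character(0)), "empty")
  expect_error(nested_subsets(r100, 0), "step")
})

test_that("hypergeometric tail matches exhaustive enumeration", {
  u <- sprintf("u%02d", 1:10)
  expect_equal(hypergeom_enrich(u[1:5], u[c(1, 2, 3, 9)], u), 66 / 252)
  expect_equal(enum_hypergeom(10, 4, 5, 3), 66 / 252)
  # overlap 0 and subset = universe are full-tail cases
  expect_equal(hypergeom_enrich(u[5:9], u[10], u), 1)
  expect_equal(hypergeom_enrich(u, u[1:4], u), 1)
  # sweep all parameterizations with universe size <= 8 (the acceptance
  # suite extends this to 12)
  for (N in c(4, 6, 8)) {
    un <- sprintf("u%02d", seq_len(N))
    for (K in 1:N) for (n in 1:N) {
      p <- hypergeom_enrich(un[seq_len(n)], un[seq(N - K + 1, N)], un)
      x <- length(intersect(seq_len(n), seq(N - K + 1, N)))
      expect_equal(p, enum_hypergeom(N, K, n, x),
                   info = sprintf("N=%d K=%d n=%d", N, K, n))
    }
  }
  expect_error(hypergeom_enrich(u[1:3], u[1:2], character(0)), "empty universe")
  expect_error(hypergeom_enrich(c(u[1], "zz"), u[1:2], u), "contained")
  expect_warning(p1 <- hypergeom_enrich(u[1:3], "zz", u), "no members")
  expect_equal(p1, 1)
})

test_that("enum oracle and tail test need the marked-vs-overlap correction", {
  # p is P(X >= observed); enumeration at a different x must disagree,
  # guarding against an off-by-one in the tail
  u <- sprintf("u%02d", 1:10)
  expect_false(isTRUE(all.equal(hypergeom_enrich(u[1:5], u[c(1, 2, 3, 9)], u),
                                enum_hypergeom(10, 4, 5, 4))))
})

test_that("true-path propagation feeds ancestors and reduces to flat testing", {
  u <- sprintf("g%02d", 1:40)
  # 3-level DAG: leaf1, leaf2 -> mid -> root; extra edge leaf1 -> root
  col <- geneset_collection(
    list(leaf1 = u[1:5], leaf2 = u[6:10], mid = u[11:12], root = character(0)),
    hierarchy = data.frame(child = c("leaf1", "leaf2", "mid", "leaf1"),
                           parent = c("mid", "mid", "root", "root")))
  prop <- propagate_annotations(col)
  expect_setequal(prop$sets$mid, u[1:12])
  expect_setequal(prop$sets$root, u[1:12])   # manual transitive closure
  expect_setequal(prop$sets$leaf1, u[1:5])
  # parent with no direct members is tested on exactly its children's genes
  col2 <- geneset_collection(list(leaf = u[1:6], parent = character(0)),
                             hierarchy = data.frame(child = "leaf",
                                                    parent = "parent"))
  p <- go_enrich(u[1:10], col2, u)
  expect_equal(unname(p["parent"]), unname(p["leaf"]))
  # flat hierarchy: identical to per-set hypergeometric
  col3 <- geneset_collection(list(a = u[1:8], b = u[5:20]))
  expect_equal(go_enrich(u[1:10], col3, u),
               c(a = hypergeom_enrich(u[1:10], u[1:8], u),
                 b = hypergeom_enrich(u[1:10], u[5:20], u)))
  expect_error(geneset_collection(list(a = u[1:2], b = u[3:4]),
                                  hierarchy = data.frame(child = c("a", "b"),
                                                         parent = c("b", "a"))),
               "cyclic")
})

test_that("enrichment profiles peak where the signal is planted and decay after", {
  universe <- sprintf("g%04d", 1:1000)
  ranked <- universe[1:100]
  subs <- nested_subsets(ranked, 25)
  col <- geneset_collection(list(top25 = universe[1:25]))
  pr <- enrichment_profile(col, subs, universe)
  expect_s3_class(pr, "enrich_profile")
  expect_equal(dim(pr$p), c(1, 4))
  expect_equal(which.min(pr$p["top25", ]), c(`25` = 1))
  expect_true(all(diff(pr$neglogp["top25", ]) < 0))
  expect_equal(unname(pr$best_p["top25"]), min(pr$p))
  expect_true(all(pr$mask["top25", ]))
  # observed overlap is non-decreasing with subset size for any geneset
  set.seed(6)
  gs <- sample(universe, 60)
  ov <- vapply(subs, function(s) length(intersect(s, gs)), numeric(1))
  expect_true(all(diff(ov) >= 0))
  # empty collection -> empty profile
  pr0 <- enrichment_profile(geneset_collection(list()), subs, universe)
  expect_equal(nrow(pr0$p), 0)
})

test_that("profile p-values equal the direct per-cell hypergeometric test", {
  set.seed(61)
  universe <- sprintf("g%04d", 1:300)
  ranked <- sample(universe, 80)
  subs <- nested_subsets(ranked, 25)
  sets <- lapply(1:10, function(i) sample(universe, sample(10:40, 1)))
  names(sets) <- sprintf("s%02d", 1:10)
  pr <- enrichment_profile(geneset_collection(sets), subs, universe)
  for (nm in names(sets)) for (j in seq_along(subs))
    expect_equal(pr$p[nm, j], hypergeom_enrich(subs[[j]], sets[[nm]], universe))
})

test_that("geneset ranking equals a brute-force min-per-row sort", {
  set.seed(62)
  universe <- sprintf("g%04d", 1:500)
  ranked <- universe[sample(500, 150)]
  subs <- nested_subsets(ranked, 25)
  sets <- lapply(1:50, function(i) sample(universe, 30))
  names(sets) <- sprintf("s%02d", 1:50)
  pr <- enrichment_profile(geneset_collection(sets), subs, universe)
  brute <- names(sort(apply(pr$p, 1, min)))[1:15]
  # resolve ties identically (by name) before comparing
  mins <- apply(pr$p, 1, min)
  brute <- names(mins)[order(mins, names(mins))][1:15]
  expect_identical(rank_genesets(pr, 15), brute)
  expect_identical(rank_genesets(pr, 1), brute[1])
  expect_error(rank_genesets(pr, 0), "top_k")
})

test_that("profile input validation catches unnested or out-of-universe subsets", {
  universe <- sprintf("g%04d", 1:100)
  col <- geneset_collection(list(a = universe[1:10]))
  bad <- list(universe[1:25], universe[c(30:54)])
  expect_error(enrichment_profile(col, bad, universe), "nested")
  subs <- nested_subsets(c(universe[1:20], "not_in_universe"), 10)
  expect_error(enrichment_profile(col, subs, universe), "contained")
})
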