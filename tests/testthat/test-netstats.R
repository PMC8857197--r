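test_that("motif counts match exhaustive enumeration on all 3-node digraphs", {
  # all 64 loop-free digraphs on 3 nodes
  pairs <- expand.grid(from = c("a", "b", "c"), to = c("a", "b", "c"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  for (bits in 1:63) {
    sel <- as.logical(bitwAnd(bits, 2^(0:5)))
    net <- grn(data.frame(regulator = pairs$from[sel], target = pairs$to[sel]))
    got <- count_motifs(net)
    want <- enumerate_motifs(net)
    expect_equal(got$ffc, want$ffc)
    expect_equal(got$complex_ffc, want$complex_ffc)
    expect_equal(got$feedback_3, want$feedback_3)
  }
})

test_that("motif counts match enumeration on random digraphs up to 5 nodes", {
  for (seed in 1:40) {
    n <- 3 + seed %% 3 # 3..5 nodes
    net <- random_digraph_grn(n, 0.4, seed = seed)
    got <- count_motifs(net)
    want <- enumerate_motifs(net)
    expect_equal(got$ffc, want$ffc)
    expect_equal(got$complex_ffc, want$complex_ffc)
    expect_equal(got$feedback_3, want$feedback_3)
  }
})

test_that("the structural profile reproduces hand-computed toy values", {
  cyc <- toy_grn(c("A>B", "B>C", "C>A"))
  p <- structural_profile(cyc)
  expect_length(p, 15L)
  expect_named(p, structural_profile_names())
  expect_equal(unname(p["feedback_loops_3"]), 1)
  expect_equal(unname(p["feedforward_circuits"]), 0)
  expect_equal(unname(p["density"]), 0.5)
  expect_equal(unname(p["regulators_pct"]), 100)
  expect_equal(unname(p["giant_component_pct"]), 100)

  ffc <- toy_grn(c("A>B", "A>C", "B>C"))
  p2 <- structural_profile(ffc)
  expect_equal(unname(p2["feedforward_circuits"]), 1)
  expect_equal(unname(p2["feedback_loops_3"]), 0)

  two_comp <- toy_grn(c("A>B", "C>D"))
  p3 <- structural_profile(two_comp)
  expect_equal(unname(p3["weakly_connected_components"]), 2)
  expect_equal(unname(p3["giant_component_pct"]), 50)

  selfy <- grn(data.frame(regulator = c("A", "A"), target = c("A", "B")))
  p4 <- structural_profile(selfy)
  expect_equal(unname(p4["self_regulation_pct"]), 50)
  expect_error(structural_profile(grn()), "empty")
})

test_that("ln(ln(N)) reference matches printed ultra-small-world values", {
  expect_equal(ultra_small_world_reference(6263), 2.17)
  expect_equal(ultra_small_world_reference(4739), 2.14)
  expect_equal(ultra_small_world_reference(4763), 2.14)
  expect_equal(ultra_small_world_reference(3804), 2.11)
  expect_equal(ultra_small_world_reference(5386), 2.15)
  expect_equal(ultra_small_world_reference(exp(exp(1))), 1.00)
  expect_error(ultra_small_world_reference(2), ">= 3")
})

test_that("CCDF regression recovers the exponent of an exact power-law sequence", {
  # counts chosen so that CCDF(k) = 1/k exactly: slope -1, alpha = 2
  degs <- rep(c(1, 2, 3, 4), times = c(6, 2, 1, 3))
  f <- fit_powerlaw_regression(degs)
  expect_equal(f$alpha, 2, tolerance = 1e-9)
  expect_equal(f$r2adj, 1, tolerance = 1e-9)
  expect_error(fit_powerlaw_regression(c(3, 3, 3)), "distinct")
})

test_that("CCDF regression recovers alpha within 0.15 on synthetic scale-free degrees", {
  for (alpha in c(2.0, 2.5, 3.0)) {
    est <- vapply(1:20, function(seed) {
      set.seed(alpha * 1000 + seed)
      degs <- rpowerlaw(2000, alpha)
      suppressWarnings(fit_powerlaw_regression(degs)$alpha)
    }, numeric(1))
    expect_lt(abs(median(est) - alpha), 0.15)
  }
})

test_that("discrete MLE recovers alpha and prefers the generating model", {
  set.seed(2024)
  x <- rpowerlaw(10000, 2.5)
  f <- fit_powerlaw_mle(x, candidates = "power_law")
  expect_lt(abs(f$alpha - 2.5), 0.1)
  # geometric sample: exponential must beat the power law by KS distance
  set.seed(7)
  geo <- rgeom(2000, 0.25) + 1L
  g <- fit_powerlaw_mle(geo, candidates = c("power_law", "exponential"))
  expect_equal(g$preferred, "exponential")
  expect_lt(g$model_comparison[["exponential"]],
            g$model_comparison[["power_law"]])
  expect_error(fit_powerlaw_mle(x, candidates = character()), "empty")
  expect_error(fit_powerlaw_mle(1:10), "at least 50")
})

test_that("C(k) scaling fits exact k^-1 data and requires enough degrees", {
  stats_in <- list(ck = data.frame(k = c(2, 4, 8, 16), ck = 1 / c(2, 4, 8, 16)))
  f <- suppressWarnings(fit_ck_scaling(stats_in)) # perfect fit trips lm's summary
  expect_equal(f$exponent, 1, tolerance = 1e-9)
  expect_equal(f$r2adj, 1, tolerance = 1e-9)
  expect_error(fit_ck_scaling(list(ck = data.frame(k = 2, ck = 0.5))), "three")
  expect_error(fit_ck_scaling(list(ck = data.frame(k = c(2, 3, 4), ck = 0))), "zero")
})

test_that("profile clustering pairs identical profiles and flags constant ones", {
  set.seed(5)
  base <- runif(15)
  profs <- rbind(p1 = base, p2 = base + rnorm(15, sd = 1e-3), p3 = rev(base) * 3)
  cl <- cluster_profiles(profs)
  expect_equal(cl$correlation["p1", "p2"], 1, tolerance = 1e-3)
  expect_equal(cl$hclust$merge[1, ], c(-1, -2)) # the near-identical pair merges first
  # input order invariance of the pairwise structure
  cl2 <- cluster_profiles(profs[c(3, 1, 2), ])
  expect_equal(cl2$correlation["p1", "p3"], cl$correlation["p1", "p3"])
  expect_error(cluster_profiles(rbind(a = rep(1, 15), b = runif(15))), "constant")
  expect_error(cluster_profiles(profs[1, , drop = FALSE]), "two profiles")
  # min-max scaling keeps the correlation matrix well-formed
  cl3 <- cluster_profiles(profs, scaling = "minmax")
  expect_true(all(abs(cl3$correlation) <= 1 + 1e-12))
})

test_that("network dissimilarity is zero on identity, symmetric, and bounded", {
  tri <- toy_grn(c("A>B", "B>C", "C>A"))
  path3 <- toy_grn(c("A>B", "B>C"))
  expect_equal(network_dissimilarity(tri, tri), 0, tolerance = 1e-12)
  expect_gt(network_dissimilarity(tri, path3), 0)
  expect_error(network_dissimilarity(tri, path3, weights = c(1, 1, 1)), "summing")
  for (seed in 1:20) {
    g1 <- random_digraph_grn(8, 0.25, seed = seed)
    g2 <- random_digraph_grn(8, 0.25, seed = seed + 100)
    d12 <- network_dissimilarity(g1, g2)
    d21 <- network_dissimilarity(g2, g1)
    expect_equal(d12, d21, tolerance = 1e-12)
    expect_gte(d12, 0)
    expect_lte(d12, 1)
    expect_equal(network_dissimilarity(g1, g1), 0, tolerance = 1e-12)
  }
})

test_that("with weight only on the distance term, equal distance distributions give zero", {
  # two disjoint-label copies of the same topology
  a <- toy_grn(c("A>B", "B>C"))
  b <- toy_grn(c("X>Y", "Y>Z"))
  expect_equal(network_dissimilarity(a, b, weights = c(1, 0, 0)), 0,
               tolerance = 1e-12)
})
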