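test_that("sampled subnetworks are connected, sized and reproducible", {
  set.seed(9)
  net <- random_instance(12, 0.35)
  for (k in 2:4) {
    sets <- sample_connected_subnetworks(net, k, 25, seed = 5)
    expect_true(all(lengths(sets) == k))
    expect_true(all(vapply(sets, function(g) subgraph_connected(net, g),
                           logical(1))))
    expect_identical(sample_connected_subnetworks(net, k, 25, seed = 5), sets)
  }
  # a path graph sampled at full size always returns the whole path
  path <- toy_net(c("A-B", "B-C", "C-D"))
  sets <- sample_connected_subnetworks(path, 4, 10, seed = 1)
  expect_true(all(vapply(sets, function(s)
    identical(s, c("A", "B", "C", "D")), logical(1))))
  expect_error(sample_connected_subnetworks(path, 5, 1), "component")
})

test_that("the truncated-normal fit recovers generating parameters", {
  set.seed(2000)
  counts <- pmin(pmax(rnorm(2000, 10, 2), 0), 30)
  null <- fit_coexpression_null(counts, c(0, 30))
  expect_false(null$degenerate)
  expect_lt(abs(null$mean - 10), 0.2)
  expect_lt(abs(null$sd - 2), 0.2)
})

test_that("a constant sample gives a degenerate point-mass null", {
  null <- fit_coexpression_null(rep(5, 50), c(0, 30))
  expect_true(null$degenerate)
  expect_identical(coexpression_pvalue(null, 5), 1)
  expect_identical(coexpression_pvalue(null, 4), 1)
  expect_identical(coexpression_pvalue(null, 6), 0)
})

test_that("co-expression p-values follow the truncated upper tail", {
  set.seed(17)
  counts <- pmin(pmax(rnorm(500, 6, 3), 0), 12)
  null <- fit_coexpression_null(counts, c(0, 12))
  # p at the lower truncation bound is 1; tail is non-increasing
  expect_equal(coexpression_pvalue(null, 0), 1)
  ps <- coexpression_pvalue(null, 0:12)
  expect_true(all(diff(ps) <= 1e-12))
  expect_gt(ps[12], 0)
  # the continuous upper tail vanishes at and beyond the truncation bound
  expect_equal(ps[13], 0)
  expect_identical(coexpression_pvalue(null, 13), 0)
  # quadrature oracle: integrate the truncated density over [x, upper]
  dens <- function(t) dnorm(t, null$mean, null$sd) /
    (pnorm(12, null$mean, null$sd) - pnorm(0, null$mean, null$sd))
  for (x in c(2, 5.5, 9)) {
    expect_equal(coexpression_pvalue(null, x),
                 integrate(dens, x, 12, rel.tol = 1e-9)$value,
                 tolerance = 1e-6)
  }
})

test_that("density p-values match exact combinatorial summation", {
  # worked case: 5 genes, 6 edges, module of 3 genes with 3 edges
  expect_equal(density_pvalue(5, 6, 3, 3), 20 / 120)
  expect_equal(density_pvalue(5, 6, 3, 3), 1 / 6)
  # boundary conventions
  expect_equal(density_pvalue(5, 6, 5, 6), 1)   # the whole network drawn
  expect_equal(density_pvalue(9, 4, 3, 0), 1)   # upper tail at the minimum
  # exhaustive check against the summation oracle on small networks
  for (n in 3:8) {
    N <- choose(n, 2)
    for (E in c(1, 3, N %/% 2, N)) {
      for (k in 2:n) {
        K <- choose(k, 2)
        for (m in 0:min(K, E)) {
          expect_equal(density_pvalue(n, E, k, m),
                       hyper_upper_oracle(N, E, K, m), tolerance = 1e-12)
        }
      }
    }
  }
  expect_error(density_pvalue(5, 6, 1, 0), "k")
  expect_error(density_pvalue(5, 6, 3, 4), "m")
})

test_that("module ranking averages the two criterion ranks", {
  set.seed(88)
  net <- random_instance(14, 0.35, n_conditions = 8)
  mods <- enumerate_dcbs(net, dcb_params(0.5, 2.5, 2), min_size = 2)
  skip_if(length(mods) < 2, "instance produced too few modules")
  ranked <- rank_modules(mods, net, epsilon = 2.5, n_samples = 100, seed = 3)
  for (m in ranked) {
    expect_equal(m$overall_rank, (m$rank_coexpression + m$rank_density) / 2)
    expect_true(m$p_coexpression >= 0 && m$p_coexpression <= 1)
    expect_true(m$p_density >= 0 && m$p_density <= 1)
  }
  overall <- vapply(ranked, `[[`, numeric(1), "overall_rank")
  expect_true(all(diff(overall) >= 0))
  # a module dominating on both criteria is overall rank 1
  best <- which.min(vapply(ranked, `[[`, numeric(1), "p_density"))
  if (best == which.min(vapply(ranked, `[[`, numeric(1), "p_coexpression")))
    expect_equal(ranked[[best]]$overall_rank, min(overall))
})

test_that("ranking is deterministic under a fixed seed and input order", {
  set.seed(99)
  net <- random_instance(12, 0.4, n_conditions = 6)
  mods <- enumerate_dcbs(net, dcb_params(0.5, 2.5, 2), min_size = 2)
  skip_if(length(mods) < 2, "instance produced too few modules")
  r1 <- rank_modules(mods, net, epsilon = 2.5, n_samples = 60, seed = 11)
  r2 <- rank_modules(mods, net, epsilon = 2.5, n_samples = 60, seed = 11)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r3 <- rank_modules(mods[sample(length(mods))], net, epsilon = 2.5,
                     n_samples = 60, seed = 11)
  expect_identical(as.data.frame(r1), as.data.frame(r3))
})

test_that("the redundancy filter drops covered modules only", {
  ranked <- structure(list(
    bare_module(c("A", "B", "C")),
    bare_module(c("A", "B")),
    bare_module(c("C", "D"))), class = "dcb_module_set")
  kept <- filter_ranked(ranked)
  expect_identical(lapply(kept, `[[`, "genes"),
                   list(c("A", "B", "C"), c("C", "D")))
  # all-disjoint lists pass through; duplicates of kept modules drop
  disjoint <- structure(list(bare_module(c("A", "B")),
                             bare_module(c("X", "Y"))),
                        class = "dcb_module_set")
  expect_length(filter_ranked(disjoint), 2)
  dup <- structure(list(bare_module(c("A", "B")), bare_module(c("A", "B"))),
                   class = "dcb_module_set")
  expect_length(filter_ranked(dup), 1)
  # top-N stop
  expect_length(filter_ranked(disjoint, top_n = 1), 1)
  # kept modules are never covered by the union of those above them
  set.seed(121)
  mods <- lapply(1:12, function(i)
    bare_module(sample(LETTERS[1:10], sample(2:4, 1))))
  kept <- filter_ranked(structure(mods, class = "dcb_module_set"))
  for (i in seq_along(kept)) {
    above <- unique(unlist(lapply(kept[seq_len(i - 1)], `[[`, "genes")))
    expect_false(all(kept[[i]]$genes %in% above))
  }
})
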