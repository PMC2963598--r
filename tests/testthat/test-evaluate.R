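test_that("term levels are shortest directed paths from a root", {
  expect_identical(term_levels(cbind("t1", "root")),
                   c(root = 0L, t1 = 1L))
  chain <- rbind(c("t1", "root"), c("t2", "t1"))
  expect_identical(term_levels(chain)[["t2"]], 2L)
  # two routes of different length: the shorter wins
  dag <- rbind(c("a", "root"), c("b", "a"), c("t", "b"),   # length 3
               c("x", "root"), c("t", "x"))                # length 2
  expect_identical(term_levels(dag)[["t"]], 2L)
  # several roots: minimum over roots
  dag2 <- rbind(c("t", "r1"), c("m", "r2"), c("t", "m"))
  expect_identical(term_levels(dag2)[["t"]], 1L)
  expect_error(term_levels(rbind(c("a", "b"), c("b", "a"))), "cycle")
  expect_error(term_levels(rbind(c("a", "root"), c("b", "c"), c("c", "b"))),
               "cycle")
})

test_that("module enrichment is the one-sided hypergeometric tail", {
  fx <- worked_enrichment()
  enr <- enrich_modules(fx$mods, fx$ann, fx$background)
  expect_equal(nrow(enr), 1)
  expect_equal(enr$p, 22 / 120)    # P(X >= 2), 3 of 10 carry T, draw 3
  expect_equal(enr$level, 8L)

  # all background genes carry the term -> p = 1
  ann_all <- make_annotations(setNames(as.list(rep("T", 10)),
                                       sprintf("g%d", 1:10)),
                              levels = c(T = 8L))
  enr_all <- enrich_modules(fx$mods, ann_all, fx$background)
  expect_equal(enr_all$p, 1)

  # module = background -> p = 1 for every term
  mods_all <- module_set(list(bare_module(sprintf("g%d", 1:10))))
  enr_bg <- enrich_modules(mods_all, ann_all, fx$background)
  expect_true(all(enr_bg$p == 1))

  expect_error(enrich_modules(fx$mods, fx$ann, background = "g1"),
               "not in background")
})

test_that("raw enrichment p-values match the combinatorial oracle", {
  set.seed(606)
  background <- sprintf("g%d", 1:10)
  for (rep in 1:15) {
    terms <- c("T1", "T2", "T3")
    gt <- lapply(setNames(nm = sample(background, 7)), function(g)
      sample(terms, sample(1:2, 1)))
    ann <- make_annotations(gt, levels = c(T1 = 2L, T2 = 8L, T3 = 9L))
    mods <- module_set(list(bare_module(sample(background, 4)),
                            bare_module(sample(background, 3))))
    enr <- enrich_modules(mods, ann, background)
    mod_sets <- lapply(unclass(mods), `[[`, "genes")
    for (r in seq_len(nrow(enr))) {
      with_term <- names(gt)[vapply(gt, function(tt)
        enr$term[r] %in% tt, logical(1))]
      expect_equal(enr$p[r],
                   hyper_upper_oracle(10, length(with_term),
                                      length(mod_sets[[enr$module[r]]]),
                                      enr$overlap[r]),
                   tolerance = 1e-12)
    }
    expect_true(all(enr$p_adj >= enr$p))
  }
})

test_that("enrichment ratio counts modules with deep enriched terms", {
  background <- sprintf("g%d", 1:12)
  ann <- make_annotations(
    list(g1 = "deep", g2 = "deep", g3 = "deep",
         g4 = "shallow", g5 = "shallow", g6 = "shallow"),
    levels = c(deep = 8L, shallow = 2L))
  mods <- module_set(list(bare_module(c("g1", "g2", "g3")),
                          bare_module(c("g7", "g8", "g9"))))
  er <- enrichment_ratio(mods, ann, p_threshold = 0.05, deep_level = 7,
                         background = background)
  expect_equal(er, 50)           # only the deep-term module qualifies
  # deep_level 0 counts any enriched term, a superset of the default
  er0 <- enrichment_ratio(mods, ann, p_threshold = 0.05, deep_level = 0,
                          background = background)
  expect_gte(er0, er)
  expect_equal(enrichment_ratio(mods, make_annotations(list(), integer(0)),
                                background = background), 0)
})

test_that("coverage is the enriched fraction of dataset terms", {
  background <- sprintf("g%d", 1:12)
  ann <- make_annotations(
    list(g1 = c("A", "B"), g2 = "A", g3 = "A", g4 = "C", g5 = "D"),
    levels = c(A = 8L, B = 8L, C = 8L, D = 8L))
  mods <- module_set(list(bare_module(c("g1", "g2", "g3"))))
  # term A: 3/3 module genes vs 3/12 background -> strongly enriched;
  # B rides along in the same module but is not significant
  cov <- coverage(mods, ann, p_threshold = 0.05, background = background)
  expect_equal(cov, 25)          # 1 of the 4 dataset terms
  expect_equal(coverage(module_set(), ann, background = background), 0)
})

test_that("coverage and enrichment ratio are monotone in the threshold", {
  set.seed(707)
  background <- sprintf("g%d", 1:14)
  gt <- lapply(setNames(nm = sample(background, 10)), function(g)
    sample(c("T1", "T2", "T3", "T4"), sample(1:3, 1)))
  ann <- make_annotations(gt, levels = c(T1 = 8L, T2 = 8L, T3 = 3L, T4 = 9L))
  mods <- module_set(lapply(1:3, function(i)
    bare_module(sample(background, 4))))
  enr <- enrich_modules(mods, ann, background)
  ths <- c(0.01, 0.05, 0.2, 0.5, 1)
  covs <- vapply(ths, function(t)
    coverage(mods, ann, t, background, enr), numeric(1))
  ers <- vapply(ths, function(t)
    enrichment_ratio(mods, ann, t, 7, background, enr), numeric(1))
  expect_true(all(diff(covs) >= 0))
  expect_true(all(diff(ers) >= 0))
})

test_that("individual coverage averages per-gene enriched-term fractions", {
  # fixture evaluating the printed formula directly: g1 has 2 terms with 1
  # satisfied (0.5), g2 has 1 term satisfied (1.0) -> IC = 75
  mods <- module_set(list(bare_module(c("g1", "g2"))))
  ann <- make_annotations(list(g1 = c("TA", "TB"), g2 = "TA"),
                          levels = c(TA = 8L, TB = 8L))
  enr <- data.frame(module = c(1L, 1L), term = c("TA", "TB"),
                    overlap = c(2L, 1L), p = c(0.001, 0.9),
                    p_adj = c(0.002, 0.9), level = c(8L, 8L))
  expect_equal(individual_coverage(mods, ann, 0.05, enrichment = enr), 75)
  # nothing satisfied -> 0; everything satisfied -> 100
  enr0 <- transform(enr, p_adj = 1)
  expect_equal(individual_coverage(mods, ann, 0.05, enrichment = enr0), 0)
  enr1 <- transform(enr, p_adj = 0.001)
  expect_equal(individual_coverage(mods, ann, 0.05, enrichment = enr1), 100)
})

test_that("IC is 100 for a partition whose genes' terms are all enriched", {
  mods <- module_set(list(bare_module(c("g1", "g2")),
                          bare_module(c("g3", "g4"))))
  ann <- make_annotations(list(g1 = "TA", g2 = "TA", g3 = "TB", g4 = "TB"),
                          levels = c(TA = 8L, TB = 8L))
  enr <- data.frame(module = c(1L, 2L), term = c("TA", "TB"),
                    overlap = 2L, p = 0.001, p_adj = 0.001, level = 8L)
  expect_equal(individual_coverage(mods, ann, 0.05, enrichment = enr), 100)
})

test_that("OMPSDF counts overlapping pairs supporting distinct functions", {
  fx <- ompsdf_fixture()
  expect_identical(
    ompsdf(fx$mods, fx$ann, core_level = 3, deep_level = 7,
           enrichment = fx$enr), 1L)
  # a shared core-level enriched term disqualifies the pair
  fx2 <- ompsdf_fixture(shared_core = TRUE)
  expect_identical(
    ompsdf(fx2$mods, fx2$ann, core_level = 3, deep_level = 7,
           enrichment = fx2$enr), 0L)
  # disjoint modules can never be counted
  disj <- module_set(list(bare_module(c("a", "b", "c")),
                          bare_module(c("x", "y", "z"))))
  expect_identical(ompsdf(disj, fx$ann, enrichment = fx$enr[0, ]), 0L)
})

test_that("partitioned module sets always score OMPSDF zero", {
  set.seed(808)
  background <- sprintf("g%d", 1:20)
  parts <- split(background, rep(1:4, each = 5))
  mods <- module_set(lapply(parts, bare_module))
  gt <- lapply(setNames(nm = background), function(g)
    sample(sprintf("T%d", 1:6), 2))
  ann <- make_annotations(gt, levels = setNames(rep(8L, 6),
                                                sprintf("T%d", 1:6)))
  expect_identical(ompsdf(mods, ann, background = background), 0L)
})

test_that("basic statistics summarize the module set", {
  net <- toy_net(c("A-B", "A-C", "B-C", "D-E", "D-F", "E-F"))
  one <- module_set(list(bare_module(c("A", "B", "C"))))
  expect_equal(basic_stats(one, net),
               list(n_genes = 3L, n_modules = 1L, ams = 3, dy = 1))
  two <- module_set(list(bare_module(c("A", "B", "C")),
                         bare_module(c("D", "E", "F"))))
  expect_equal(basic_stats(two, net)$n_genes, 6L)
  expect_equal(basic_stats(two, net)$dy, 1)
  overlapping <- module_set(list(bare_module(c("A", "B", "C")),
                                 bare_module(c("C", "D", "E"))))
  expect_equal(basic_stats(overlapping)$n_genes, 5L)
  expect_equal(basic_stats(module_set())$n_modules, 0L)
})

test_that("the full assessment report is internally consistent", {
  fx <- worked_enrichment()
  rep <- evaluate_modules(fx$mods, fx$ann, background = fx$background,
                          p_threshold = 0.2)
  expect_s3_class(rep, "dcb_metrics")
  expect_equal(rep$n_modules, 1L)
  expect_true(rep$er >= 0 && rep$er <= 100)
  expect_true(rep$cov >= 0 && rep$cov <= 100)
  expect_true(rep$ic >= 0 && rep$ic <= 100)
  expect_output(print(rep), "OMPSDF")
})
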