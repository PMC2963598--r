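# Fixture builders shared across the test files. Everything is generated in
# code; no data files.

# profile network from an edge list given as "A-B" strings and a profile
# matrix (rows named); genes missing from `profiles` get flat zero profiles
toy_net <- function(edge_strings, profiles = NULL, n_conditions = 5L) {
  edges <- do.call(rbind, strsplit(edge_strings, "-", fixed = TRUE))
  genes <- sort(unique(as.vector(edges)))
  if (is.null(profiles)) {
    profiles <- matrix(0, length(genes), n_conditions,
                       dimnames = list(genes, NULL))
  }
  profile_network(edges, profiles, quiet = TRUE)
}

# random Erdos-Renyi instance with uniform random profiles; guaranteed to
# have at least one edge
random_instance <- function(n, p_edge, n_conditions = 6L,
                            profile_range = c(0, 3)) {
  repeat {
    g <- igraph::sample_gnp(n, p_edge)
    if (igraph::ecount(g) > 0L) break
  }
  el <- igraph::as_edgelist(g)
  genes <- sprintf("g%02d", seq_len(n))
  edges <- cbind(genes[el[, 1L]], genes[el[, 2L]])
  expr <- matrix(stats::runif(n * n_conditions, profile_range[1L],
                              profile_range[2L]),
                 n, n_conditions, dimnames = list(genes, NULL))
  profile_network(edges, expr, quiet = TRUE)
}

# canonical signature of a module set: sorted "genes;subspace" keys, the
# comparison used for oracle-equivalence checks
module_signature <- function(modules) {
  sort(vapply(modules, function(m)
    paste(paste(m$genes, collapse = ","),
          paste(m$subspace, collapse = ","), sep = ";"),
    character(1)))
}

# exact hypergeometric upper-tail by combinatorial summation (independent of
# phyper): P(X >= m) drawing K from N with M successes
hyper_upper_oracle <- function(N, M, K, m) {
  j <- seq(max(m, 0L), min(M, K))
  if (!length(j)) return(0)
  sum(choose(M, j) * choose(N - M, K - j)) / choose(N, K)
}

# small annotation fixture used by the evaluation tests: builds an
# annotation_set from a named list gene -> terms and a named level vector
make_annotations <- function(gene_terms, levels) {
  gt <- cbind(rep(names(gene_terms), lengths(gene_terms)),
              unlist(gene_terms, use.names = FALSE))
  annotation_set(gt, levels = levels)
}

# plain module (no network behind it) for metric tests
bare_module <- function(genes, subspace = 1:3, density = 1,
                        provenance = "enumerated") {
  dcbnet:::new_module(genes, subspace, density, provenance)
}

# worked enrichment fixture: 10-gene background, term T on 3 genes, module
# of 3 genes holding 2 of them (raw p = 22/120)
worked_enrichment <- function() {
  ann <- make_annotations(list(g1 = "T", g2 = "T", g3 = "T"),
                          levels = c(T = 8L))
  mods <- module_set(list(bare_module(c("g1", "g2", "g4"))))
  list(ann = ann, mods = mods, background = sprintf("g%d", 1:10))
}

# constructed OMPSDF fixture: M1 and M2 share gene gS which carries two deep
# terms, one enriched in each module only; optionally a shared core-level
# enriched term that disqualifies the pair
ompsdf_fixture <- function(shared_core = FALSE) {
  mods <- module_set(list(bare_module(c("g1", "g2", "gS")),
                          bare_module(c("gS", "g4", "g5"))),
                     sort = FALSE)
  ann <- make_annotations(
    list(gS = c("D1", "D2", "CORE"), g1 = c("D1", "CORE"),
         g2 = c("D1", "CORE"), g4 = c("D2", "CORE"), g5 = c("D2", "CORE")),
    levels = c(D1 = 8L, D2 = 9L, CORE = 2L))
  enr <- data.frame(
    module = c(1L, 2L, if (shared_core) c(1L, 2L)),
    term = c("D1", "D2", if (shared_core) c("CORE", "CORE")),
    overlap = 2L, p = 0.001, p_adj = 0.001,
    level = c(8L, 9L, if (shared_core) c(2L, 2L)))
  list(mods = mods, ann = ann, enr = enr)
}
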