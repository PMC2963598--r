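#' Specification of a planted-module benchmark instance
#'
#' Describes a random background network (Erdos-Renyi, or a degree-preserving
#' configuration model rewiring of it) with planted connected, dense,
#' co-expressed gene sets: each plant's genes induce a connected subgraph
#' with `ceiling(density * choose(size, 2))` edges and agree to within
#' `band_width` on `subspace_size` randomly chosen conditions.
#'
#' Expression model: on its planted conditions, a plant member's value is
#' the plant's per-condition center plus uniform jitter in
#' `[-band_width/2, band_width/2]` (so the spread constraint holds exactly)
#' plus Gaussian noise with sd `noise_sd`; raising `noise_sd` progressively
#' destroys the planted co-expression. All other cells are independent
#' draws from `N(0, background_sd)`, emulating unstructured log fold-change
#' scatter, except that on a plant's conditions non-member values are kept
#' at distance greater than `1.5 * band_width` from the plant's center
#' (a chance draw inside the band would co-express with the plant and make
#' the planted membership ill-defined). Missing values are masked at rate
#' `missing_rate` outside the planted cells.
#'
#' @param n_genes number of genes in the background (default 100).
#' @param edge_p background edge probability (default 0.05).
#' @param n_conditions number of expression conditions (default 10).
#' @param plants list of plant descriptions, each a list with `size`,
#'   `density` (in `[0, 1]`, must admit a connected wiring:
#'   `ceiling(density * choose(size, 2)) >= size - 1`), `subspace_size`,
#'   and optionally `overlap_with` (index of an earlier plant) and
#'   `overlap_genes` (how many genes to share with it).
#' @param band_width maximum within-plant spread on planted conditions
#'   (the generator's homogeneity guarantee; default 0.5).
#' @param noise_sd sd of Gaussian noise added to planted cells (default 0).
#' @param missing_rate missing-value rate outside planted cells (default 0).
#' @param background_sd sd of the unstructured background expression
#'   (default 2, a realistic log2 fold-change spread).
#' @param degree_preserving rewire the background with a degree-preserving
#'   configuration model instead of plain Erdos-Renyi.
#' @param seed optional integer seed stored in the spec and used by
#'   [generate_planted()].
#' @return An object of class `plant_spec`.
#' @export
plant_spec <- function(n_genes = 100L, edge_p = 0.05, n_conditions = 10L,
                       plants = list(), band_width = 0.5, noise_sd = 0,
                       missing_rate = 0, background_sd = 2,
                       degree_preserving = FALSE, seed = NULL) {
  stopifnot(n_genes >= 2, edge_p >= 0, edge_p <= 1, n_conditions >= 1,
            band_width >= 0, noise_sd >= 0, missing_rate >= 0,
            missing_rate <= 1, background_sd >= 0)
  for (i in seq_along(plants)) {
    p <- plants[[i]]
    if (is.null(p$size) || is.null(p$density) || is.null(p$subspace_size))
      stop("plant ", i, ": needs size, density and subspace_size",
           call. = FALSE)
    target <- ceiling(p$density * choose(p$size, 2))
    if (target < p$size - 1L)
      stop("plant ", i, ": density ", p$density, " cannot keep ", p$size,
           " genes connected (needs at least a spanning tree)", call. = FALSE)
    if (p$subspace_size > n_conditions)
      stop("plant ", i, ": subspace larger than the number of conditions",
           call. = FALSE)
    if (!is.null(p$overlap_with) &&
        (p$overlap_with >= i || p$overlap_with < 1))
      stop("plant ", i, ": overlap_with must name an earlier plant",
           call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes), edge_p = edge_p,
                 n_conditions = as.integer(n_conditions), plants = plants,
                 band_width = band_width, noise_sd = noise_sd,
                 missing_rate = missing_rate, background_sd = background_sd,
                 degree_preserving = degree_preserving, seed = seed),
            class = "plant_spec")
}

#' Generate a planted-module benchmark instance
#'
#' Realizes a [plant_spec]: samples the background graph, wires each plant
#' as a random connected subgraph at its target density (random spanning
#' tree plus random extra edges), fills in the expression matrix, masks
#' missing values, and returns the [profile_network] together with the
#' ground truth.
#'
#' @param spec a [plant_spec].
#' @param seed overrides `spec$seed`.
#' @return A list with `network` (a [profile_network]), `truth` (list of
#'   plants, each with `genes` and `subspace`), `edges` and `expr` (the raw
#'   inputs, convenient for writing to disk).
#' @export
generate_planted <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "plant_spec"))
  if (is.null(seed)) seed <- spec$seed
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_genes
  genes <- sprintf("g%0*d", nchar(n), seq_len(n))

  g <- igraph::sample_gnp(n, spec$edge_p)
  if (spec$degree_preserving && igraph::ecount(g) > 1L)
    g <- igraph::rewire(g, igraph::keeping_degseq(niter = 10L * igraph::ecount(g)))
  edge_mat <- igraph::as_edgelist(g)

  # assign plant gene indices (fresh genes from the front of the id list)
  used <- 0L
  plant_idx <- list()
  for (i in seq_along(spec$plants)) {
    p <- spec$plants[[i]]
    shared <- integer(0)
    if (!is.null(p$overlap_with) && isTRUE(p$overlap_genes > 0)) {
      pool <- plant_idx[[p$overlap_with]]
      shared <- pool[seq_len(min(p$overlap_genes, length(pool)))]
    }
    fresh_n <- p$size - length(shared)
    if (used + fresh_n > n)
      stop("not enough genes for all plants", call. = FALSE)
    fresh <- used + seq_len(fresh_n)
    used <- used + fresh_n
    plant_idx[[i]] <- sort(c(shared, fresh))
  }

  # wire each plant: random spanning tree, then extra random pairs
  plant_edges <- list()
  for (i in seq_along(spec$plants)) {
    p <- spec$plants[[i]]
    idx <- plant_idx[[i]]
    k <- length(idx)
    target <- ceiling(p$density * choose(k, 2))
    perm <- sample(idx)
    tree <- cbind(perm[-1L],
                  vapply(seq(2L, k), function(j)
                    perm[sample.int(j - 1L, 1L)], numeric(1)))
    pairs <- t(utils::combn(idx, 2L))
    keys <- paste(pmin(pairs[, 1], pairs[, 2]),
                  pmax(pairs[, 1], pairs[, 2]))
    tree_keys <- paste(pmin(tree[, 1], tree[, 2]),
                       pmax(tree[, 1], tree[, 2]))
    extra_pool <- which(!(keys %in% tree_keys))
    n_extra <- target - (k - 1L)
    extra <- if (n_extra > 0L) sample(extra_pool, n_extra) else integer(0)
    plant_edges[[i]] <- rbind(tree, pairs[extra, , drop = FALSE])
  }

  all_edges <- rbind(edge_mat, do.call(rbind, plant_edges))
  edges <- cbind(genes[pmin(all_edges[, 1], all_edges[, 2])],
                 genes[pmax(all_edges[, 1], all_edges[, 2])])
  edges <- edges[!duplicated(edges), , drop = FALSE]

  expr <- matrix(stats::rnorm(n * spec$n_conditions, 0, spec$background_sd),
                 n, spec$n_conditions,
                 dimnames = list(genes,
                                 paste0("c", seq_len(spec$n_conditions))))
  planted_cell <- matrix(FALSE, n, spec$n_conditions)
  truth <- list()
  for (i in seq_along(spec$plants)) {
    p <- spec$plants[[i]]
    idx <- plant_idx[[i]]
    subspace <- sort(sample.int(spec$n_conditions, p$subspace_size))
    centers <- stats::runif(length(subspace), -4, 4)
    for (ci in seq_along(subspace)) {
      d <- subspace[ci]
      expr[idx, d] <- centers[ci] +
        stats::runif(length(idx), -spec$band_width / 2, spec$band_width / 2) +
        stats::rnorm(length(idx), 0, spec$noise_sd)
      planted_cell[idx, d] <- TRUE
    }
    truth[[i]] <- list(genes = genes[idx], subspace = subspace,
                       centers = centers, size = p$size, density = p$density)
  }
  # keep non-members out of every plant's expression band on its planted
  # conditions: a value within 1.5 * band_width of the center could sit
  # within band_width of a member, which would blur the ground truth and
  # make exact membership ill-defined
  guard <- 1.5 * spec$band_width
  for (i in seq_along(truth)) {
    for (ci in seq_along(truth[[i]]$subspace)) {
      d <- truth[[i]]$subspace[ci]
      ctr <- truth[[i]]$centers[ci]
      outside <- which(!planted_cell[, d])
      for (iter in 1:50) {
        clash <- outside[abs(expr[outside, d] - ctr) <= guard]
        if (!length(clash)) break
        expr[clash, d] <- stats::rnorm(length(clash), 0, spec$background_sd)
      }
      clash <- outside[abs(expr[outside, d] - ctr) <= guard]
      if (length(clash))   # degenerate background (sd ~ 0): place explicitly
        expr[clash, d] <- ctr + sample(c(-1, 1), length(clash),
                                       replace = TRUE) * (guard + 1)
    }
  }
  if (spec$missing_rate > 0) {
    mask <- matrix(stats::runif(n * spec$n_conditions) < spec$missing_rate,
                   n, spec$n_conditions) & !planted_cell
    expr[mask] <- NA_real_
  }

  net <- profile_network(edges, expr, quiet = TRUE)
  list(network = net, truth = truth, edges = edges, expr = expr)
}

#' Score recovery of planted modules
#'
#' For each planted gene set, the best Jaccard index over the found
#' modules' gene sets; a plant is exactly recovered at Jaccard 1.
#'
#' @param found a [module_set] (or list of modules).
#' @param truth the `truth` component of [generate_planted()].
#' @return A list with `jaccard` (numeric, one value per plant) and
#'   `n_exact` (number of plants at Jaccard 1).
#' @export
score_recovery <- function(found, truth) {
  found_sets <- lapply(found, `[[`, "genes")
  jac <- vapply(truth, function(p) {
    if (!length(found_sets)) return(0)
    max(vapply(found_sets, function(s)
      length(intersect(s, p$genes)) / length(union(s, p$genes)),
      numeric(1)))
  }, numeric(1))
  list(jaccard = jac, n_exact = sum(jac == 1))
}
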