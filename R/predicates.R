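# Internal index-based predicate kernels. These operate on a precomputed
# logical adjacency matrix and the expression matrix so that the lattice
# traversal and the brute-force oracle avoid per-candidate graph object
# construction.

dcb_density_idx <- function(adj, idx) {
  k <- length(idx)
  if (k == 1L) return(1.0)
  sum(adj[idx, idx]) / (k * (k - 1L))   # sum counts both triangle halves
}

dcb_connected_idx <- function(adj, idx) {
  k <- length(idx)
  if (k == 1L) return(TRUE)
  sub <- adj[idx, idx, drop = FALSE]
  seen <- logical(k)
  seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nb <- which(colSums(sub[frontier, , drop = FALSE]) > 0L & !seen)
    seen[nb] <- TRUE
    frontier <- nb
  }
  all(seen)
}

dcb_subspace_idx <- function(expr, idx, epsilon) {
  vals <- expr[idx, , drop = FALSE]
  cmx <- vals[1L, ]
  cmn <- cmx
  for (r in seq_len(nrow(vals))[-1L]) {
    cmx <- pmax(cmx, vals[r, ])   # NA propagates: any missing value
    cmn <- pmin(cmn, vals[r, ])   # disqualifies the condition
  }
  spread <- unname(cmx - cmn)
  which(!is.na(spread) & spread <= epsilon)
}

dcb_test_idx <- function(adj, expr, idx, gamma, epsilon, d_min) {
  if (!dcb_connected_idx(adj, idx))
    return(list(ok = FALSE, subspace = integer(0)))
  if (dcb_density_idx(adj, idx) < gamma)
    return(list(ok = FALSE, subspace = integer(0)))
  sub <- dcb_subspace_idx(expr, idx, epsilon)
  list(ok = length(sub) >= d_min, subspace = sub)
}

#' Density of an induced subgraph
#'
#' The fraction of possible edges, `choose(k, 2)` for `k` genes, that are
#' present in the subgraph induced by `genes`. A singleton has density 1 by
#' convention (it never forms a reported module; the convention only avoids a
#' 0/0 in internal calls).
#'
#' @param net a [profile_network].
#' @param genes character vector of gene identifiers, a subset of
#'   `net$genes`.
#' @return A single number in `[0, 1]`.
#' @export
subgraph_density <- function(net, genes) {
  idx <- pn_index(net, genes)
  k <- length(idx)
  if (k == 1L) return(1.0)
  m <- igraph::ecount(igraph::induced_subgraph(net$graph, idx))
  m / choose(k, 2)
}

#' Connectivity of an induced subgraph
#'
#' @inheritParams subgraph_density
#' @return `TRUE` iff the subgraph of `net` induced by `genes` is connected
#'   (a singleton counts as connected).
#' @export
subgraph_connected <- function(net, genes) {
  idx <- pn_index(net, genes)
  if (length(idx) == 1L) return(TRUE)
  igraph::is_connected(igraph::induced_subgraph(net$graph, idx))
}

#' Co-expression subspace of a gene set
#'
#' The set of conditions in which all the given genes are mutually
#' co-expressed: every gene has a non-missing value and the spread
#' (max minus min, equivalently the largest pairwise difference) is at most
#' `epsilon`. A condition with a missing value for any member gene is
#' excluded: co-expression there cannot be witnessed.
#'
#' @inheritParams subgraph_density
#' @param epsilon homogeneity threshold (`>= 0`).
#' @return Integer vector of condition indices (1-based, ascending).
#' @examples
#' expr <- rbind(A = c(1.0, 2.0, 5.0), B = c(1.2, 3.5, 5.1))
#' net <- profile_network(cbind("A", "B"), expr, quiet = TRUE)
#' coexpression_subspace(net, c("A", "B"), epsilon = 0.5)  # conditions 1, 3
#' @export
coexpression_subspace <- function(net, genes, epsilon) {
  idx <- pn_index(net, genes)
  dcb_subspace_idx(net$expr, idx, epsilon)
}

#' Test a gene set against the densely-connected-bicluster constraints
#'
#' A gene set is a densely connected bicluster (DCB) when its induced
#' subgraph is connected, its density is at least `gamma`, and its
#' co-expression subspace holds at least `d_min` conditions.
#'
#' @inheritParams subgraph_density
#' @param params a [dcb_params] object.
#' @return A list with `ok` (logical) and `subspace` (the full witnessing
#'   condition set when `ok`, otherwise empty).
#' @export
is_dcb <- function(net, genes, params) {
  stopifnot(inherits(params, "dcb_params"))
  idx <- pn_index(net, genes)
  if (length(idx) < 2L)
    stop("a densely connected bicluster needs at least 2 genes", call. = FALSE)
  adj <- pn_adjacency(net)
  dcb_test_idx(adj, net$expr, idx, params$gamma, params$epsilon, params$d_min)
}
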