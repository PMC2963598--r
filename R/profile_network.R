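#' Build a profile network
#'
#' A profile network couples an undirected gene interaction graph (e.g. a
#' BioGRID-style PPI/GI edge list) with a per-gene expression profile over a
#' shared, ordered list of conditions (log fold-changes; missing values
#' allowed). It is the input object for all module discovery functions.
#'
#' Self-loops and duplicate edges are dropped. Genes present in only one of
#' the two inputs cannot take part in any densely connected bicluster and are
#' dropped, with a message reporting how many came from each side. Matching of
#' gene identifiers is exact and case-sensitive.
#'
#' @param edges two-column character matrix or data frame of undirected
#'   interactions (one row per edge).
#' @param expr numeric matrix of expression values, genes in rows (rownames
#'   are gene identifiers), conditions in columns; `NA` marks missing values.
#' @param quiet suppress the messages about dropped edges/genes.
#' @return An object of class `profile_network` with components `graph`
#'   (a named [igraph][igraph::graph_from_edgelist] graph), `genes`, `expr`
#'   (rows restricted and ordered to `genes`) and `conditions`.
#' @examples
#' edges <- cbind(c("A", "A", "B"), c("B", "C", "C"))
#' expr <- matrix(rnorm(9), 3, 3, dimnames = list(c("A", "B", "C"), NULL))
#' net <- profile_network(edges, expr)
#' @export
profile_network <- function(edges, expr, quiet = FALSE) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L)
    stop("`edges` must have exactly two columns", call. = FALSE)
  storage.mode(edges) <- "character"
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("`expr` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(expr)))
    stop("`expr` must have gene identifiers as rownames", call. = FALSE)
  if (anyDuplicated(rownames(expr)))
    stop("duplicate gene rows in `expr`: ",
         paste(unique(rownames(expr)[duplicated(rownames(expr))]), collapse = ", "),
         call. = FALSE)
  if (is.null(colnames(expr)))
    colnames(expr) <- paste0("c", seq_len(ncol(expr)))

  self <- edges[, 1L] == edges[, 2L]
  if (any(self) && !quiet)
    message(sum(self), " self-loop(s) dropped")
  edges <- edges[!self, , drop = FALSE]
  # canonical orientation, then dedup
  flip <- edges[, 1L] > edges[, 2L]
  edges[flip, ] <- edges[flip, 2:1]
  dup <- duplicated(edges)
  if (any(dup) && !quiet)
    message(sum(dup), " duplicate edge(s) dropped")
  edges <- edges[!dup, , drop = FALSE]

  net_genes <- sort(unique(as.vector(edges)))
  expr_genes <- rownames(expr)
  genes <- intersect(net_genes, expr_genes)
  only_net <- setdiff(net_genes, genes)
  only_expr <- setdiff(expr_genes, genes)
  if ((length(only_net) || length(only_expr)) && !quiet)
    message("dropped ", length(only_net), " gene(s) without expression and ",
            length(only_expr), " gene(s) absent from the network")
  keep <- edges[, 1L] %in% genes & edges[, 2L] %in% genes
  edges <- edges[keep, , drop = FALSE]
  genes <- sort(unique(as.vector(edges)))
  if (length(genes) == 0L)
    stop("no genes shared between network and expression matrix", call. = FALSE)

  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::permute(g, match(igraph::V(g)$name, sort(igraph::V(g)$name)))
  structure(
    list(graph = g,
         genes = igraph::V(g)$name,
         expr = expr[igraph::V(g)$name, , drop = FALSE],
         conditions = colnames(expr)),
    class = "profile_network")
}

#' @export
print.profile_network <- function(x, ...) {
  cat("profile_network: ", length(x$genes), " genes, ",
      igraph::ecount(x$graph), " interactions, ",
      length(x$conditions), " conditions (",
      format(100 * mean(is.na(x$expr)), digits = 3), "% missing)\n", sep = "")
  invisible(x)
}

# map gene ids to row indices, failing loudly on unknown ids
pn_index <- function(net, genes) {
  idx <- match(genes, net$genes)
  if (anyNA(idx))
    stop("unknown gene identifier(s): ",
         paste(genes[is.na(idx)], collapse = ", "), call. = FALSE)
  idx
}

# dense logical adjacency matrix; small networks only, used by the
# enumeration hot paths
pn_adjacency <- function(net) {
  a <- as.matrix(igraph::as_adjacency_matrix(net$graph, type = "both"))
  storage.mode(a) <- "logical"
  a
}

#' Constraint parameters for densely connected biclusters
#'
#' Bundles the three constraint thresholds of the module definition: the
#' density threshold `gamma` (fraction of possible edges that must be present
#' in the induced subgraph), the homogeneity threshold `epsilon` (maximum
#' spread, in expression units, allowed between member genes in a condition
#' for it to count as co-expressed) and `d_min`, the minimum number of
#' co-expressed conditions.
#'
#' @param gamma density threshold in `[0, 1]`.
#' @param epsilon homogeneity threshold, `>= 0`, same units as the expression
#'   values (typically log2 fold-change).
#' @param d_min minimum number of co-expressed conditions, a positive integer.
#' @return An object of class `dcb_params`.
#' @examples
#' dcb_params(gamma = 0.5, epsilon = 1, d_min = 3)
#' @export
dcb_params <- function(gamma = 0.5, epsilon = 1, d_min = 3L) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0 || gamma > 1)
    stop("`gamma` must be a single value in [0, 1]", call. = FALSE)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0)
    stop("`epsilon` must be a single non-negative value", call. = FALSE)
  if (!is.numeric(d_min) || length(d_min) != 1L || d_min < 1 ||
      d_min != round(d_min))
    stop("`d_min` must be a positive integer", call. = FALSE)
  structure(list(gamma = gamma, epsilon = epsilon, d_min = as.integer(d_min)),
            class = "dcb_params")
}

#' @export
print.dcb_params <- function(x, ...) {
  cat("dcb_params: gamma = ", x$gamma, ", epsilon = ", x$epsilon,
      ", d_min = ", x$d_min, "\n", sep = "")
  invisible(x)
}
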