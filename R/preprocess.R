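#' Variance-interval gene filter
#'
#' Retains the genes whose profile escapes an interval of `k` standard
#' deviations around the gene's own mean in at least one condition, i.e.
#' genes that somewhere exhibit expression beyond their usual scatter.
#' Typical use: reducing a large compendium (e.g. a yeast log fold-change
#' matrix) to differentially expressed genes before module discovery.
#'
#' The interval is `mean +/- k * sd`, with the sample (n-1) standard
#' deviation over the gene's non-missing values, and the escape is strict
#' (`>`). A constant profile (sd 0) never escapes and is discarded. Genes
#' with fewer than two non-missing values are excluded with a warning.
#'
#' @param expr numeric expression matrix, genes in rows.
#' @param k interval half-width in standard deviations (default 1.5).
#' @return Character vector of retained gene identifiers.
#' @export
variance_filter <- function(expr, k = 1.5) {
  stopifnot(is.matrix(expr), is.numeric(expr), k > 0)
  n_ok <- rowSums(!is.na(expr))
  short <- n_ok < 2L
  if (any(short))
    warning(sum(short), " gene(s) with fewer than 2 non-missing values excluded",
            call. = FALSE)
  mu <- rowMeans(expr, na.rm = TRUE)
  sdv <- apply(expr, 1L, stats::sd, na.rm = TRUE)
  escapes <- abs(expr - mu) > k * sdv
  keep <- !short & rowSums(escapes, na.rm = TRUE) > 0L
  rownames(expr)[keep]
}

#' Fold-change gene filter
#'
#' Retains genes showing at least `min_dev` absolute deviation (in log2
#' units; the default 1.0 corresponds to a 2-fold ratio change) from the
#' gene's mean in at least `min_samples` conditions. Typical use: keeping
#' variably expressed genes of a human tissue fold-change matrix.
#'
#' The comparison is inclusive (`>=`, "at least 2-fold"); means are over
#' non-missing values. Genes with fewer than two non-missing values are
#' excluded with a warning.
#'
#' @inheritParams variance_filter
#' @param min_dev minimum absolute deviation from the gene mean, log2 units
#'   (default 1.0, i.e. 2-fold).
#' @param min_samples minimum number of conditions showing the deviation
#'   (default 2).
#' @return Character vector of retained gene identifiers.
#' @export
fold_filter <- function(expr, min_dev = 1.0, min_samples = 2L) {
  stopifnot(is.matrix(expr), is.numeric(expr), min_dev > 0, min_samples >= 1)
  n_ok <- rowSums(!is.na(expr))
  short <- n_ok < 2L
  if (any(short))
    warning(sum(short), " gene(s) with fewer than 2 non-missing values excluded",
            call. = FALSE)
  mu <- rowMeans(expr, na.rm = TRUE)
  hits <- rowSums(abs(expr - mu) >= min_dev, na.rm = TRUE)
  rownames(expr)[!short & hits >= min_samples]
}

#' Prune edges that cannot lie inside any module
#'
#' Removes every edge whose two endpoint genes are co-expressed in fewer
#' than `d_min` conditions, then removes genes left without edges. The
#' pruning is sound: the co-expression subspace is anti-monotone (a
#' superset's subspace is contained in every pair's subspace), so a failing
#' pair can never be part of a densely connected bicluster, and the set of
#' maximal DCBs is unchanged.
#'
#' @param net a [profile_network].
#' @param params a [dcb_params] (uses `epsilon` and `d_min`).
#' @param quiet suppress the removal message.
#' @return A pruned [profile_network].
#' @export
prune_edges <- function(net, params, quiet = FALSE) {
  stopifnot(inherits(net, "profile_network"), inherits(params, "dcb_params"))
  el <- igraph::as_edgelist(net$graph)
  drop <- logical(nrow(el))
  for (r in seq_len(nrow(el))) {
    idx <- pn_index(net, el[r, ])
    drop[r] <- length(dcb_subspace_idx(net$expr, idx, params$epsilon)) <
      params$d_min
  }
  g <- igraph::delete_edges(net$graph, which(drop))
  iso <- which(igraph::degree(g) == 0L)
  g <- igraph::delete_vertices(g, iso)
  if (!quiet)
    message(sum(drop), " edge(s) pruned, ", length(iso),
            " isolated gene(s) removed")
  if (igraph::vcount(g) == 0L) {
    out <- net
    out$graph <- g
    out$genes <- character(0)
    out$expr <- net$expr[character(0), , drop = FALSE]
    return(out)
  }
  out <- net
  out$graph <- g
  out$genes <- igraph::V(g)$name
  out$expr <- net$expr[out$genes, , drop = FALSE]
  out
}
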