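#' Enumerate all maximal densely connected biclusters
#'
#' Exhaustive breadth-first traversal of the subnetwork lattice. Level 2
#' holds every edge whose endpoint pair is co-expressed in at least `d_min`
#' conditions (an edge is trivially connected and has density 1); level
#' `k + 1` candidates are generated by extending each size-`k` DCB with one
#' neighboring gene, deduplicated, and tested against the full constraint.
#' Completeness rests on loose anti-monotonicity: for `gamma >= 0.5` every
#' DCB of size `k + 1` contains at least one DCB of size `k`, so no
#' satisfying set is ever missed by growing only from satisfying parents.
#' A final pass drops every DCB whose gene set is a strict subset of another
#' enumerated DCB's gene set, leaving exactly the maximal ones.
#'
#' For `gamma < 0.5` loose anti-monotonicity fails and the traversal would be
#' incomplete; the function refuses and points to [brute_force_dcbs()].
#'
#' @param net a [profile_network].
#' @param params a [dcb_params]; `params$gamma` must be at least 0.5.
#' @param min_size smallest module size to report (default 3; a bare edge is
#'   rarely an interesting module). Size-2 DCBs still seed the traversal.
#' @param max_size optional safety cap on module size. Hitting it is
#'   reported with a warning because it voids the completeness guarantee.
#' @return A [module_set] of the maximal DCBs with `min_size` or more genes,
#'   each carrying its full witnessing condition subspace and recomputed
#'   density.
#' @seealso [brute_force_dcbs()] for the verification oracle,
#'   [merge_modules()] for the core-attachment refinement,
#'   [prune_edges()] for the (sound) standalone edge pruning, which level 2
#'   of this traversal applies implicitly.
#' @export
enumerate_dcbs <- function(net, params, min_size = 3L, max_size = Inf) {
  stopifnot(inherits(net, "profile_network"), inherits(params, "dcb_params"))
  if (params$gamma < 0.5)
    stop("the lattice traversal is only exhaustive for gamma >= 0.5 ",
         "(loose anti-monotonicity fails below); use brute_force_dcbs()",
         call. = FALSE)
  if (min_size < 2L) stop("`min_size` must be at least 2", call. = FALSE)

  adj <- pn_adjacency(net)
  expr <- net$expr
  n <- length(net$genes)

  # level 2: surviving edges (pair subspace >= d_min); this *is* the
  # co-expression edge pruning, applied on the fly
  ut <- which(adj & upper.tri(adj), arr.ind = TRUE)
  level <- list()
  for (r in seq_len(nrow(ut))) {
    pair <- sort(as.integer(ut[r, ]))
    sub <- dcb_subspace_idx(expr, pair, params$epsilon)
    if (length(sub) < params$d_min) next
    level <- c(level, list(list(idx = pair, subspace = sub)))
  }

  all_dcbs <- level
  k <- 2L
  capped <- FALSE
  while (length(level) && k < max_size) {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    nxt <- list()
    for (d in level) {
      S <- d$idx
      nb <- which(rowSums(adj[, S, drop = FALSE]) > 0L)
      nb <- setdiff(nb, S)
      for (v in nb) {
        cand <- sort(c(S, v))
        key <- paste(cand, collapse = ".")
        if (!is.null(seen[[key]])) next
        assign(key, TRUE, envir = seen)
        res <- dcb_test_idx(adj, expr, cand, params$gamma, params$epsilon,
                            params$d_min)
        if (res$ok)
          nxt <- c(nxt, list(list(idx = cand, subspace = res$subspace)))
      }
    }
    level <- nxt
    all_dcbs <- c(all_dcbs, level)
    k <- k + 1L
    if (length(level) && k >= max_size) capped <- TRUE
  }
  if (capped)
    warning("size cap max_size = ", max_size, " reached: output may miss ",
            "larger modules and maximality is relative to the cap",
            call. = FALSE)

  finalize_maximal(net, adj, all_dcbs, min_size)
}

#' Brute-force oracle for densely connected biclusters
#'
#' Enumerates every induced subgraph of the network (all gene subsets up to
#' `max_size`), keeps those satisfying the DCB constraints, and applies the
#' same strict-subset maximality filter as [enumerate_dcbs()]. Deliberately
#' naive -- its value is being obviously correct -- so it is capped at small
#' networks. It also serves `gamma < 0.5`, where the lattice traversal's
#' completeness guarantee does not hold.
#'
#' @inheritParams enumerate_dcbs
#' @param max_size largest subset size to test (default: all genes).
#' @param max_genes refuse networks larger than this (default 18; subset
#'   enumeration is exponential).
#' @return A [module_set]; for `gamma >= 0.5` and equal size bounds it equals
#'   the output of [enumerate_dcbs()].
#' @export
brute_force_dcbs <- function(net, params, min_size = 3L, max_size = Inf,
                             max_genes = 18L) {
  stopifnot(inherits(net, "profile_network"), inherits(params, "dcb_params"))
  n <- length(net$genes)
  if (n > max_genes)
    stop("network has ", n, " genes; brute force is capped at ", max_genes,
         call. = FALSE)
  if (min_size < 2L) stop("`min_size` must be at least 2", call. = FALSE)
  adj <- pn_adjacency(net)
  expr <- net$expr
  hi <- min(n, max_size)

  dcbs <- list()
  for (k in seq(2L, hi)) {
    if (k > n) break
    sets <- utils::combn(n, k, simplify = FALSE)
    for (S in sets) {
      res <- dcb_test_idx(adj, expr, S, params$gamma, params$epsilon,
                          params$d_min)
      if (res$ok)
        dcbs <- c(dcbs, list(list(idx = S, subspace = res$subspace)))
    }
  }
  finalize_maximal(net, adj, dcbs, min_size)
}

# shared tail of both enumerators: maximality filter over all collected
# DCBs, then size cut and conversion to named modules
finalize_maximal <- function(net, adj, dcbs, min_size) {
  if (!length(dcbs)) return(module_set())
  keep <- drop_non_maximal(lapply(dcbs, `[[`, "idx"))
  dcbs <- dcbs[keep]
  dcbs <- dcbs[vapply(dcbs, function(d) length(d$idx) >= min_size, logical(1))]
  mods <- lapply(dcbs, function(d) {
    new_module(genes = net$genes[d$idx], subspace = d$subspace,
               density = dcb_density_idx(adj, d$idx),
               provenance = "enumerated")
  })
  module_set(mods)
}
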