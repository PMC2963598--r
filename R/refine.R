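#' Merge overlapping modules into core-attachment modules
#'
#' In biomolecular networks functional subunits often consist of a dense
#' core plus peripherally attached genes, and incomplete interaction maps
#' and noisy expression split such units into overlapping fragments. This
#' refinement iteratively merges pairs of modules that overlap in at least
#' `member_overlap` of their gene sets and at least `subspace_overlap` of
#' their co-expression subspaces, replacing the pair by the gene union with
#' the subspace intersection, until no pair qualifies.
#'
#' Overlap is measured against the smaller set by default (a small module
#' sitting almost wholly inside a larger one should merge); set
#' `overlap = "jaccard"` for the symmetric alternative. Pairs are processed
#' highest member-overlap first, ties broken lexicographically, so the
#' fixpoint is deterministic and independent of input order. Exact-duplicate
#' gene sets are always collapsed.
#'
#' Merging deliberately relaxes the enumeration constraints: a merged
#' module's density may fall below `gamma` and its subspace intersection may
#' fall below `d_min` (reported via a message). Merged modules carry
#' `provenance = "merged"` and, when `net` is supplied, a recomputed density.
#'
#' @param modules a [module_set] (or plain list of modules).
#' @param member_overlap,subspace_overlap overlap thresholds in `(0, 1]`
#'   (defaults 0.75).
#' @param net optional [profile_network] for recomputing merged densities;
#'   without it a merged module's density is `NA`.
#' @param overlap `"min"` (default: intersection over the smaller set) or
#'   `"jaccard"`.
#' @param quiet suppress messages about constraint-relaxing merges.
#' @return A [module_set] at the merge fixpoint.
#' @export
merge_modules <- function(modules, member_overlap = 0.75,
                          subspace_overlap = 0.75, net = NULL,
                          overlap = c("min", "jaccard"), quiet = FALSE) {
  overlap <- match.arg(overlap)
  if (!(member_overlap > 0 && member_overlap <= 1) ||
      !(subspace_overlap > 0 && subspace_overlap <= 1))
    stop("overlap thresholds must be in (0, 1]", call. = FALSE)
  mods <- unclass(module_set(modules))   # canonical order for determinism
  if (length(mods) <= 1L) return(module_set(mods))

  ov <- function(a, b) {
    i <- length(intersect(a, b))
    if (overlap == "min") i / min(length(a), length(b))
    else i / length(union(a, b))
  }

  relaxed <- 0L
  repeat {
    # collapse exact duplicate gene sets (subspaces intersected)
    keys <- vapply(mods, module_key, character(1))
    if (anyDuplicated(keys)) {
      merged <- list()
      for (key in unique(keys)) {
        grp <- mods[keys == key]
        m <- grp[[1L]]
        for (o in grp[-1L]) m$subspace <- intersect(m$subspace, o$subspace)
        merged <- c(merged, list(m))
      }
      mods <- merged
    }
    n <- length(mods)
    if (n <= 1L) break

    best <- NULL
    best_ov <- -1
    best_key <- NULL
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        mo <- ov(mods[[i]]$genes, mods[[j]]$genes)
        if (mo < member_overlap || mo < best_ov) next
        so <- ov(mods[[i]]$subspace, mods[[j]]$subspace)
        if (is.nan(so) || so < subspace_overlap) next
        key <- paste(module_key(mods[[i]]), module_key(mods[[j]]), sep = "\r")
        if (mo > best_ov || (mo == best_ov && key < best_key)) {
          best <- c(i, j)
          best_ov <- mo
          best_key <- key
        }
      }
    }
    if (is.null(best)) break
    m1 <- mods[[best[1L]]]
    m2 <- mods[[best[2L]]]
    genes <- sort(union(m1$genes, m2$genes))
    subspace <- sort(intersect(m1$subspace, m2$subspace))
    dens <- if (!is.null(net)) subgraph_density(net, genes) else NA_real_
    if (length(subspace) < min(length(m1$subspace), length(m2$subspace)))
      relaxed <- relaxed + 1L
    merged <- new_module(genes, subspace, dens, provenance = "merged")
    mods <- c(mods[-best], list(merged))
    mods <- mods[module_order(mods)]
  }
  if (relaxed && !quiet)
    message(relaxed, " merge(s) shrank the co-expression subspace below ",
            "both parents' (constraints relaxed)")
  module_set(mods)
}
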