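# Module container: a dcb_module_set is a list of modules, each a list with
# fields genes (sorted character), subspace (sorted integer condition
# indices), density (numeric), provenance ("enumerated" or "merged") and,
# after ranking, p_coexpression / p_density / rank_coexpression /
# rank_density / overall_rank.

new_module <- function(genes, subspace, density, provenance = "enumerated") {
  list(genes = sort(genes), subspace = sort(as.integer(subspace)),
       density = density, provenance = provenance)
}

module_key <- function(m) paste(m$genes, collapse = "|")

# canonical ordering: size descending, then lexicographic gene list
module_order <- function(modules) {
  sizes <- vapply(modules, function(m) length(m$genes), integer(1))
  keys <- vapply(modules, module_key, character(1))
  order(-sizes, keys, method = "radix")
}

#' Construct a module set
#'
#' @param modules a list of modules as produced by [enumerate_dcbs()],
#'   [merge_modules()] or [read_modules()].
#' @param sort reorder canonically (size descending, then lexicographic gene
#'   list)?
#' @return An object of class `dcb_module_set`.
#' @export
module_set <- function(modules = list(), sort = TRUE) {
  if (sort && length(modules))
    modules <- modules[module_order(modules)]
  structure(modules, class = "dcb_module_set")
}

#' @export
`[.dcb_module_set` <- function(x, i) {
  structure(unclass(x)[i], class = "dcb_module_set")
}

#' @export
print.dcb_module_set <- function(x, n = 10L, ...) {
  cat("dcb_module_set with ", length(x), " module(s)\n", sep = "")
  if (length(x)) {
    df <- as.data.frame(x)
    print(utils::head(df, n))
    if (length(x) > n) cat("... and ", length(x) - n, " more\n", sep = "")
  }
  invisible(x)
}

#' Tabulate a module set
#'
#' @param x a `dcb_module_set`.
#' @param ... unused.
#' @return A data frame with one row per module: size, density, provenance,
#'   subspace width, comma-joined gene list, and ranking columns when
#'   present.
#' @export
as.data.frame.dcb_module_set <- function(x, ...) {
  if (!length(x))
    return(data.frame(size = integer(0), density = numeric(0),
                      provenance = character(0), n_conditions = integer(0),
                      genes = character(0)))
  df <- data.frame(
    size = vapply(x, function(m) length(m$genes), integer(1)),
    density = vapply(x, function(m) m$density, numeric(1)),
    provenance = vapply(x, function(m) m$provenance, character(1)),
    n_conditions = vapply(x, function(m) length(m$subspace), integer(1)),
    genes = vapply(x, function(m) paste(m$genes, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  for (f in c("p_coexpression", "p_density", "rank_coexpression",
              "rank_density", "overall_rank")) {
    if (!is.null(x[[1]][[f]]))
      df[[f]] <- vapply(x, function(m) as.numeric(m[[f]]), numeric(1))
  }
  df
}

# strict-subset maximality filter shared by both enumerators: drop any
# module whose gene set is a strict subset of another's
drop_non_maximal <- function(sets) {
  n <- length(sets)
  if (n <= 1L) return(rep(TRUE, n))
  sizes <- lengths(sets)
  ord <- order(-sizes)
  keep <- rep(TRUE, n)
  for (a in seq_len(n)) {
    i <- ord[a]
    for (b in seq_len(a - 1L)) {
      j <- ord[b]
      if (sizes[j] > sizes[i] && all(sets[[i]] %in% sets[[j]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  keep
}
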