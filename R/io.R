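# File formats: all inputs and outputs are plain tab-separated text.
#   network      two columns of gene ids, one undirected edge per line
#   expression   header row of condition names; first column gene ids;
#                "NA" or empty cells are missing
#   gene->term / child->parent annotation tables: two columns
#   modules      the package's own dialect, see write_modules()

read_two_columns <- function(path, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty ", what, " file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed ", what, " line ", bad[1L], " in ", path,
         " (expected 2 tab-separated fields)", call. = FALSE)
  matrix(unlist(parts), ncol = 2L, byrow = TRUE)
}

#' Read an interaction network edge list
#'
#' Two tab-separated gene identifier columns, one undirected edge per line
#' (the form BioGRID-style exports reduce to). Self-loops are dropped with a
#' message and duplicate edges (in either orientation) are collapsed.
#'
#' @param path file path.
#' @param header does the file start with a header line to skip?
#' @return A two-column character matrix of deduplicated edges.
#' @export
read_network <- function(path, header = FALSE) {
  edges <- read_two_columns(path, "network")
  if (header) {
    if (nrow(edges) == 1L) stop("empty network file: ", path, call. = FALSE)
    edges <- edges[-1L, , drop = FALSE]
  }
  self <- edges[, 1L] == edges[, 2L]
  if (any(self)) message(sum(self), " self-loop(s) dropped")
  edges <- edges[!self, , drop = FALSE]
  flip <- edges[, 1L] > edges[, 2L]
  edges[flip, ] <- edges[flip, 2:1]
  edges <- edges[!duplicated(edges), , drop = FALSE]
  if (!nrow(edges)) stop("network file has no usable edges: ", path,
                         call. = FALSE)
  colnames(edges) <- c("from", "to")
  edges
}

#' Read an expression matrix
#'
#' Tab-separated; the header row names the conditions, the first column
#' holds gene identifiers. `NA` or empty cells are missing values. Duplicate
#' gene rows and non-numeric cells are rejected.
#'
#' @param path file path.
#' @return A numeric matrix, genes in rows.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("expression file needs a header and at least one gene row: ", path,
         call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  conditions <- parts[[1L]][-1L]
  nfield <- length(conditions) + 1L
  body <- parts[-1L]
  bad <- which(lengths(body) != nfield)
  if (length(bad))
    stop("malformed expression line ", bad[1L] + 1L, " in ", path,
         call. = FALSE)
  genes <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(genes))
    stop("duplicate gene row(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  cells <- matrix(unlist(lapply(body, `[`, -1L)), nrow = length(genes),
                  byrow = TRUE)
  missing <- cells == "NA" | cells == ""
  vals <- suppressWarnings(as.numeric(cells))
  bad_cell <- which(is.na(vals) & !missing)
  if (length(bad_cell)) {
    rc <- arrayInd(bad_cell[1L], dim(cells))
    stop("non-numeric cell at gene ", genes[rc[1L]], ", condition ",
         conditions[rc[2L]], ": '", cells[bad_cell[1L]], "'", call. = FALSE)
  }
  vals[missing] <- NA_real_
  matrix(vals, nrow = length(genes),
         dimnames = list(genes, conditions))
}

#' Read a gene-to-term annotation table
#'
#' @param path two-column TSV, gene then term identifier.
#' @return A two-column character matrix (`gene`, `term`).
#' @export
read_gene_terms <- function(path) {
  m <- read_two_columns(path, "annotation")
  colnames(m) <- c("gene", "term")
  m
}

#' Read an ontology child-parent edge table
#'
#' @param path two-column TSV, child term then parent term.
#' @return A two-column character matrix (`child`, `parent`).
#' @export
read_term_dag <- function(path) {
  m <- read_two_columns(path, "term DAG")
  colnames(m) <- c("child", "parent")
  m
}

module_file_columns <- c("module_id", "provenance", "genes", "subspace",
                         "density", "p_coexpression", "p_density",
                         "rank_coexpression", "rank_density", "overall_rank")

#' Write a module set
#'
#' The native module format is a TSV with a header and one record per
#' module: a running id, provenance, comma-joined sorted gene list,
#' comma-joined 1-based condition indices of the witnessing subspace,
#' density, and the five ranking fields (`NA` when the set is unranked).
#' Records are written in canonical order (size descending, then
#' lexicographic gene list), so identical inputs give identical files;
#' numeric fields round-trip exactly through [read_modules()].
#'
#' @param modules a [module_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_modules <- function(modules, path) {
  mods <- unclass(module_set(modules))
  num <- function(x) {
    if (is.null(x) || is.na(x)) "NA" else formatC(x, digits = 17, format = "g")
  }
  rows <- vapply(seq_along(mods), function(i) {
    m <- mods[[i]]
    paste(c(i, m$provenance,
            paste(m$genes, collapse = ","),
            paste(m$subspace, collapse = ","),
            num(m$density), num(m$p_coexpression), num(m$p_density),
            num(m$rank_coexpression), num(m$rank_density),
            num(m$overall_rank)),
          collapse = "\t")
  }, character(1))
  writeLines(c(paste(module_file_columns, collapse = "\t"), rows), path)
  invisible(path)
}

#' Read a module set
#'
#' @param path a file written by [write_modules()].
#' @return A [module_set].
#' @export
read_modules <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines) ||
      !identical(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]],
                 module_file_columns))
    stop("not a module file (bad header): ", path, call. = FALSE)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  mods <- vector("list", length(body))
  for (r in seq_along(body)) {
    f <- strsplit(body[r], "\t", fixed = TRUE)[[1L]]
    if (length(f) != length(module_file_columns))
      stop("malformed module record ", r, " in ", path, call. = FALSE)
    numf <- function(s) if (s == "NA") NULL else as.numeric(s)
    subspace <- if (nzchar(f[4L]))
      as.integer(strsplit(f[4L], ",", fixed = TRUE)[[1L]]) else integer(0)
    m <- new_module(genes = strsplit(f[3L], ",", fixed = TRUE)[[1L]],
                    subspace = subspace,
                    density = if (f[5L] == "NA") NA_real_ else as.numeric(f[5L]),
                    provenance = f[2L])
    for (ci in 6:10) {
      v <- numf(f[ci])
      if (!is.null(v)) m[[module_file_columns[ci]]] <- v
    }
    mods[[r]] <- m
  }
  module_set(mods, sort = FALSE)
}

#' Write a network edge list
#' @param edges two-column character matrix or a [profile_network].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(edges, path) {
  if (inherits(edges, "profile_network"))
    edges <- igraph::as_edgelist(edges$graph)
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an expression matrix
#' @param expr numeric matrix, genes in rows.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a flat key=value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment; values are parsed
#' as numbers where possible. YAML files (`.yaml`/`.yml`) are read with the
#' yaml package when it is installed.
#'
#' @param path file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path) && requireNamespace("yaml", quietly = TRUE))
    return(yaml::read_yaml(path))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad))
    stop("malformed config line ", bad[1L], ": '", lines[bad[1L]], "'",
         call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, character(1), 2L))
  vals <- trimws(vapply(kv, `[[`, character(1), 3L))
  out <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  stats::setNames(out, keys)
}
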