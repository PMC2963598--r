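#' Term levels from ontology child-parent edges
#'
#' The level of a term is the length of the shortest directed path from an
#' ontology root (a term with no parent) to the term, following parent-to-
#' child edges; roots have level 0 and with several roots the minimum
#' applies. Deep terms (large level) are the specific ones.
#'
#' @param dag_edges two-column data frame or matrix of (child, parent) term
#'   pairs.
#' @return Named integer vector of levels for every term in the DAG.
#' @export
term_levels <- function(dag_edges) {
  dag_edges <- as.matrix(dag_edges)
  if (ncol(dag_edges) != 2L)
    stop("`dag_edges` must have two columns (child, parent)", call. = FALSE)
  storage.mode(dag_edges) <- "character"
  terms <- unique(as.vector(dag_edges))
  children <- split(dag_edges[, 1L], dag_edges[, 2L])
  has_parent <- unique(dag_edges[, 1L])
  roots <- setdiff(terms, has_parent)
  if (!length(roots))
    stop("no root term: the child-parent table contains a cycle",
         call. = FALSE)
  level <- stats::setNames(rep(NA_integer_, length(terms)), terms)
  level[roots] <- 0L
  frontier <- roots
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(children[intersect(frontier, names(children))],
                         use.names = FALSE))
    nxt <- nxt[is.na(level[nxt])]
    level[nxt] <- d
    frontier <- nxt
  }
  if (anyNA(level))
    stop("cycle detected: term(s) unreachable from any root: ",
         paste(utils::head(names(level)[is.na(level)], 5L), collapse = ", "),
         call. = FALSE)
  level[order(names(level), method = "radix")]
}

#' Gene annotations with term levels
#'
#' Bundles a gene-to-term mapping with term levels, either supplied directly
#' or derived from a child-parent edge table via [term_levels()]. Terms
#' without a known level get level `NA` and never qualify for level-based
#' criteria.
#'
#' @param gene_terms two-column data frame or matrix of (gene, term) pairs.
#' @param dag_edges optional (child, parent) term table.
#' @param levels optional named integer vector of term levels (ignored when
#'   `dag_edges` is given).
#' @return An object of class `annotation_set` with `gene_terms` (named list
#'   gene -> character vector of terms), `term_level`, `genes`, `terms`.
#' @export
annotation_set <- function(gene_terms, dag_edges = NULL, levels = NULL) {
  if (is.null(gene_terms) || !length(gene_terms))
    gene_terms <- matrix(character(0), 0L, 2L)
  gene_terms <- as.matrix(gene_terms)
  if (ncol(gene_terms) != 2L)
    stop("`gene_terms` must have two columns (gene, term)", call. = FALSE)
  storage.mode(gene_terms) <- "character"
  gt <- lapply(split(gene_terms[, 2L], gene_terms[, 1L]), unique)
  terms <- unique(gene_terms[, 2L])
  if (!is.null(dag_edges)) {
    levels <- term_levels(dag_edges)
  } else if (is.null(levels)) {
    levels <- stats::setNames(integer(0), character(0))
  }
  lv <- stats::setNames(rep(NA_integer_, length(terms)), terms)
  known <- intersect(terms, names(levels))
  lv[known] <- as.integer(levels[known])
  structure(list(gene_terms = gt, term_level = lv,
                 genes = names(gt), terms = terms),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set: ", length(x$genes), " genes, ", length(x$terms),
      " terms (", sum(!is.na(x$term_level)), " with levels)\n", sep = "")
  invisible(x)
}

# genes of the background annotated with a given term
term_genes <- function(ann, background) {
  flat <- rep(names(ann$gene_terms), lengths(ann$gene_terms))
  tt <- unlist(ann$gene_terms, use.names = FALSE)
  keep <- flat %in% background
  split(flat[keep], factor(tt[keep], levels = ann$terms))
}

#' Term enrichment of modules
#'
#' One-sided hypergeometric (Fisher) test per (module, term) pair: the
#' probability of drawing at least the observed number of term-annotated
#' genes when drawing `|module|` genes from the background. Multiple-testing
#' correction is applied across all tests of the run (`family = "global"`,
#' default) or within each module.
#'
#' @param modules a [module_set].
#' @param annotations an [annotation_set].
#' @param background character vector of background gene identifiers
#'   (default: union of module genes and annotated genes; in a pipeline pass
#'   the genes of the analyzed, post-filter dataset). Module genes must all
#'   be contained in it.
#' @param p_adjust correction method, `"BH"` (default) or any
#'   [stats::p.adjust] method, e.g. `"bonferroni"`.
#' @param family `"global"` or `"per_module"` correction family.
#' @return Data frame with columns `module` (index into the canonical
#'   ordering of `modules`), `term`, `overlap`, `p`, `p_adj`, `level`.
#' @export
enrich_modules <- function(modules, annotations, background = NULL,
                           p_adjust = "BH",
                           family = c("global", "per_module")) {
  family <- match.arg(family)
  stopifnot(inherits(annotations, "annotation_set"))
  mods <- unclass(module_set(modules))
  mod_genes <- lapply(mods, `[[`, "genes")
  if (is.null(background))
    background <- sort(union(unlist(mod_genes), annotations$genes))
  if (!length(background)) stop("empty background", call. = FALSE)
  missing <- setdiff(unlist(mod_genes), background)
  if (length(missing))
    stop("module gene(s) not in background: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  tg <- term_genes(annotations, background)
  N <- length(background)
  rows <- list()
  for (i in seq_along(mods)) {
    g <- mod_genes[[i]]
    terms_here <- unique(unlist(annotations$gene_terms[intersect(g, annotations$genes)],
                                use.names = FALSE))
    for (tm in terms_here) {
      M <- length(tg[[tm]])
      obs <- length(intersect(g, tg[[tm]]))
      p <- stats::phyper(obs - 1, M, N - M, length(g), lower.tail = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(module = i, term = tm, overlap = obs, p = p,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(module = integer(0), term = character(0),
                      overlap = integer(0), p = numeric(0),
                      p_adj = numeric(0), level = integer(0)))
  res <- do.call(rbind, rows)
  res$p_adj <- if (family == "global") {
    stats::p.adjust(res$p, method = p_adjust)
  } else {
    stats::ave(res$p, res$module,
               FUN = function(p) stats::p.adjust(p, method = p_adjust))
  }
  res$level <- unname(annotations$term_level[res$term])
  res
}

# rows of an enrichment table that pass the significance threshold
enriched_rows <- function(enrichment, p_threshold) {
  enrichment[enrichment$p_adj < p_threshold, , drop = FALSE]
}

#' Enrichment ratio (ER)
#'
#' Percentage of modules enriched (corrected p below `p_threshold`) with at
#' least one term of level `deep_level` or deeper -- a proxy for the
#' probability that an inferred module is a set of functionally related
#' genes.
#'
#' @inheritParams enrich_modules
#' @param p_threshold corrected-p significance threshold (default 0.05).
#' @param deep_level minimum term level to count (default 7).
#' @param enrichment optional precomputed [enrich_modules()] table.
#' @return ER in `[0, 100]`.
#' @export
enrichment_ratio <- function(modules, annotations, p_threshold = 0.05,
                             deep_level = 7L, background = NULL,
                             enrichment = NULL) {
  if (is.null(enrichment))
    enrichment <- enrich_modules(modules, annotations, background)
  if (!length(modules)) return(0)
  sig <- enriched_rows(enrichment, p_threshold)
  sig <- sig[!is.na(sig$level) & sig$level >= deep_level, , drop = FALSE]
  100 * length(unique(sig$module)) / length(modules)
}

#' Coverage (COV)
#'
#' Percentage of all terms associated with the dataset's genes that are
#' enriched in at least one module.
#'
#' @inheritParams enrichment_ratio
#' @return COV in `[0, 100]`.
#' @export
coverage <- function(modules, annotations, p_threshold = 0.05,
                     background = NULL, enrichment = NULL) {
  if (is.null(enrichment))
    enrichment <- enrich_modules(modules, annotations, background)
  if (is.null(background))
    background <- sort(union(unlist(lapply(modules, `[[`, "genes")),
                             annotations$genes))
  dataset_terms <- unique(unlist(
    annotations$gene_terms[intersect(background, annotations$genes)],
    use.names = FALSE))
  if (!length(dataset_terms)) return(0)
  sig <- enriched_rows(enrichment, p_threshold)
  100 * length(intersect(unique(sig$term), dataset_terms)) /
    length(dataset_terms)
}

#' Individual coverage (IC)
#'
#' For each gene appearing in at least one module and carrying at least one
#' term, the fraction of its terms enriched in some module containing the
#' gene; IC is 100 times the mean of these fractions. It measures how well
#' the several functional contexts of individual genes are reflected --
#' methods producing overlapping modules can assign a gene to several
#' functional contexts and thus reach higher IC.
#'
#' @inheritParams enrichment_ratio
#' @return IC in `[0, 100]`.
#' @export
individual_coverage <- function(modules, annotations, p_threshold = 0.05,
                                background = NULL, enrichment = NULL) {
  if (is.null(enrichment))
    enrichment <- enrich_modules(modules, annotations, background)
  mods <- unclass(module_set(modules))
  sig <- enriched_rows(enrichment, p_threshold)
  genes <- intersect(unique(unlist(lapply(mods, `[[`, "genes"))),
                     annotations$genes)
  if (!length(genes)) return(0)
  fractions <- vapply(genes, function(g) {
    t_g <- annotations$gene_terms[[g]]
    in_mod <- which(vapply(mods, function(m) g %in% m$genes, logical(1)))
    e_terms <- unique(sig$term[sig$module %in% in_mod])
    length(intersect(t_g, e_terms)) / length(t_g)
  }, numeric(1))
  100 * mean(fractions)
}

#' Overlapping module pairs supporting different functionalities (OMPSDF)
#'
#' Counts unordered module pairs that (i) overlap in at least one gene,
#' (ii) share no enriched term at level `core_level` or shallower (so they
#' reflect different cellular core processes), and (iii) share a gene
#' annotated with two deep terms (level `deep_level` or deeper), one
#' enriched in the first module only and the other in the second only --
#' evidence that the shared gene participates in two essentially different
#' functionalities. Partitioning methods (disjoint modules) always score 0.
#'
#' @inheritParams enrichment_ratio
#' @param core_level maximum level of a shared enriched term that
#'   disqualifies a pair (default 3).
#' @param deep_level minimum level of the discriminating terms (default 7).
#' @return Integer pair count.
#' @export
ompsdf <- function(modules, annotations, p_threshold = 0.05, core_level = 3L,
                   deep_level = 7L, background = NULL, enrichment = NULL) {
  if (is.null(enrichment))
    enrichment <- enrich_modules(modules, annotations, background)
  mods <- unclass(module_set(modules))
  n <- length(mods)
  if (n < 2L) return(0L)
  sig <- enriched_rows(enrichment, p_threshold)
  enr <- split(sig$term, factor(sig$module, levels = seq_len(n)))
  lv <- annotations$term_level
  count <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      shared <- intersect(mods[[i]]$genes, mods[[j]]$genes)
      if (!length(shared)) next
      e1 <- enr[[i]]; e2 <- enr[[j]]
      core_shared <- intersect(e1, e2)
      core_shared <- core_shared[!is.na(lv[core_shared]) &
                                   lv[core_shared] <= core_level]
      if (length(core_shared)) next
      only1 <- setdiff(e1, e2)
      only2 <- setdiff(e2, e1)
      only1 <- only1[!is.na(lv[only1]) & lv[only1] >= deep_level]
      only2 <- only2[!is.na(lv[only2]) & lv[only2] >= deep_level]
      if (!length(only1) || !length(only2)) next
      hit <- FALSE
      for (g in intersect(shared, annotations$genes)) {
        tg <- annotations$gene_terms[[g]]
        if (length(intersect(tg, only1)) && length(intersect(tg, only2))) {
          hit <- TRUE
          break
        }
      }
      if (hit) count <- count + 1L
    }
  }
  count
}

#' Basic module-set statistics
#'
#' @param modules a [module_set].
#' @param net optional [profile_network] for recomputing densities; without
#'   it the stored densities are averaged.
#' @return A list: `n_genes` (union of module genes), `n_modules`, `ams`
#'   (average module size) and `dy` (average density).
#' @export
basic_stats <- function(modules, net = NULL) {
  mods <- unclass(module_set(modules))
  if (!length(mods))
    return(list(n_genes = 0L, n_modules = 0L, ams = NA_real_, dy = NA_real_))
  sizes <- vapply(mods, function(m) length(m$genes), integer(1))
  dens <- if (!is.null(net)) {
    vapply(mods, function(m) subgraph_density(net, m$genes), numeric(1))
  } else {
    vapply(mods, function(m) m$density, numeric(1))
  }
  list(n_genes = length(unique(unlist(lapply(mods, `[[`, "genes")))),
       n_modules = length(mods),
       ams = mean(sizes),
       dy = mean(dens))
}

#' Full module-set assessment
#'
#' Computes the enrichment table once and derives all assessment metrics:
#' basic statistics, enrichment ratio, coverage, individual coverage and the
#' OMPSDF pair count.
#'
#' @inheritParams enrichment_ratio
#' @inheritParams ompsdf
#' @param net optional [profile_network] for density recomputation.
#' @param p_adjust multiple-testing correction method (default `"BH"`).
#' @return An object of class `dcb_metrics`: all metrics plus the
#'   enrichment table.
#' @export
evaluate_modules <- function(modules, annotations, net = NULL,
                             background = NULL, p_threshold = 0.05,
                             deep_level = 7L, core_level = 3L,
                             p_adjust = "BH") {
  modules <- module_set(modules)
  enrichment <- enrich_modules(modules, annotations, background,
                               p_adjust = p_adjust)
  stats <- basic_stats(modules, net)
  structure(
    c(stats,
      list(er = enrichment_ratio(modules, annotations, p_threshold,
                                 deep_level, background, enrichment),
           cov = coverage(modules, annotations, p_threshold, background,
                          enrichment),
           ic = individual_coverage(modules, annotations, p_threshold,
                                    background, enrichment),
           ompsdf = ompsdf(modules, annotations, p_threshold, core_level,
                           deep_level, background, enrichment),
           p_threshold = p_threshold, deep_level = deep_level,
           core_level = core_level, enrichment = enrichment)),
    class = "dcb_metrics")
}

#' @export
print.dcb_metrics <- function(x, ...) {
  cat("module assessment\n",
      "  genes covered: ", x$n_genes, "   modules: ", x$n_modules,
      "   AMS: ", format(x$ams, digits = 4),
      "   DY: ", format(x$dy, digits = 4), "\n",
      "  ER: ", format(x$er, digits = 4),
      "%   COV: ", format(x$cov, digits = 4),
      "%   IC: ", format(x$ic, digits = 4),
      "%   OMPSDF: ", x$ompsdf, "\n", sep = "")
  invisible(x)
}
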