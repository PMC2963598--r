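#' Sample random connected subnetworks
#'
#' Draws `n_samples` connected induced gene sets of exactly `k` genes: a
#' start gene is chosen uniformly among genes lying in components of size at
#' least `k`, then the set grows by repeatedly adding a uniformly chosen
#' neighbor of the current set. Used as the empirical null for module
#' co-expression.
#'
#' @param net a [profile_network].
#' @param k subnetwork size.
#' @param n_samples number of draws.
#' @param seed optional integer seed for reproducibility.
#' @return A list of `n_samples` character vectors of gene identifiers.
#' @export
sample_connected_subnetworks <- function(net, k, n_samples, seed = NULL) {
  stopifnot(inherits(net, "profile_network"), k >= 1, n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  comp <- igraph::components(net$graph)
  eligible <- which(comp$csize[comp$membership] >= k)
  if (!length(eligible))
    stop("no connected component of size >= ", k, call. = FALSE)
  adj <- pn_adjacency(net)
  out <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    S <- sample(eligible, 1L)
    while (length(S) < k) {
      nb <- which(rowSums(adj[, S, drop = FALSE]) > 0L)
      nb <- setdiff(nb, S)
      S <- c(S, nb[sample.int(length(nb), 1L)])
    }
    out[[s]] <- net$genes[sort(S)]
  }
  out
}

#' Fit a truncated-normal null to co-expressed-condition counts
#'
#' Maximum-likelihood fit of a normal distribution truncated to
#' `bounds` (by default `[0, C]`, the natural support of a count of
#' co-expressed conditions out of `C`). A constant sample is flagged
#' degenerate and treated as a point mass.
#'
#' @param counts numbers of co-expressed conditions observed in sampled
#'   connected subnetworks.
#' @param bounds length-2 numeric truncation interval.
#' @return An object of class `coexpression_null`: `mean`, `sd`, `lower`,
#'   `upper`, `n`, `degenerate` (and `point` for the degenerate case).
#' @export
fit_coexpression_null <- function(counts, bounds) {
  stopifnot(length(counts) > 0, length(bounds) == 2L, bounds[1] < bounds[2])
  if (any(counts < bounds[1] | counts > bounds[2]))
    stop("counts outside the truncation bounds", call. = FALSE)
  a <- bounds[1]; b <- bounds[2]
  if (stats::var(counts) == 0 || length(counts) == 1L) {
    return(structure(list(mean = counts[1], sd = 0, lower = a, upper = b,
                          n = length(counts), degenerate = TRUE,
                          point = counts[1]),
                     class = "coexpression_null"))
  }
  nll <- function(par) {
    mu <- par[1]; s <- exp(par[2])
    z <- stats::pnorm(b, mu, s) - stats::pnorm(a, mu, s)
    if (!is.finite(z) || z <= 0) return(1e10)
    -sum(stats::dnorm(counts, mu, s, log = TRUE)) + length(counts) * log(z)
  }
  init <- c(mean(counts), log(stats::sd(counts)))
  fit <- stats::optim(init, nll, method = "Nelder-Mead")
  structure(list(mean = fit$par[1], sd = exp(fit$par[2]), lower = a,
                 upper = b, n = length(counts), degenerate = FALSE),
            class = "coexpression_null")
}

#' @export
print.coexpression_null <- function(x, ...) {
  if (x$degenerate)
    cat("coexpression_null: degenerate point mass at ", x$point,
        " (n = ", x$n, ")\n", sep = "")
  else
    cat("coexpression_null: truncated normal, mean ", format(x$mean, digits = 4),
        ", sd ", format(x$sd, digits = 4), " on [", x$lower, ", ", x$upper,
        "] (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Upper-tail p-value under the co-expression null
#'
#' `P(X >= observed)` for the fitted truncated normal: a module co-expressed
#' in more conditions than random connected subnetworks of its size is more
#' significant. For a degenerate (point-mass) null the p-value is 1 when the
#' observation does not exceed the mass point and 0 otherwise.
#'
#' @param null a [fit_coexpression_null()] object.
#' @param observed observed count(s) of co-expressed conditions.
#' @return p-value(s) in `[0, 1]`, non-increasing in `observed`.
#' @export
coexpression_pvalue <- function(null, observed) {
  stopifnot(inherits(null, "coexpression_null"))
  if (null$degenerate)
    return(ifelse(observed <= null$point, 1, 0))
  x <- pmin(pmax(observed, null$lower), null$upper)
  z <- stats::pnorm(null$upper, null$mean, null$sd) -
    stats::pnorm(null$lower, null$mean, null$sd)
  p <- (stats::pnorm(null$upper, null$mean, null$sd) -
          stats::pnorm(x, null$mean, null$sd)) / z
  ifelse(observed > null$upper, 0, pmin(pmax(p, 0), 1))
}

#' Hypergeometric p-value for module density
#'
#' Probability that a random draw of `choose(k, 2)` gene pairs from the
#' `choose(n_nodes, 2)` possible pairs of the network contains at least `m`
#' of its `n_edges` actual edges -- the urn model for how surprising a
#' subnetwork with `k` genes and `m` internal edges is.
#'
#' @param n_nodes,n_edges size of the whole network.
#' @param k module size (`2 <= k <= n_nodes`).
#' @param m number of edges inside the module.
#' @return Upper-tail p-value `P(X >= m)`.
#' @examples
#' density_pvalue(5, 6, 3, 3)  # 20/120 = 1/6
#' @export
density_pvalue <- function(n_nodes, n_edges, k, m) {
  if (k < 2 || k > n_nodes)
    stop("`k` must be in [2, n_nodes]", call. = FALSE)
  if (m < 0 || m > choose(k, 2) || m > n_edges)
    stop("`m` must be in [0, min(choose(k, 2), n_edges)]", call. = FALSE)
  N <- choose(n_nodes, 2)
  stats::phyper(m - 1, n_edges, N - n_edges, choose(k, 2),
                lower.tail = FALSE)
}

#' Rank modules by co-expression and density significance
#'
#' Every module receives a co-expression p-value (its number of co-expressed
#' conditions against a truncated-normal null fitted to counts from randomly
#' sampled connected subnetworks of the same size) and a density p-value
#' (hypergeometric, see [density_pvalue()]). Modules are ranked on each
#' criterion separately, smaller p-value first, with competition ranking
#' (ties share the smallest rank), and the overall rank is the average of
#' the two; the returned set is sorted by overall rank, ties broken by size
#' (descending) then gene list.
#'
#' @param modules a [module_set].
#' @param net the [profile_network] the modules were discovered in.
#' @param epsilon homogeneity threshold used when counting co-expressed
#'   conditions of the sampled null subnetworks (use the discovery value).
#' @param n_samples connected subnetworks sampled per module size
#'   (default 2000).
#' @param seed optional integer seed.
#' @param pooled fit one null from all sampled sizes pooled instead of one
#'   per module size.
#' @return The module set with fields `p_coexpression`, `p_density`,
#'   `rank_coexpression`, `rank_density` and `overall_rank` added to every
#'   module, sorted by overall rank.
#' @export
rank_modules <- function(modules, net, epsilon, n_samples = 2000L,
                         seed = NULL, pooled = FALSE) {
  stopifnot(inherits(net, "profile_network"), length(modules) > 0)
  if (!is.null(seed)) set.seed(seed)
  mods <- unclass(module_set(modules))
  sizes <- vapply(mods, function(m) length(m$genes), integer(1))
  n_cond <- length(net$conditions)

  sampled_counts <- function(k) {
    sets <- sample_connected_subnetworks(net, k, n_samples)
    vapply(sets, function(g)
      length(coexpression_subspace(net, g, epsilon)), integer(1))
  }
  nulls <- list()
  if (pooled) {
    counts <- unlist(lapply(sort(unique(sizes)), sampled_counts))
    pooled_null <- fit_coexpression_null(counts, c(0, n_cond))
  } else {
    for (k in sort(unique(sizes)))
      nulls[[as.character(k)]] <- fit_coexpression_null(sampled_counts(k),
                                                        c(0, n_cond))
  }

  n_nodes <- length(net$genes)
  n_edges <- igraph::ecount(net$graph)
  p_co <- numeric(length(mods))
  p_de <- numeric(length(mods))
  for (i in seq_along(mods)) {
    m <- mods[[i]]
    null <- if (pooled) pooled_null else nulls[[as.character(length(m$genes))]]
    p_co[i] <- coexpression_pvalue(null, length(m$subspace))
    k <- length(m$genes)
    edges <- round(subgraph_density(net, m$genes) * choose(k, 2))
    p_de[i] <- density_pvalue(n_nodes, n_edges, k, edges)
  }
  r_co <- rank_competition(p_co)
  r_de <- rank_competition(p_de)
  overall <- (r_co + r_de) / 2
  for (i in seq_along(mods)) {
    mods[[i]]$p_coexpression <- p_co[i]
    mods[[i]]$p_density <- p_de[i]
    mods[[i]]$rank_coexpression <- r_co[i]
    mods[[i]]$rank_density <- r_de[i]
    mods[[i]]$overall_rank <- overall[i]
  }
  keys <- vapply(mods, module_key, character(1))
  ord <- order(overall, -sizes, keys, method = "radix")
  structure(mods[ord], class = "dcb_module_set")
}

# competition ("1224") ranking: ties share the smallest rank
rank_competition <- function(p) {
  as.integer(rank(p, ties.method = "min"))
}

#' Redundancy filter over a ranked module list
#'
#' Walks the ranked list from best to worst and keeps a module only if its
#' gene set is not already covered by the genes of the modules kept so far
#' (by default collectively, i.e. against their union; set
#' `containment = "single"` to only drop modules nested inside one kept
#' module). Optionally stops after `top_n` modules have been kept, yielding
#' a top-N collection.
#'
#' @param ranked a module set sorted by overall rank, as returned by
#'   [rank_modules()].
#' @param top_n keep at most this many modules (default: no limit).
#' @param containment `"union"` (default) or `"single"`.
#' @return The filtered [module_set], still in rank order.
#' @export
filter_ranked <- function(ranked, top_n = Inf,
                          containment = c("union", "single")) {
  containment <- match.arg(containment)
  kept <- list()
  kept_genes <- character(0)
  for (m in ranked) {
    if (length(kept) >= top_n) break
    covered <- if (containment == "union") {
      all(m$genes %in% kept_genes)
    } else {
      any(vapply(kept, function(kk) all(m$genes %in% kk$genes), logical(1)))
    }
    if (!covered) {
      kept <- c(kept, list(m))
      kept_genes <- union(kept_genes, m$genes)
    }
  }
  structure(kept, class = "dcb_module_set")
}
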