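#' Whittaker's index of association between two abundance profiles
#'
#' Profiles are scaled to percentages; `IA = 100 - 0.5 * sum |p_s - q_s|`.
#' Proportional profiles score 100, profiles with disjoint site support
#' score 0; the index is symmetric.
#'
#' @param x,y non-negative count vectors over the same sites, positive totals.
#' @return IA value in \[0, 100\].
#' @export
index_of_association <- function(x, y) {
  if (length(x) != length(y)) stop("profiles must cover the same sites")
  if (sum(x) <= 0 || sum(y) <= 0)
    stop("undefined IA: zero-total abundance vector")
  p <- 100 * x / sum(x)
  q <- 100 * y / sum(y)
  100 - 0.5 * sum(abs(p - q))
}

#' All pairwise IA values of an oligotype table
#'
#' @param table oligotype-by-site count matrix (rows with positive totals).
#' @return symmetric matrix of IA values (diagonal 100).
#' @export
ia_matrix <- function(table) {
  if (any(rowSums(table) <= 0)) stop("undefined IA: zero-total row(s)")
  P <- 100 * table / rowSums(table)
  D <- as.matrix(stats::dist(P, method = "manhattan"))
  ia <- 100 - 0.5 * D
  dimnames(ia) <- list(rownames(table), rownames(table))
  ia
}

#' Permutation null for pairwise IA values
#'
#' Each permutation independently shuffles the site order within every
#' oligotype abundance vector and recomputes all pairwise IA values. The
#' probability of the observed IA given the permuted values is estimated as
#' the plug-in proportion `p_ij = #permuted IA >= observed IA / n_perm`
#' (default), which can reach exactly 0 for pairs whose observed association
#' exceeds every permuted one — without this, no pair can survive
#' Benjamini-Hochberg correction over a large pair family at a few hundred
#' permutations. The conservative add-one estimator
#' `(1 + hits) / (1 + n_perm)` is available via `convention = "add-one"`.
#' Adjustment is over all unordered pairs by Benjamini-Hochberg.
#'
#' @param table oligotype-by-site count matrix (>= 2 rows).
#' @param n_perm number of permutations (default 200).
#' @param seed integer seed.
#' @param convention `"plug-in"` (default) or `"add-one"` p-value estimator.
#' @return list with matrices `ia` (observed), `p` and `p_adjusted`.
#' @export
ia_null <- function(table, n_perm = 200, seed = 1L,
                    convention = c("plug-in", "add-one")) {
  convention <- match.arg(convention)
  m <- nrow(table)
  if (m < 2L) stop("need at least 2 oligotypes")
  ns <- ncol(table)
  obs <- ia_matrix(table)
  set.seed(seed)
  P <- 100 * table / rowSums(table)
  hits <- matrix(0L, m, m)
  for (b in seq_len(n_perm)) {
    Pp <- t(apply(P, 1, function(r) r[sample.int(ns)]))
    iap <- 100 - 0.5 * as.matrix(stats::dist(Pp, method = "manhattan"))
    hits <- hits + (iap >= obs)
  }
  p <- if (convention == "add-one") (1 + hits) / (1 + n_perm)
       else hits / n_perm
  diag(p) <- NA
  ut <- upper.tri(p)
  padj <- matrix(NA_real_, m, m, dimnames = dimnames(obs))
  padj[ut] <- fdr_bh(p[ut])
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  dimnames(p) <- dimnames(obs)
  list(ia = obs, p = p, p_adjusted = padj)
}

#' Build the oligotype association graph
#'
#' Nodes are oligotypes with total abundance at least `min_abundance`;
#' edges link pairs with `IA > ia_min` and adjusted p below `alpha`, the IA
#' value serving as edge weight.
#'
#' @param table oligotype-by-site count matrix (rownames = node names).
#' @param null result of [ia_null()] on the same table.
#' @param ia_min IA threshold, strict (default 85).
#' @param alpha adjusted-p threshold, strict (default 0.05).
#' @param min_abundance minimum total read count per node (default 2).
#' @param taxonomy optional data.frame (`node`, `phylum`, `class`) of node
#'   annotations.
#' @return an igraph undirected graph with node attributes `abundance`
#'   (and `phylum`/`class` when supplied) and edge attributes `weight`
#'   (IA), `p` and `p_adjusted`.
#' @export
build_graph <- function(table, null, ia_min = 85, alpha = 0.05,
                        min_abundance = 2, taxonomy = NULL) {
  keep <- rowSums(table) >= min_abundance
  nodes <- rownames(table)[keep]
  ia <- null$ia[nodes, nodes, drop = FALSE]
  padj <- null$p_adjusted[nodes, nodes, drop = FALSE]
  adj <- (ia > ia_min) & !is.na(padj) & (padj < alpha)
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  g <- igraph::set_vertex_attr(g, "abundance",
                               value = unname(rowSums(table)[keep]))
  if (nrow(idx)) {
    g <- igraph::add_edges(g, rbind(idx[, 1], idx[, 2]))
    g <- igraph::set_edge_attr(g, "weight", value = ia[idx])
    g <- igraph::set_edge_attr(g, "p", value = null$p[nodes, nodes][idx])
    g <- igraph::set_edge_attr(g, "p_adjusted", value = padj[idx])
  }
  if (!is.null(taxonomy)) {
    mt <- taxonomy[match(nodes, taxonomy$node), ]
    g <- igraph::set_vertex_attr(g, "phylum", value = mt$phylum)
    g <- igraph::set_vertex_attr(g, "class", value = mt$class)
  }
  g
}

#' Summary statistics of an association network
#'
#' Density `2E/(N(N-1))`; mean local clustering coefficient with nodes of
#' degree < 2 contributing 0; heterogeneity (coefficient of variation of
#' degree); degree centralization `N/(N-2) * (k_max/(N-1) - density)`
#' (undefined below 3 nodes); connected components; mean neighbors `2E/N`;
#' and a least-squares power-law fit `count = a * degree^b` on the raw
#' degree histogram (positive degrees), NetworkAnalyzer-style.
#'
#' @param g igraph graph with >= 1 node.
#' @return list of statistics (`n_nodes`, `n_edges`, `density`,
#'   `clustering_coefficient`, `heterogeneity`, `centralization`,
#'   `mean_neighbors`, `n_components`, `component_sizes`,
#'   `power_law` with `coefficient` and `exponent`).
#' @export
network_stats <- function(g) {
  N <- igraph::vcount(g)
  if (N < 1) stop("need at least 1 node")
  E <- igraph::ecount(g)
  deg <- igraph::degree(g)
  density <- if (N > 1) 2 * E / (N * (N - 1)) else 0
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc <- mean(loc)
  het <- if (mean(deg) > 0) stats::sd(deg) / mean(deg) else 0
  centr <- if (N >= 3) (N / (N - 2)) * (max(deg) / (N - 1) - density) else NA_real_
  comp <- igraph::components(g)
  dtab <- table(deg[deg > 0])
  pl <- if (length(dtab) >= 2) {
    fit <- stats::lm(log(as.numeric(dtab)) ~ log(as.numeric(names(dtab))))
    list(coefficient = unname(exp(stats::coef(fit)[1])),
         exponent = unname(stats::coef(fit)[2]))
  } else list(coefficient = NA_real_, exponent = NA_real_)
  list(n_nodes = N, n_edges = E, density = density,
       clustering_coefficient = cc, heterogeneity = het,
       centralization = centr, mean_neighbors = if (N > 0) 2 * E / N else 0,
       n_components = comp$no,
       component_sizes = sort(as.integer(comp$csize), decreasing = TRUE),
       power_law = pl)
}

#' Rescale IA edge weights for Markov clustering
#'
#' Linear increasing map from IA in \[85, 100\] onto \[0.001, 0.15\], the
#' compressed weight interval that keeps the MCL flow well-conditioned.
#'
#' @param ia numeric vector of IA values in \[85, 100\].
#' @param from,to source and target intervals.
#' @return rescaled weights.
#' @export
rescale_edge_weights <- function(ia, from = c(85, 100), to = c(0.001, 0.15)) {
  if (any(ia < from[1] - 1e-9 | ia > from[2] + 1e-9))
    stop("IA value(s) outside [", from[1], ", ", from[2], "]")
  to[1] + (ia - from[1]) / diff(from) * diff(to)
}

#' Markov clustering (MCL) of a weighted graph
#'
#' Builds a column-stochastic flow matrix from the (rescaled) edge weights
#' with self-loops set to each node's maximum incident weight, then
#' alternates expansion (matrix squaring) and inflation (entrywise power
#' `inflation`, column renormalization) with pruning of small entries until
#' the matrix is idempotent. Clusters are read off the attractor rows;
#' nodes attracted by several attractors are resolved to the heaviest.
#'
#' @param g igraph graph with positive edge weights (attribute `weight`),
#'   or a symmetric non-negative weight matrix.
#' @param inflation granularity parameter (> 1, default 2.5).
#' @param prune_threshold entries below this are zeroed each step.
#' @param tol convergence tolerance on the max entry change.
#' @param max_iterations iteration cap.
#' @return list with `membership` (named integer vector; cluster ids are
#'   1-based, ordered by decreasing cluster size), `n_clusters` and
#'   `iterations`.
#' @export
mcl <- function(g, inflation = 2.5, prune_threshold = 1e-5, tol = 1e-8,
                max_iterations = 200L) {
  if (inflation <= 1) stop("inflation must exceed 1")
  if (inherits(g, "igraph")) {
    W <- igraph::as_adjacency_matrix(g, attr = if (!is.null(igraph::E(g)$weight))
      "weight" else NULL, sparse = FALSE)
    nodes <- igraph::V(g)$name
    if (is.null(nodes)) nodes <- as.character(seq_len(nrow(W)))
  } else {
    W <- as.matrix(g)
    if (!isTRUE(all.equal(W, t(W)))) stop("weight matrix must be symmetric")
    nodes <- rownames(W) %||% as.character(seq_len(nrow(W)))
  }
  n <- nrow(W)
  if (n == 0) stop("empty graph")
  if (any(W < 0)) stop("weights must be non-negative")
  diag(W) <- 0
  # self-loop regularization: each node's maximum incident weight (or 1 for
  # isolated nodes) keeps the walk aperiodic
  self <- apply(W, 2, max)
  self[self == 0] <- 1
  diag(W) <- self
  M <- sweep(W, 2, colSums(W), `/`)

  it <- 0L
  repeat {
    it <- it + 1L
    M2 <- M %*% M                      # expansion
    M2 <- M2^inflation                 # inflation
    M2[M2 < prune_threshold] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2, cs, `/`)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
    if (it >= max_iterations)
      stop("MCL failed to converge after ", max_iterations,
           " iterations (last change ", signif(delta, 3), ")")
  }

  attractors <- which(rowSums(M) > prune_threshold)
  membership <- integer(n)
  # attractors whose rows overlap in support (or flow into each other)
  # belong to one cluster: take connected components of that relation
  na <- length(attractors)
  S <- M[attractors, , drop = FALSE] > 0
  B <- (S %*% t(S) > 0) |
    (M[attractors, attractors, drop = FALSE] > 0) |
    t(M[attractors, attractors, drop = FALSE] > 0)
  cluster_of_attr <- if (na) igraph::components(
    igraph::graph_from_adjacency_matrix(1 * B, mode = "max"))$membership
  else integer(0)
  cl <- max(cluster_of_attr, 0L)
  for (j in seq_len(n)) {
    w <- M[attractors, j]
    if (!length(w) || all(w == 0)) {  # stray node: own singleton cluster
      cl <- cl + 1L
      membership[j] <- cl
    } else {
      membership[j] <- cluster_of_attr[which.max(w)]
    }
  }
  # relabel clusters by decreasing size
  sizes <- sort(table(membership), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  membership <- unname(relabel[as.character(membership)])
  names(membership) <- nodes
  list(membership = membership, n_clusters = length(sizes), iterations = it)
}

#' Summarize MCL clusters
#'
#' @param membership named cluster assignment from [mcl()].
#' @param node_meta data.frame with columns `node`, `abundance` and
#'   optionally `phylum`, `class`.
#' @return data.frame sorted by decreasing cluster size: `cluster`, `size`,
#'   `mean_abundance`, `max_abundance`, `n_phyla`, `n_classes`.
#' @export
cluster_summary <- function(membership, node_meta) {
  if (!length(membership))
    return(data.frame(cluster = integer(0), size = integer(0),
                      mean_abundance = numeric(0), max_abundance = numeric(0),
                      n_phyla = integer(0), n_classes = integer(0)))
  meta <- node_meta[match(names(membership), node_meta$node), ]
  rows <- lapply(split(seq_along(membership), membership), function(ii) {
    data.frame(
      cluster = membership[ii[1]],
      size = length(ii),
      mean_abundance = mean(meta$abundance[ii]),
      max_abundance = max(meta$abundance[ii]),
      n_phyla = if ("phylum" %in% names(meta))
        length(unique(stats::na.omit(meta$phylum[ii]))) else NA_integer_,
      n_classes = if ("class" %in% names(meta))
        length(unique(stats::na.omit(meta$class[ii]))) else NA_integer_)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out <- out[order(-out$size, out$cluster), , drop = FALSE]
  rownames(out) <- NULL
  out
}
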