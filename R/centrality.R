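# Six topological centrality measures on simple undirected graphs.
#
# Conventions (fixed, documented):
#  - BC sums over ordered distinct pairs (each unordered pair counted twice);
#    a constant factor that never changes a ranking.
#  - CC uses the component-local form (n_c - 1) / sum of within-component
#    distances; isolated nodes score 0.
#  - SC is computed by full symmetric eigendecomposition of the adjacency
#    matrix (no series truncation).
#  - ECC(u,v) = (# triangles on the edge) / min(deg(u) - 1, deg(v) - 1), with
#    a zero denominator mapped to 0; NC(v) sums ECC over v's incident edges.

#' Degree centrality
#'
#' @param g A simple undirected `igraph`.
#' @return Named numeric vector of node degrees.
#' @export
degree_centrality <- function(g) {
  g <- ensure_named(g)
  deg <- igraph::degree(g)
  stats::setNames(as.numeric(deg), igraph::V(g)$name)
}

#' Betweenness centrality (ordered-pair convention)
#'
#' Sum over ordered pairs `s != v != t` of the fraction of shortest `s`-`t`
#' paths passing through `v`; unreachable pairs contribute 0. Equals twice
#' the usual unordered-pair betweenness of an undirected graph.
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(g) {
  g <- ensure_named(g)
  b <- 2 * igraph::betweenness(g, directed = FALSE, weights = NA)
  stats::setNames(as.numeric(b), igraph::V(g)$name)
}

#' Closeness centrality (component-local)
#'
#' For a node `v` in a connected component of size `n_c`,
#' `CC(v) = (n_c - 1) / sum(d(v, u))` over the nodes `u` of that component.
#' Isolated nodes score 0. Cross-component distances -- undefined for the
#' textbook formula -- never enter.
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector.
#' @export
closeness_centrality <- function(g) {
  g <- ensure_named(g)
  n <- igraph::vcount(g)
  cc <- stats::setNames(numeric(n), igraph::V(g)$name)
  if (n == 0L) return(cc)
  comp <- igraph::components(g)
  for (ci in seq_len(comp$no)) {
    mem <- which(comp$membership == ci)
    if (length(mem) < 2L) next
    d <- igraph::distances(g, v = mem, to = mem, weights = NA)
    cc[mem] <- (length(mem) - 1) / rowSums(d)
  }
  cc
}

#' Subgraph centrality
#'
#' `SC(i)` weights the closed walks starting and ending at node `i` by the
#' reciprocal factorial of their length, which equals the `i`-th diagonal
#' entry of the matrix exponential of the adjacency matrix. It is computed
#' through the spectral form `sum_j v_ji^2 * exp(lambda_j)` from a full
#' symmetric eigendecomposition.
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector (every entry is at least 1: the length-0
#'   walk).
#' @export
subgraph_centrality <- function(g) {
  g <- ensure_named(g)
  n <- igraph::vcount(g)
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  e <- eigen(A, symmetric = TRUE)
  sc <- drop((e$vectors^2) %*% exp(e$values))
  stats::setNames(as.numeric(sc), igraph::V(g)$name)
}

#' Local average connectivity (LAC)
#'
#' `LAC(v)` is the average degree, within the subgraph induced on `v`'s
#' neighbours (excluding `v` itself), of those neighbours. Every edge of that
#' induced subgraph closes a triangle through `v`, so
#' `LAC(v) = 2 * T(v) / deg(v)` with `T(v)` the number of triangles at `v`;
#' degree-0 nodes score 0.
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector.
#' @export
lac <- function(g) {
  g <- ensure_named(g)
  deg <- igraph::degree(g)
  tri <- igraph::count_triangles(g)
  out <- ifelse(deg == 0, 0, 2 * tri / pmax(deg, 1))
  stats::setNames(as.numeric(out), igraph::V(g)$name)
}

ecc_table <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  nm <- igraph::V(g)$name
  if (nrow(el) == 0L)
    return(data.frame(u = character(), v = character(), triangles = numeric(),
                      ecc = numeric(), stringsAsFactors = FALSE))
  deg <- igraph::degree(g)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  A2 <- A %*% A
  z <- as.numeric(A2[cbind(el[, 1L], el[, 2L])])
  den <- pmin(deg[el[, 1L]], deg[el[, 2L]]) - 1
  data.frame(u = nm[el[, 1L]], v = nm[el[, 2L]], triangles = z,
             ecc = ifelse(den <= 0, 0, z / pmax(den, 1)),
             stringsAsFactors = FALSE)
}

#' Edge clustering coefficient of one edge
#'
#' The number of triangles containing the edge -- equivalently the number of
#' common neighbours of its endpoints -- divided by the maximum possible,
#' `min(deg(u) - 1, deg(v) - 1)`; 0 when that denominator is 0 (a pendant
#' edge).
#'
#' @inheritParams degree_centrality
#' @param u,v Vertex names of an existing edge.
#' @return A single number in `[0, 1]`.
#' @export
edge_clustering_coefficient <- function(g, u, v) {
  g <- ensure_named(g)
  eid <- igraph::get_edge_ids(g, c(u, v))
  if (eid == 0) stop(sprintf("(%s, %s) is not an edge of the graph", u, v),
                     call. = FALSE)
  nu <- igraph::neighbors(g, u)
  nv <- igraph::neighbors(g, v)
  z <- length(intersect(as.integer(nu), as.integer(nv)))
  den <- min(igraph::degree(g, u), igraph::degree(g, v)) - 1
  if (den <= 0) 0 else z / den
}

#' Edge-clustering-coefficient centrality (NC)
#'
#' `NC(v)` sums the edge clustering coefficients of the edges incident to
#' `v`.
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector.
#' @export
nc <- function(g) {
  g <- ensure_named(g)
  nm <- igraph::V(g)$name
  out <- stats::setNames(numeric(length(nm)), nm)
  tab <- ecc_table(g)
  if (nrow(tab)) {
    agg <- rowsum(c(tab$ecc, tab$ecc), c(tab$u, tab$v))
    out[rownames(agg)] <- agg[, 1L]
  }
  out
}

centrality_measures <- c("DC", "BC", "CC", "SC", "LAC", "NC")

#' Compute one centrality measure by name
#'
#' @inheritParams degree_centrality
#' @param measure One of `"DC"`, `"BC"`, `"CC"`, `"SC"`, `"LAC"`, `"NC"`.
#' @return Named numeric vector of node scores.
#' @export
centrality_scores <- function(g, measure) {
  measure <- match.arg(measure, centrality_measures)
  switch(measure,
         DC = degree_centrality(g),
         BC = betweenness_centrality(g),
         CC = closeness_centrality(g),
         SC = subgraph_centrality(g),
         LAC = lac(g),
         NC = nc(g))
}

#' Deterministic descending ranking of scored nodes
#'
#' Nodes are ordered by descending score; ties are broken lexicographically
#' by identifier (byte order, locale-independent), so the ranking is fully
#' deterministic.
#'
#' @param scores Named numeric vector of node scores.
#' @return A data frame with columns `node` and `score`, ordered.
#' @export
rank_nodes <- function(scores) {
  if (length(scores) == 0L)
    return(data.frame(node = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  if (is.null(names(scores))) stop("scores must be named", call. = FALSE)
  ord <- order(-scores, names(scores), method = "radix")
  data.frame(node = names(scores)[ord], score = as.numeric(scores)[ord],
             stringsAsFactors = FALSE)
}
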