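# Active-network construction: restrict the static PPI graph, per time point,
# to edges whose two endpoint proteins are simultaneously active.

ensure_named <- function(g) {
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- sprintf("v%03d", seq_len(igraph::vcount(g)))
  g
}

#' Build the active protein interaction network
#'
#' For each time point `t`, an edge of the static network belongs to the
#' active network at `t` exactly when both of its endpoint proteins are
#' active at `t`. Proteins without an expression profile (absent from the
#' activity matrix) are never active. The union graph collects every edge
#' active at at least one time point; its node set is the set of endpoints of
#' those edges.
#'
#' @param graph Static PPI network: a simple undirected `igraph` with vertex
#'   names.
#' @param activity An `"activity_matrix"` from [activity_matrix()].
#' @return An object of class `"active_network"`: a list with `timepoints`,
#'   `static` (the input graph), `per_time` (list of static-edge index
#'   vectors, one per time point), `union_edges` (index vector) and
#'   `union_graph` (an `igraph`).
#' @export
build_active_network <- function(graph, activity) {
  if (!igraph::is_igraph(graph)) stop("graph must be an igraph object", call. = FALSE)
  if (igraph::vcount(graph) == 0L) stop("empty static network", call. = FALSE)
  if (!inherits(activity, "activity_matrix"))
    stop("activity must be an activity_matrix object", call. = FALSE)
  graph <- ensure_named(graph)
  act <- activity$active
  M <- ncol(act)
  ne <- igraph::ecount(graph)
  if (ne == 0L) {
    co <- matrix(FALSE, 0L, M)
  } else {
    el <- igraph::as_edgelist(graph, names = TRUE)
    # pad with an all-FALSE row standing in for proteins without expression
    pad <- rbind(act, matrix(FALSE, 1L, M))
    ia <- match(el[, 1L], rownames(act), nomatch = nrow(pad))
    ib <- match(el[, 2L], rownames(act), nomatch = nrow(pad))
    co <- pad[ia, , drop = FALSE] & pad[ib, , drop = FALSE]
  }
  per_time <- lapply(seq_len(M), function(t) which(co[, t]))
  union_idx <- if (ne) which(rowSums(co) > 0) else integer()
  union_graph <- igraph::subgraph_from_edges(graph, union_idx,
                                             delete.vertices = TRUE)
  structure(
    list(timepoints = M, static = graph, per_time = per_time,
         union_edges = union_idx, union_graph = union_graph),
    class = "active_network")
}

#' Long-format table of active edges
#'
#' @param net An `"active_network"`.
#' @return A data frame with columns `u`, `v`, `t` listing each edge at each
#'   time point where it is active.
#' @export
active_edges <- function(net) {
  stopifnot(inherits(net, "active_network"))
  el <- igraph::as_edgelist(net$static, names = TRUE)
  rows <- lapply(seq_len(net$timepoints), function(t) {
    idx <- net$per_time[[t]]
    if (!length(idx)) return(NULL)
    data.frame(u = el[idx, 1L], v = el[idx, 2L], t = t,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(u = character(), v = character(), t = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Active subnetwork at one time point
#'
#' @param net An `"active_network"`.
#' @param t Time point index in `1:net$timepoints`.
#' @return An `igraph` of the edges active at `t` (isolated vertices dropped).
#' @export
per_time_graph <- function(net, t) {
  stopifnot(inherits(net, "active_network"))
  if (t < 1 || t > net$timepoints) stop("time point out of range", call. = FALSE)
  igraph::subgraph_from_edges(net$static, net$per_time[[t]],
                              delete.vertices = TRUE)
}

#' @export
print.active_network <- function(x, ...) {
  cat(sprintf("active network: %d time points; union graph %d nodes / %d edges (static: %d / %d)\n",
              x$timepoints, igraph::vcount(x$union_graph),
              igraph::ecount(x$union_graph),
              igraph::vcount(x$static), igraph::ecount(x$static)))
  invisible(x)
}

#' Restrict a network to proteins with expression data
#'
#' Returns the subgraph induced on the nodes present in `measured_genes`, so
#' that static-versus-active comparisons can share a node universe.
#'
#' @param graph An `igraph` with vertex names.
#' @param measured_genes Character vector of gene/protein identifiers.
#' @return The induced `igraph` subgraph.
#' @export
restrict_to_expression <- function(graph, measured_genes) {
  if (!igraph::is_igraph(graph)) stop("graph must be an igraph object", call. = FALSE)
  graph <- ensure_named(graph)
  keep <- intersect(igraph::V(graph)$name, measured_genes)
  igraph::induced_subgraph(graph, keep)
}
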