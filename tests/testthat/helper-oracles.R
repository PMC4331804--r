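# Independent oracles, deliberately naive: hand-coded Gaussian elimination
# for least squares, BFS path enumeration for betweenness/closeness, a
# truncated Taylor series for the matrix exponential, and direct
# induced-subgraph / common-neighbour counting for LAC, ECC and NC.

# least squares via the normal equations, solved by Gaussian elimination
# with partial pivoting (no qr(), no solve()).
oracle_ols <- function(X, Y) {
  A <- t(X) %*% X
  b <- drop(t(X) %*% Y)
  n <- nrow(A)
  M <- cbind(A, b)
  for (col in seq_len(n)) {
    piv <- which.max(abs(M[col:n, col])) + col - 1L
    if (abs(M[piv, col]) < 1e-12) stop("singular system")
    if (piv != col) M[c(col, piv), ] <- M[c(piv, col), ]
    M[col, ] <- M[col, ] / M[col, col]
    for (r in seq_len(n)[-col]) M[r, ] <- M[r, ] - M[r, col] * M[col, ]
  }
  M[, n + 1L]
}

# BFS from source s over an adjacency list: distances and shortest-path counts
oracle_bfs <- function(adj, s) {
  n <- length(adj)
  dist <- rep(Inf, n)
  nsp <- numeric(n)
  dist[s] <- 0
  nsp[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        nxt <- c(nxt, w)
        nsp[w] <- nsp[w] + nsp[v]
      } else if (dist[w] == dist[v] + 1) {
        nsp[w] <- nsp[w] + nsp[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, nsp = nsp)
}

graph_adjlist <- function(g) {
  lapply(igraph::as_adj_list(g), as.integer)
}

# ordered-pair betweenness by explicit enumeration over (s, t, v)
oracle_betweenness <- function(g) {
  n <- igraph::vcount(g)
  adj <- graph_adjlist(g)
  bfs <- lapply(seq_len(n), function(s) oracle_bfs(adj, s))
  bc <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    if (is.infinite(bfs[[s]]$dist[t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      on_path <- bfs[[s]]$dist[v] + bfs[[t]]$dist[v] == bfs[[s]]$dist[t]
      if (on_path)
        bc[v] <- bc[v] + bfs[[s]]$nsp[v] * bfs[[t]]$nsp[v] / bfs[[s]]$nsp[t]
    }
  }
  stats::setNames(bc, igraph::V(g)$name)
}

oracle_closeness <- function(g) {
  n <- igraph::vcount(g)
  adj <- graph_adjlist(g)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    d <- oracle_bfs(adj, v)$dist
    reach <- which(is.finite(d) & seq_len(n) != v)
    cc[v] <- if (length(reach)) length(reach) / sum(d[reach]) else 0
  }
  stats::setNames(cc, igraph::V(g)$name)
}

# diagonal of exp(A) by a truncated Taylor series
oracle_expm_diag <- function(A, terms = 50L) {
  n <- nrow(A)
  acc <- diag(n)
  term <- diag(n)
  for (k in seq_len(terms)) {
    term <- term %*% A / k
    acc <- acc + term
  }
  diag(acc)
}

oracle_lac <- function(g) {
  n <- igraph::vcount(g)
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- as.integer(igraph::neighbors(g, v))
    if (!length(nb)) next
    sub <- igraph::induced_subgraph(g, nb)
    out[v] <- sum(igraph::degree(sub)) / length(nb)
  }
  stats::setNames(out, igraph::V(g)$name)
}

oracle_nc <- function(g) {
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  adj <- lapply(seq_len(n), function(v) as.integer(igraph::neighbors(g, v)))
  out <- numeric(n)
  el <- igraph::as_edgelist(g, names = FALSE)
  for (i in seq_len(nrow(el))) {
    u <- el[i, 1L]; v <- el[i, 2L]
    z <- length(intersect(adj[[u]], adj[[v]]))
    den <- min(deg[u], deg[v]) - 1
    ecc <- if (den <= 0) 0 else z / den
    out[u] <- out[u] + ecc
    out[v] <- out[v] + ecc
  }
  stats::setNames(out, igraph::V(g)$name)
}

# small random named graph
random_small_graph <- function(n = NULL, p = NULL) {
  if (is.null(n)) n <- sample(3:12, 1)
  if (is.null(p)) p <- stats::runif(1, 0.15, 0.7)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

named_graph <- function(edges, isolated = character()) {
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  if (length(isolated)) g <- igraph::add_vertices(g, length(isolated),
                                                  name = isolated)
  g
}
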