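# Active-network construction from co-activity, and its invariants.

# build an activity_matrix object directly from a logical gene x time matrix
as_activity <- function(flags) {
  expr <- ifelse(flags, 1, -1) # any values strictly above/below threshold 0
  m <- matrix(as.numeric(expr), nrow(flags), ncol(flags),
              dimnames = dimnames(flags))
  structure(list(active = flags, threshold = stats::setNames(
    rep(0, nrow(flags)), rownames(flags)),
    mean = rowMeans(m), sd = rep(1, nrow(flags)),
    damping = rep(0.5, nrow(flags)), k = 2.5),
    class = "activity_matrix")
}

edge_keys <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0) return(character())
  paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
}

test_that("an edge is active exactly when both endpoints are active", {
  g <- named_graph(c("A", "B", "B", "C"))
  flags <- rbind(A = c(TRUE, FALSE), B = c(TRUE, TRUE), C = c(FALSE, TRUE))
  net <- build_active_network(g, as_activity(flags))
  expect_equal(net$timepoints, 2)
  el <- igraph::as_edgelist(g, names = TRUE)
  expect_equal(unname(el[net$per_time[[1]], ]), c("A", "B"))
  expect_equal(unname(el[net$per_time[[2]], ]), c("B", "C"))
  expect_setequal(edge_keys(net$union_graph), c("A B", "B C"))
  expect_setequal(igraph::V(net$union_graph)$name, c("A", "B", "C"))
  tab <- active_edges(net)
  expect_equal(tab$t, c(1L, 2L))
})

test_that("no activity gives an empty network; missing genes are inactive", {
  g <- named_graph(c("A", "B", "B", "C"))
  flags <- rbind(A = c(FALSE, FALSE), B = c(FALSE, FALSE), C = c(FALSE, FALSE))
  net <- build_active_network(g, as_activity(flags))
  expect_true(all(lengths(net$per_time) == 0))
  expect_equal(igraph::ecount(net$union_graph), 0)

  # B has no expression row: the A-B edge never activates
  flags2 <- rbind(A = c(TRUE, TRUE), C = c(TRUE, TRUE))
  net2 <- build_active_network(g, as_activity(flags2))
  expect_equal(igraph::ecount(net2$union_graph), 0)

  expect_error(build_active_network(igraph::make_empty_graph(0),
                                    as_activity(flags)), "empty")
})

test_that("a planted co-active module is recovered exactly", {
  set.seed(29)
  g <- igraph::sample_gnm(50, 120)
  igraph::V(g)$name <- sprintf("P%02d", 1:50)
  module <- sprintf("P%02d", 1:10)
  flags <- matrix(FALSE, 50, 8, dimnames = list(igraph::V(g)$name, NULL))
  flags[module, 5] <- TRUE
  net <- build_active_network(g, as_activity(flags))
  expected <- igraph::induced_subgraph(g, module)
  expect_setequal(edge_keys(net$union_graph), edge_keys(expected))
})

test_that("containment, monotonicity and edge-order invariance hold", {
  set.seed(37)
  for (i in 1:25) {
    g <- random_small_graph(n = sample(6:15, 1))
    n <- igraph::vcount(g)
    M <- 5
    flags <- matrix(runif(n * M) < 0.4, n, M,
                    dimnames = list(igraph::V(g)$name, NULL))
    net <- build_active_network(g, as_activity(flags))
    static_keys <- edge_keys(g)
    union_keys <- edge_keys(net$union_graph)
    expect_true(all(union_keys %in% static_keys))
    el <- igraph::as_edgelist(g, names = TRUE)
    for (t in 1:M) {
      idx <- net$per_time[[t]]
      if (length(idx))
        expect_true(all(paste(pmin(el[idx, 1], el[idx, 2]),
                              pmax(el[idx, 1], el[idx, 2])) %in% union_keys))
    }

    # adding activity never removes active edges
    flags2 <- flags
    flags2[sample(length(flags2), 5)] <- TRUE
    net2 <- build_active_network(g, as_activity(flags2))
    for (t in 1:M)
      expect_true(all(net$per_time[[t]] %in% net2$per_time[[t]]))

    # permuting the static edge list leaves the result unchanged
    perm <- sample(igraph::ecount(g))
    g_perm <- igraph::graph_from_edgelist(
      igraph::as_edgelist(g, names = TRUE)[perm, , drop = FALSE],
      directed = FALSE)
    net3 <- build_active_network(g_perm, as_activity(flags))
    expect_setequal(edge_keys(net3$union_graph), union_keys)
  }
})

test_that("restriction to measured genes induces the right subgraph", {
  star <- named_graph(c("C", "L1", "C", "L2", "C", "L3", "C", "L4"))
  expect_equal(igraph::ecount(restrict_to_expression(
    star, c("C", "L1", "L2", "L3", "L4"))), 4)
  expect_equal(igraph::vcount(restrict_to_expression(star, character())), 0)
  r <- restrict_to_expression(star, c("C", "L1", "L3"))
  expect_setequal(edge_keys(r), c("C L1", "C L3"))
})

test_that("per-time subgraph accessor returns the right slice", {
  g <- named_graph(c("A", "B", "B", "C"))
  flags <- rbind(A = c(TRUE, FALSE), B = c(TRUE, TRUE), C = c(FALSE, TRUE))
  net <- build_active_network(g, as_activity(flags))
  expect_setequal(edge_keys(per_time_graph(net, 1)), "A B")
  expect_setequal(edge_keys(per_time_graph(net, 2)), "B C")
  expect_error(per_time_graph(net, 3), "out of range")
})
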