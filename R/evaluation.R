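# Ranking evaluation against a reference essential-protein list: top-k
# counts, jackknife cumulative curves with (normalized) AUC, and pairwise
# overlap decomposition between two rankings.

ranking_nodes <- function(ranking) {
  if (is.data.frame(ranking)) {
    if (!"node" %in% names(ranking))
      stop("ranking data frame must have a 'node' column", call. = FALSE)
    as.character(ranking$node)
  } else {
    as.character(ranking)
  }
}

#' True-essential counts among the top-k ranked proteins
#'
#' @param ranking A ranking: either the data frame returned by
#'   [rank_nodes()] or a character vector of identifiers in rank order.
#' @param essential Character vector of known essential identifiers.
#' @param ks Integer vector of cutoffs, each at most the ranking length.
#' @return Named integer vector, one count per cutoff.
#' @export
top_k_counts <- function(ranking, essential, ks) {
  nodes <- ranking_nodes(ranking)
  if (any(ks < 1) || any(ks != round(ks)))
    stop("cutoffs must be positive integers", call. = FALSE)
  if (any(ks > length(nodes)))
    stop(sprintf("invalid cutoff: k = %d exceeds ranking length %d",
                 max(ks), length(nodes)), call. = FALSE)
  essential <- unique(as.character(essential))
  stats::setNames(vapply(as.integer(ks), function(k)
    sum(nodes[seq_len(k)] %in% essential), integer(1)), ks)
}

#' Jackknife cumulative curve and area under it
#'
#' Walks the ranking from the top and accumulates the count of true
#' essentials, giving points `(i, y_i)` for `i = 0, ..., n`. The area under
#' the curve is computed by the trapezoidal rule over the full ranking;
#' `auc_normalized` divides by the AUC of the ideal ranking (all true
#' essentials first) on the same node set, giving a value in `[0, 1]`.
#'
#' @inheritParams top_k_counts
#' @return An object of class `"jackknife_curve"`: a list with `x` (0..n),
#'   `y`, `auc` and `auc_normalized`.
#' @export
jackknife <- function(ranking, essential) {
  nodes <- ranking_nodes(ranking)
  if (!length(nodes)) stop("ranking must be nonempty", call. = FALSE)
  hit <- as.integer(nodes %in% unique(as.character(essential)))
  y <- c(0L, cumsum(hit))
  n <- length(nodes)
  trap <- function(yy) sum((yy[-1] + yy[-length(yy)]) / 2)
  auc <- trap(y)
  auc_ideal <- trap(c(0L, cumsum(sort(hit, decreasing = TRUE))))
  structure(
    list(x = 0:n, y = y, auc = auc,
         auc_normalized = if (auc_ideal > 0) auc / auc_ideal else 0),
    class = "jackknife_curve")
}

#' @export
print.jackknife_curve <- function(x, ...) {
  cat(sprintf("jackknife curve over %d proteins: %d essentials recovered; AUC %.6g (normalized %.4f)\n",
              length(x$x) - 1L, x$y[length(x$y)], x$auc, x$auc_normalized))
  invisible(x)
}

#' Plot a jackknife curve
#'
#' @param x A `"jackknife_curve"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.jackknife_curve <- function(x, ...) {
  graphics::plot(x$x, x$y, type = "s",
                 xlab = "top-ranked proteins considered",
                 ylab = "cumulative true essentials", ...)
  invisible(x)
}

#' Overlap decomposition of two rankings' top-k essential sets
#'
#' Reports `S1` and `S2`, the numbers of true essentials in the top-k of each
#' ranking, `S3`, the size of the intersection of the two top-k
#' true-essential sets, and the unique counts `S1 - S3` and `S2 - S3`.
#'
#' @param rank_a,rank_b Two rankings (see [top_k_counts()]).
#' @inheritParams top_k_counts
#' @param k Single cutoff, at most the length of either ranking.
#' @return A list with `k`, `S1`, `S2`, `S3`, `S1_only`, `S2_only`.
#' @export
overlap_report <- function(rank_a, rank_b, essential, k) {
  a <- ranking_nodes(rank_a)
  b <- ranking_nodes(rank_b)
  if (k < 1 || k > length(a) || k > length(b))
    stop("invalid cutoff k for these rankings", call. = FALSE)
  essential <- unique(as.character(essential))
  ea <- intersect(a[seq_len(k)], essential)
  eb <- intersect(b[seq_len(k)], essential)
  s3 <- length(intersect(ea, eb))
  list(k = as.integer(k), S1 = length(ea), S2 = length(eb), S3 = s3,
       S1_only = length(ea) - s3, S2_only = length(eb) - s3)
}

#' Compare centrality rankings on the static and active networks
#'
#' For each measure, ranks proteins on the static network ("PPIN") and on the
#' active union graph ("APPIN"), then reports top-k essential counts,
#' jackknife AUCs, and the overlap decomposition at each cutoff. By default
#' both rankings share the static node universe: proteins absent from the
#' active network are appended with score `-Inf` (tied, broken
#' lexicographically), so counts are comparable; `include_unranked = FALSE`
#' restricts each ranking to its own graph's nodes instead.
#'
#' @param static Static PPI network (`igraph`).
#' @param active An `"active_network"` (or an `igraph` used directly as the
#'   active graph).
#' @param essential Character vector of known essential identifiers; it is
#'   deduplicated and intersected with the static node universe.
#' @param measures Subset of `c("DC","BC","CC","SC","LAC","NC")`.
#' @param ks Integer cutoffs.
#' @param include_unranked Keep a common node universe (default) or rank only
#'   each graph's own nodes.
#' @return An object of class `"network_comparison"`: a list of data frames
#'   `counts` (measure, network, k, count), `auc` (measure, network, auc,
#'   auc_normalized) and `overlaps` (measure, k, S1, S2, S3, S1_only,
#'   S2_only).
#' @export
compare_networks <- function(static, active, essential,
                             measures = centrality_measures,
                             ks, include_unranked = TRUE) {
  if (!igraph::is_igraph(static)) stop("static must be an igraph", call. = FALSE)
  static <- ensure_named(static)
  g_active <- if (inherits(active, "active_network")) active$union_graph else active
  if (!igraph::is_igraph(g_active))
    stop("active must be an active_network or an igraph", call. = FALSE)
  g_active <- ensure_named(g_active)
  measures <- match.arg(measures, centrality_measures, several.ok = TRUE)
  universe <- igraph::V(static)$name
  essential <- intersect(unique(as.character(essential)), universe)
  if (!length(essential)) stop("no essential protein occurs in the network",
                               call. = FALSE)
  counts <- auc <- overlaps <- list()
  for (m in measures) {
    r_static <- rank_nodes(centrality_scores(static, m))
    sa <- centrality_scores(g_active, m)
    if (include_unranked) {
      full <- stats::setNames(rep(-Inf, length(universe)), universe)
      full[names(sa)] <- sa
      r_active <- rank_nodes(full)
    } else {
      r_active <- rank_nodes(sa)
    }
    ka <- ks[ks <= nrow(r_static)]
    kb <- ks[ks <= nrow(r_active)]
    kc <- intersect(ka, kb)
    count_frame <- function(network, ranking, kk) {
      if (!length(kk))
        return(data.frame(measure = character(), network = character(),
                          k = integer(), count = integer()))
      data.frame(measure = m, network = network, k = kk,
                 count = as.integer(top_k_counts(ranking, essential, kk)))
    }
    counts[[m]] <- rbind(count_frame("PPIN", r_static, ka),
                         count_frame("APPIN", r_active, kb))
    ja <- jackknife(r_static, essential)
    jb <- if (nrow(r_active)) jackknife(r_active, essential) else
      list(auc = 0, auc_normalized = 0)
    auc[[m]] <- data.frame(
      measure = m, network = c("PPIN", "APPIN"),
      auc = c(ja$auc, jb$auc),
      auc_normalized = c(ja$auc_normalized, jb$auc_normalized))
    overlaps[[m]] <- do.call(rbind, lapply(kc, function(k) {
      ov <- overlap_report(r_static, r_active, essential, k)
      data.frame(measure = m, k = k, S1 = ov$S1, S2 = ov$S2, S3 = ov$S3,
                 S1_only = ov$S1_only, S2_only = ov$S2_only)
    }))
  }
  structure(
    list(counts = do.call(rbind, c(counts, list(make.row.names = FALSE))),
         auc = do.call(rbind, c(auc, list(make.row.names = FALSE))),
         overlaps = do.call(rbind, c(overlaps, list(make.row.names = FALSE)))),
    class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat("network comparison (PPIN vs APPIN)\n\ntop-k true-essential counts:\n")
  print(x$counts, row.names = FALSE)
  cat("\njackknife AUC:\n")
  print(x$auc, row.names = FALSE)
  invisible(x)
}
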