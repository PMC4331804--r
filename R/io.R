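# Tab-delimited I/O for the three standard inputs (edge list, expression
# matrix, protein list) and the end-to-end pipeline driver. Tab is the only
# field separator; identifiers are opaque strings.

content_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a static PPI network from a two-column edge list
#'
#' Tab-delimited text with at least two columns (extra columns ignored);
#' lines starting with `#` are comments. Self-interactions and duplicate
#' (order-insensitive) edges are dropped, with counts reported via
#' [message()].
#'
#' @param path File path.
#' @return A simple undirected `igraph` with vertex names.
#' @export
read_edge_list <- function(path) {
  cl <- content_lines(path)
  if (!length(cl$lines)) stop("empty network", call. = FALSE)
  f <- strsplit(cl$lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 2L))
    stop(sprintf("malformed edge line %d: fewer than 2 tab-separated fields",
                 cl$lineno[which(nf < 2L)[1L]]), call. = FALSE)
  a <- vapply(f, `[`, "", 1L)
  b <- vapply(f, `[`, "", 2L)
  self <- a == b
  key <- paste(pmin(a, b), pmax(a, b), sep = "\t")
  dup <- duplicated(key) & !self
  keep <- !self & !dup
  if (any(self)) message(sprintf("dropped %d self-interaction(s)", sum(self)))
  if (any(dup)) message(sprintf("dropped %d duplicate edge(s)", sum(dup)))
  if (!any(keep)) stop("empty network: no valid edges remain", call. = FALSE)
  igraph::graph_from_edgelist(cbind(a[keep], b[keep]), directed = FALSE)
}

#' Write an edge list
#'
#' @param graph An `igraph` with vertex names.
#' @param path File path.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(ensure_named(graph), names = TRUE)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an expression matrix
#'
#' Tab-delimited text: first column gene identifier, remaining `M` numeric
#' columns, optional header. Rows with missing or non-numeric expression
#' cells are dropped with a warning; for duplicated gene identifiers the
#' first row is kept with a warning.
#'
#' @param path File path.
#' @param header `"auto"` (default: header assumed when any non-identifier
#'   field of the first line is non-numeric), `TRUE` or `FALSE`.
#' @return Numeric matrix with gene identifiers as rownames.
#' @export
read_expression <- function(path, header = "auto") {
  cl <- content_lines(path)
  if (!length(cl$lines)) stop("empty expression file", call. = FALSE)
  f <- strsplit(cl$lines, "\t", fixed = TRUE)
  has_header <- if (identical(header, "auto")) {
    any(is.na(suppressWarnings(as.numeric(f[[1L]][-1L]))))
  } else isTRUE(header)
  if (has_header) {
    f <- f[-1L]
    cl$lineno <- cl$lineno[-1L]
    if (!length(f)) stop("empty expression file (header only)", call. = FALSE)
  }
  nf <- lengths(f)
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("inconsistent column count at line %d (%d fields, expected %d)",
                 cl$lineno[bad], nf[bad], nf[1L]), call. = FALSE)
  }
  if (nf[1L] < 2L) stop("expression rows need an identifier plus at least one value",
                        call. = FALSE)
  ids <- vapply(f, `[`, "", 1L)
  vals <- t(vapply(f, function(r) suppressWarnings(as.numeric(r[-1L])),
                   numeric(nf[1L] - 1L)))
  ok <- apply(vals, 1L, function(r) all(is.finite(r)))
  if (!all(ok))
    warning(sprintf("dropped %d profile(s) with missing or non-numeric values",
                    sum(!ok)))
  ids <- ids[ok]
  vals <- vals[ok, , drop = FALSE]
  dup <- duplicated(ids)
  if (any(dup)) {
    warning(sprintf("%d duplicated gene identifier(s); keeping first occurrence",
                    sum(dup)))
    ids <- ids[!dup]
    vals <- vals[!dup, , drop = FALSE]
  }
  rownames(vals) <- ids
  vals
}

#' Write an expression matrix
#'
#' @param expr Numeric matrix with gene rownames.
#' @param path File path.
#' @export
write_expression <- function(expr, path) {
  out <- cbind(gene = rownames(expr),
               as.data.frame(expr, stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a protein identifier list
#'
#' One identifier per line; blank lines ignored; duplicates removed.
#'
#' @param path File path.
#' @return Character vector of unique identifiers.
#' @export
read_protein_list <- function(path) {
  cl <- content_lines(path)
  ids <- unique(trimws(cl$lines))
  ids <- ids[nzchar(ids)]
  if (!length(ids)) stop("empty protein list", call. = FALSE)
  ids
}

#' Write a protein identifier list
#'
#' @param ids Character vector.
#' @param path File path.
#' @export
write_protein_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes, end to end: time-dependence calls, noise filtering, active
#' thresholds and activity flags, active-network construction, centrality
#' scoring on both the static and the active union network, and the
#' evaluation protocol against the essential list. Per-stage record counts
#' are logged to standard error and each stage's artifact is written to
#' `out_dir`:
#' `dependence_calls.tsv`, `activity.tsv` (gene, threshold, then one 0/1
#' column per time point), `active_edges.tsv` (u, v, t), `scores.tsv`
#' (network, measure, protein, score, rank), `evaluation_counts.tsv`,
#' `evaluation_auc.tsv`, `evaluation_overlaps.tsv`, `evaluation.json`, and
#' `config.json` (the resolved configuration, for provenance). All outputs
#' are deterministic functions of the inputs and configuration.
#'
#' @param network Path to an edge list, or an `igraph`.
#' @param expression Path to an expression file, or a numeric matrix with
#'   gene rownames.
#' @param essential Path to a protein list, or a character vector.
#' @param out_dir Output directory (created if missing).
#' @param alpha Significance threshold of the time-dependence call, in (0, 1).
#' @param k Active-threshold coefficient in `[0, 3]`.
#' @param mean_floor,floor_quantile Noise floor (see [filter_noise()]).
#' @param correction Multiple-testing correction across AR orders
#'   (`"none"` or `"bonferroni"`).
#' @param measures Centrality measures to run.
#' @param ks Top-k cutoffs; `NULL` picks `c(100, 200, 300, 400, 500)`
#'   truncated to the network size, falling back to five evenly spaced
#'   cutoffs for small networks.
#' @param log2_transform Apply `log2(x + 1)` to expression values first.
#' @param uppercase_ids Uppercase all identifiers before matching.
#' @param restrict_static Restrict the static network to measured genes
#'   before comparison, so both networks share a node universe drawn from
#'   genes with expression data.
#' @param include_unranked See [compare_networks()].
#' @return Invisibly, a list with the in-memory stage results (`calls`,
#'   `filter`, `activity`, `network`, `comparison`) and `paths` of the
#'   written files.
#' @export
run_pipeline <- function(network, expression, essential, out_dir,
                         alpha = 0.01, k = 2.5,
                         mean_floor = NULL, floor_quantile = 0.2,
                         correction = "none",
                         measures = centrality_measures, ks = NULL,
                         log2_transform = FALSE, uppercase_ids = FALSE,
                         restrict_static = FALSE, include_unranked = TRUE) {
  # validate configuration before touching any input
  if (!is.numeric(alpha) || length(alpha) != 1L || !(alpha > 0 && alpha < 1))
    stop("config error: alpha must lie in (0, 1)", call. = FALSE)
  check_k(k)
  if (!is.null(mean_floor) && (!is.numeric(mean_floor) || length(mean_floor) != 1L))
    stop("config error: mean_floor must be a single number or NULL", call. = FALSE)
  if (!(floor_quantile >= 0 && floor_quantile <= 1))
    stop("config error: floor_quantile must lie in [0, 1]", call. = FALSE)
  measures <- match.arg(measures, centrality_measures, several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  g <- if (igraph::is_igraph(network)) ensure_named(network) else read_edge_list(network)
  expr <- if (is.matrix(expression)) expression else read_expression(expression)
  ess <- if (is.character(essential) && length(essential) > 1L ||
             (is.character(essential) && !file.exists(essential)))
    unique(essential) else read_protein_list(essential)
  if (uppercase_ids) {
    igraph::V(g)$name <- toupper(igraph::V(g)$name)
    rownames(expr) <- toupper(rownames(expr))
    ess <- unique(toupper(ess))
  }
  if (log2_transform) expr <- log2(expr + 1)
  message(sprintf("inputs: %d proteins / %d interactions; %d expression profiles (%d time points); %d essential identifiers",
                  igraph::vcount(g), igraph::ecount(g), nrow(expr), ncol(expr),
                  length(ess)))
  if (restrict_static) {
    g <- restrict_to_expression(g, rownames(expr))
    message(sprintf("static network restricted to measured genes: %d proteins / %d interactions",
                    igraph::vcount(g), igraph::ecount(g)))
  }

  calls <- call_dependence_all(expr, alpha = alpha, correction = correction)
  expr <- expr[calls$gene, , drop = FALSE] # rows that survived finiteness checks
  message(sprintf("time-dependence: %d of %d genes called time-dependent (alpha = %g)",
                  sum(calls$time_dependent), nrow(calls), alpha))

  flt <- filter_noise(expr, calls, mean_floor, floor_quantile)
  message(sprintf("noise filter: removed %d gene(s) below mean floor %.4g; %d retained",
                  length(flt$removed), flt$mean_floor, length(flt$retained)))

  act <- activity_matrix(expr[flt$retained, , drop = FALSE], k = k)
  message(sprintf("activity: %d active flags over %d genes x %d time points (k = %g)",
                  sum(act$active), nrow(act$active), ncol(act$active), k))

  net <- build_active_network(g, act)
  message(sprintf("active network: %d nodes / %d edges in the union graph",
                  igraph::vcount(net$union_graph), igraph::ecount(net$union_graph)))

  n_universe <- igraph::vcount(g)
  if (is.null(ks)) {
    ks <- c(100L, 200L, 300L, 400L, 500L)
    ks <- ks[ks <= n_universe]
    if (!length(ks))
      ks <- unique(pmax(1L, round(n_universe * c(0.1, 0.2, 0.3, 0.4, 0.5))))
  }
  cmp <- compare_networks(g, net, ess, measures, ks, include_unranked)

  # per-measure score tables on both networks
  score_rows <- lapply(measures, function(m) {
    rbind(score_frame("PPIN", m, centrality_scores(g, m)),
          score_frame("APPIN", m, centrality_scores(net$union_graph, m)))
  })
  scores <- do.call(rbind, score_rows)

  paths <- c(
    dependence_calls = write_tsv(calls, file.path(out_dir, "dependence_calls.tsv")),
    activity = write_activity(act, file.path(out_dir, "activity.tsv")),
    active_edges = write_tsv(active_edges(net), file.path(out_dir, "active_edges.tsv")),
    scores = write_tsv(scores, file.path(out_dir, "scores.tsv")),
    evaluation_counts = write_tsv(cmp$counts, file.path(out_dir, "evaluation_counts.tsv")),
    evaluation_auc = write_tsv(cmp$auc, file.path(out_dir, "evaluation_auc.tsv")),
    evaluation_overlaps = write_tsv(cmp$overlaps, file.path(out_dir, "evaluation_overlaps.tsv")),
    evaluation = local({
      p <- file.path(out_dir, "evaluation.json")
      jsonlite::write_json(list(counts = cmp$counts, auc = cmp$auc,
                                overlaps = cmp$overlaps),
                           p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      p
    }),
    config = local({
      p <- file.path(out_dir, "config.json")
      jsonlite::write_json(
        list(alpha = alpha, k = k, mean_floor = flt$mean_floor,
             floor_quantile = floor_quantile, correction = correction,
             measures = measures, ks = ks, log2_transform = log2_transform,
             uppercase_ids = uppercase_ids, restrict_static = restrict_static,
             include_unranked = include_unranked),
        p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      p
    }))
  message(sprintf("wrote %d report files to %s", length(paths), out_dir))
  invisible(list(calls = calls, filter = flt, activity = act, network = net,
                 comparison = cmp, paths = paths))
}

score_frame <- function(network, measure, scores) {
  r <- rank_nodes(scores)
  if (nrow(r) == 0L)
    return(data.frame(network = character(), measure = character(),
                      protein = character(), score = numeric(),
                      rank = integer(), stringsAsFactors = FALSE))
  data.frame(network = network, measure = measure, protein = r$node,
             score = r$score, rank = seq_len(nrow(r)),
             stringsAsFactors = FALSE)
}

write_activity <- function(act, path) {
  m <- ncol(act$active)
  out <- data.frame(gene = rownames(act$active),
                    threshold = unname(act$threshold),
                    stringsAsFactors = FALSE)
  flags <- matrix(as.integer(act$active), nrow(act$active), m)
  colnames(flags) <- paste0("t", seq_len(m))
  write_tsv(cbind(out, flags), path)
}
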