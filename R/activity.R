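# Noise filtering and per-gene active thresholds.
#
# Each retained gene gets an active threshold u + k*sigma*(1 - F) with damping
# F = 1/(1 + sigma^2): for quiet genes (small sigma) the threshold collapses
# towards the mean, for volatile genes it approaches the classical k-sigma
# rule. A protein is "active" at a time point when its expression strictly
# exceeds its threshold.

#' Per-gene active threshold
#'
#' Computes the mean `u`, the population standard deviation `sigma` (divisor
#' `M`), the damping factor `F = 1 / (1 + sigma^2)` and the active threshold
#' `u + k * sigma * (1 - F)` of an expression series.
#'
#' @param x Numeric vector of expression values (nonempty, finite).
#' @param k Threshold coefficient in `[0, 3]`; default 2.5.
#' @return A list with `mean`, `sd`, `damping` and `threshold`.
#' @examples
#' active_threshold(c(1, 2, 3, 10), k = 2.5)
#' @export
active_threshold <- function(x, k = 2.5) {
  if (!is.numeric(x) || length(x) == 0L || !all(is.finite(x)))
    stop("x must be a nonempty finite numeric vector", call. = FALSE)
  check_k(k)
  u <- mean(x)
  sigma <- sqrt(mean((x - u)^2))
  damping <- 1 / (1 + sigma^2)
  list(mean = u, sd = sigma, damping = damping,
       threshold = u + k * sigma * (1 - damping))
}

check_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0 || k > 3)
    stop("k must be a single value in [0, 3]", call. = FALSE)
  invisible(k)
}

#' Remove noise genes
#'
#' A gene is considered noise -- and removed -- exactly when it is
#' time-independent AND its mean expression lies below `mean_floor`. Genes
#' that are time-dependent, or time-independent but reasonably expressed, are
#' retained. When `mean_floor` is `NULL` it defaults to the
#' `floor_quantile` quantile (default the 20th percentile) of all gene means,
#' recomputed for each dataset.
#'
#' @param expr Numeric matrix, genes in rows with rownames.
#' @param calls Data frame from [call_dependence_all()] covering every row of
#'   `expr` (a gene present in `expr` but absent from `calls` is an error).
#' @param mean_floor Absolute expression floor, or `NULL` for the quantile
#'   default.
#' @param floor_quantile Quantile of gene means used when `mean_floor` is
#'   `NULL`.
#' @return A list with `retained` and `removed` (character vectors of gene
#'   ids) and the resolved `mean_floor`.
#' @export
filter_noise <- function(expr, calls, mean_floor = NULL, floor_quantile = 0.2) {
  if (!is.matrix(expr) || is.null(rownames(expr)))
    stop("expr must be a matrix with gene rownames", call. = FALSE)
  missing <- setdiff(rownames(expr), calls$gene)
  if (length(missing))
    stop(sprintf("inconsistent inputs: %d gene(s) in the expression matrix have no dependence call (e.g. %s)",
                 length(missing), missing[1L]), call. = FALSE)
  means <- rowMeans(expr)
  if (is.null(mean_floor))
    mean_floor <- stats::quantile(means, floor_quantile, names = FALSE)
  td <- calls$time_dependent[match(rownames(expr), calls$gene)]
  noise <- !td & means < mean_floor
  list(retained = rownames(expr)[!noise],
       removed = rownames(expr)[noise],
       mean_floor = mean_floor)
}

#' Gene-by-time-point activity matrix
#'
#' Flags each gene as active at each time point where its expression strictly
#' exceeds its active threshold (ties at the threshold are inactive; in
#' particular a constant series is never active).
#'
#' @param expr Numeric matrix of noise-filtered genes (rows, with rownames)
#'   by time points (columns).
#' @inheritParams active_threshold
#' @return An object of class `"activity_matrix"`: a list with `active`
#'   (logical genes x time matrix), `threshold`, `mean`, `sd`, `damping`
#'   (named numeric vectors) and `k`.
#' @export
activity_matrix <- function(expr, k = 2.5) {
  if (!is.matrix(expr) || !is.numeric(expr) || is.null(rownames(expr)))
    stop("expr must be a numeric matrix with gene rownames", call. = FALSE)
  if (!all(is.finite(expr)))
    stop("expr contains non-finite values; drop or impute before thresholding",
         call. = FALSE)
  check_k(k)
  u <- rowMeans(expr)
  sigma <- sqrt(rowMeans((expr - u)^2))
  damping <- 1 / (1 + sigma^2)
  thr <- u + k * sigma * (1 - damping)
  active <- expr > thr
  structure(
    list(active = active, threshold = thr, mean = u, sd = sigma,
         damping = damping, k = k),
    class = "activity_matrix")
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("activity matrix: %d genes x %d time points (k = %g); %d active flags\n",
              nrow(x$active), ncol(x$active), x$k, sum(x$active)))
  invisible(x)
}
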