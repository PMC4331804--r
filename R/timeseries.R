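# Time-dependence test for dynamic expression profiles.
#
# A profile x = (x_1, ..., x_M) at equally spaced time points is either
# "time-dependent" -- well described by an autoregressive model of some order
# p >= 1 -- or "time-independent" -- constant plus i.i.d. Gaussian noise.
# Both models are fitted by maximum likelihood over the shared response span
# m = p+1, ..., M, and compared with a likelihood-ratio test whose statistic
# has an exact F(p, M - 2p - 1) null distribution.

check_series <- function(x) {
  if (!is.numeric(x) || length(x) < 4L)
    stop("series must be a numeric vector of length >= 4", call. = FALSE)
  if (!all(is.finite(x)))
    stop("series contains non-finite values", call. = FALSE)
  invisible(as.numeric(x))
}

check_order <- function(p, M) {
  if (length(p) != 1L || !is.numeric(p) || !is.finite(p) || p != round(p))
    stop("order p must be a single integer", call. = FALSE)
  p <- as.integer(p)
  if (p < 1L || p > (M - 1) / 2)
    stop(sprintf("invalid order: p = %d outside admissible range 1 <= p <= (M-1)/2 with M = %d",
                 p, M), call. = FALSE)
  p
}

rank_deficient <- function(p) {
  structure(
    class = c("apinet_rank_deficient", "error", "condition"),
    list(message = sprintf("design matrix is rank-deficient at order p = %d; order inadmissible for this series", p),
         call = NULL))
}

#' Response vector and design matrix for the autoregressive model
#'
#' Builds the conditional least-squares design for an AR(p) fit of a series of
#' length `M`: row `r` of the response is `x[p + r]` and row `r` of the design
#' is `(1, x[r], x[r+1], ..., x[r+p-1])`, i.e. lag columns ordered oldest to
#' newest, for `r = 1, ..., M - p`.
#'
#' @param x Numeric vector of expression values at equally spaced time points
#'   (length `M >= 4`, all finite).
#' @param p Autoregressive order, an integer with `1 <= p <= (M-1)/2`.
#' @return A list with `Y` (length `M - p`) and `X` (an `(M-p) x (p+1)` matrix
#'   whose first column is the intercept).
#' @examples
#' ar_design(c(1, 2, 3, 4), p = 1)
#' @export
ar_design <- function(x, p) {
  x <- check_series(x)
  M <- length(x)
  p <- check_order(p, M)
  Y <- x[(p + 1L):M]
  X <- matrix(1, M - p, p + 1L)
  for (j in seq_len(p)) X[, j + 1L] <- x[j:(M - p + j - 1L)]
  list(Y = Y, X = X)
}

#' Conditional least-squares / maximum-likelihood fit of an AR(p) model
#'
#' Solves the normal equations for the design of [ar_design()] and returns the
#' coefficient vector (intercept first) together with the maximum-likelihood
#' residual variance, which divides the residual sum of squares by `M - p`
#' (the number of response observations, not a degrees-of-freedom-corrected
#' divisor).
#'
#' @inheritParams ar_design
#' @return An object of class `"ar_fit"`: a list with `order`, `coefficients`
#'   (length `p + 1`) and `residual_variance`.
#' @section Degenerate series: When the design matrix is rank-deficient (for
#'   example a constant series, whose lag columns coincide with the
#'   intercept), a condition of class `"apinet_rank_deficient"` is signalled;
#'   callers scanning several orders should skip that order.
#' @export
fit_ar <- function(x, p) {
  d <- ar_design(x, p)
  qrX <- qr(d$X)
  if (qrX$rank < ncol(d$X)) stop(rank_deficient(as.integer(p)))
  beta <- qr.coef(qrX, d$Y)
  res <- d$Y - drop(d$X %*% beta)
  structure(
    list(order = as.integer(p),
         coefficients = as.numeric(beta),
         residual_variance = sum(res^2) / length(d$Y)),
    class = "ar_fit")
}

#' Maximum-likelihood fit of the time-independent (constant) model
#'
#' Fits `x_m = b0 + e_m` over the same response span `m = p+1, ..., M` used by
#' the AR(p) fit it is compared against, so that both likelihoods condition on
#' the same `M - p` observations. The residual variance uses the
#' maximum-likelihood divisor `M - p`.
#'
#' @inheritParams ar_design
#' @return An object of class `"const_fit"`: a list with `mean`,
#'   `residual_variance` and `order_context` (the AR order fixing the span).
#' @export
fit_constant <- function(x, p) {
  x <- check_series(x)
  M <- length(x)
  p <- check_order(p, M)
  xs <- x[(p + 1L):M]
  m <- mean(xs)
  structure(
    list(mean = m,
         residual_variance = mean((xs - m)^2),
         order_context = p),
    class = "const_fit")
}

#' Likelihood ratio of the constant model to the AR model
#'
#' For fits sharing the response span, the ratio of maximized likelihoods
#' reduces to `(s2_ar / s2_const)^((M - p) / 2)`. Because the constant model
#' is nested in AR(p), the ratio always lies in `[0, 1]`.
#'
#' @param ar An `"ar_fit"` object.
#' @param const A `"const_fit"` object fitted at the same order.
#' @param M Series length.
#' @return The likelihood ratio, a number in `[0, 1]`.
#' @export
likelihood_ratio <- function(ar, const, M) {
  if (ar$order != const$order_context)
    stop("AR and constant fits must share the same order p", call. = FALSE)
  if (const$residual_variance <= 0)
    stop("degenerate constant series: constant-model residual variance is zero",
         call. = FALSE)
  (ar$residual_variance / const$residual_variance)^((M - ar$order) / 2)
}

# Relative floor below which an AR residual variance is treated as an exact
# zero (a perfect fit): guards against rounding noise in exactly recursive
# series such as x_m = 1 + x_{m-1}.
.perfect_fit_tol <- 1e-14

#' F statistic of the time-dependence likelihood-ratio test
#'
#' Computes `F = (M - 2p - 1) / p * (s2_const / s2_ar - 1)`, which under the
#' constant-model null follows an F distribution with `(p, M - 2p - 1)`
#' degrees of freedom, and its upper-tail p-value.
#'
#' Degenerate cases: a perfect AR fit (`s2_ar = 0`) gives `F = Inf`,
#' `pvalue = 0`; a degenerate constant series (`s2_const = 0`) gives
#' `F = 0`, `pvalue = 1` (a flat series carries no time information).
#'
#' @inheritParams ar_design
#' @return A list with `statistic`, `pvalue`, `order` and `df` (the two
#'   degrees of freedom).
#' @export
f_statistic <- function(x, p) {
  x <- check_series(x)
  M <- length(x)
  p <- check_order(p, M)
  df2 <- M - 2L * p - 1L
  if (df2 < 1L)
    stop(sprintf("invalid order: F test requires M - 2p - 1 >= 1 (M = %d, p = %d)", M, p),
         call. = FALSE)
  ar <- fit_ar(x, p) # may signal apinet_rank_deficient
  co <- fit_constant(x, p)
  s2 <- ar$residual_variance
  sc2 <- co$residual_variance
  if (sc2 <= 0)
    return(list(statistic = 0, pvalue = 1, order = p, df = c(p, df2)))
  if (s2 <= sc2 * .perfect_fit_tol)
    return(list(statistic = Inf, pvalue = 0, order = p, df = c(p, df2)))
  stat <- max(df2 / p * (sc2 / s2 - 1), 0)
  list(statistic = stat,
       pvalue = stats::pf(stat, p, df2, lower.tail = FALSE),
       order = p, df = c(p, df2))
}

#' Classify one expression series as time-dependent or time-independent
#'
#' Scans every admissible order `p` (integer `p` with `1 <= p <= (M-1)/2` and
#' `M - 2p - 1 >= 1`), computes the F-test p-value at each, and calls the
#' series time-dependent when the smallest p-value falls below `alpha`.
#' Orders whose design matrix is rank-deficient are skipped; if every order is
#' skipped (a fully degenerate series) the call is time-independent with
#' p-value 1. By default no multiple-testing correction is applied across
#' orders -- the decision rule is the literal minimum; `correction =
#' "bonferroni"` multiplies each p-value by the number of scanned orders for
#' users who want conservatism.
#'
#' @inheritParams ar_design
#' @param alpha Significance threshold in (0, 1); default 0.01.
#' @param correction `"none"` (default) or `"bonferroni"`.
#' @return An object of class `"dependence_call"`: a list with `per_order`
#'   (data frame of order, statistic, pvalue), `min_pvalue`, `best_order`,
#'   `time_dependent` and `alpha`.
#' @examples
#' call_dependence(sin(seq_len(36)))
#' @export
call_dependence <- function(x, alpha = 0.01, correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  x <- check_series(x)
  if (!is.numeric(alpha) || length(alpha) != 1L || !(alpha > 0 && alpha < 1))
    stop("alpha must be a single value in (0, 1)", call. = FALSE)
  M <- length(x)
  orders <- seq_len(floor((M - 1) / 2))
  orders <- orders[M - 2L * orders - 1L >= 1L]
  rows <- lapply(orders, function(p) {
    tryCatch({
      f <- f_statistic(x, p)
      data.frame(order = p, statistic = f$statistic, pvalue = f$pvalue)
    }, apinet_rank_deficient = function(e) NULL)
  })
  per_order <- do.call(rbind, rows)
  if (is.null(per_order) || nrow(per_order) == 0L) {
    return(structure(
      list(per_order = data.frame(order = integer(), statistic = numeric(),
                                  pvalue = numeric()),
           min_pvalue = 1, best_order = NA_integer_,
           time_dependent = FALSE, alpha = alpha),
      class = "dependence_call"))
  }
  pv <- per_order$pvalue
  if (correction == "bonferroni") pv <- pmin(1, pv * length(pv))
  i <- which.min(pv)
  structure(
    list(per_order = per_order,
         min_pvalue = pv[i],
         best_order = as.integer(per_order$order[i]),
         time_dependent = pv[i] < alpha,
         alpha = alpha),
    class = "dependence_call")
}

#' @export
print.dependence_call <- function(x, ...) {
  cat(sprintf("dependence call: %s (min p-value %.4g at order %s, alpha %g; %d orders scanned)\n",
              if (x$time_dependent) "time-dependent" else "time-independent",
              x$min_pvalue,
              ifelse(is.na(x$best_order), "NA", x$best_order),
              x$alpha, nrow(x$per_order)))
  invisible(x)
}

#' Time-dependence calls for every row of an expression matrix
#'
#' Applies [call_dependence()] to each gene (row). Rows containing missing or
#' non-finite values are dropped with a warning -- no imputation is attempted.
#'
#' @param expr Numeric matrix, genes in rows (rownames are gene identifiers),
#'   time points in columns.
#' @param alpha,correction Passed to [call_dependence()].
#' @return A data frame with one row per retained gene: `gene`, `best_order`,
#'   `statistic` (F at the best order), `min_pvalue`, `time_dependent`.
#' @export
call_dependence_all <- function(expr, alpha = 0.01,
                                correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expr must be a numeric matrix with genes in rows", call. = FALSE)
  if (is.null(rownames(expr)))
    stop("expr must have gene identifiers as rownames", call. = FALSE)
  ok <- apply(expr, 1L, function(r) all(is.finite(r)))
  if (!all(ok))
    warning(sprintf("dropping %d gene(s) with missing or non-finite expression values",
                    sum(!ok)))
  expr <- expr[ok, , drop = FALSE]
  calls <- lapply(seq_len(nrow(expr)), function(i) {
    dc <- call_dependence(expr[i, ], alpha = alpha, correction = correction)
    io <- match(dc$best_order, dc$per_order$order)
    data.frame(gene = rownames(expr)[i],
               best_order = dc$best_order,
               statistic = if (is.na(io)) NA_real_ else dc$per_order$statistic[io],
               min_pvalue = dc$min_pvalue,
               time_dependent = dc$time_dependent,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
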