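#' Covariance PCA of one MTS item
#'
#' Eigen-decomposes the sample covariance matrix of the item's columns and
#' projects the mean-centred data onto the eigenvectors, yielding the
#' principal-component series. Columns are centred before projection so that
#' the variance of the i-th projected series equals the i-th eigenvalue.
#' Eigenvector signs are fixed so that each column's largest-magnitude entry
#' is positive, giving deterministic component series across linear-algebra
#' backends (DTW distances are sign-sensitive).
#'
#' @param item An [mts_item()].
#' @return An object of class `mts_pca`: list with `eigenvectors` (`n x n`,
#'   unit columns), `eigenvalues` (length `n`, nonincreasing, nonnegative up to
#'   roundoff), `projected` (`m x n` principal-component series), `center`
#'   (column means), and `id`.
#' @examples
#' it <- mts_item(cbind(sin(1:50), cos(1:50), rnorm(50, sd = 0.1)), "ex")
#' pc <- fit_pca(it)
#' pc$eigenvalues
#' @export
fit_pca <- function(item) {
  if (!inherits(item, "mts_item")) stop("'item' must be an mts_item")
  X <- item$values
  S <- stats::cov(X)
  if (any(!is.finite(S))) stop(sprintf("item '%s': covariance is not finite", item$id))
  if (all(abs(S) < .Machine$double.eps * 100))
    stop(sprintf("item '%s': degenerate input, every column is constant", item$id))
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)          # clip tiny negative roundoff
  vecs <- e$vectors
  # deterministic sign: largest-magnitude entry of each eigenvector positive
  for (j in seq_len(ncol(vecs))) {
    piv <- which.max(abs(vecs[, j]))
    if (vecs[piv, j] < 0) vecs[, j] <- -vecs[, j]
  }
  ctr <- colMeans(X)
  proj <- sweep(X, 2L, ctr) %*% vecs
  structure(list(id = item$id, eigenvectors = vecs, eigenvalues = vals,
                 projected = proj, center = ctr),
            class = "mts_pca")
}

#' @export
print.mts_pca <- function(x, ...) {
  fr <- cumsum(x$eigenvalues) / sum(x$eigenvalues)
  cat(sprintf("<mts_pca '%s'> n = %d, leading variance fractions: %s\n",
              x$id, length(x$eigenvalues),
              paste(sprintf("%.3f", utils::head(fr, 4)), collapse = " ")))
  invisible(x)
}

#' Retained component count under the variance-retention rule
#'
#' Returns the smallest `p` such that for every item the first `p` eigenvalues
#' carry strictly more than `threshold` of that item's total variance; if no
#' smaller `p` qualifies, returns `n`. This is the whole-matching rule: the
#' retention requirement must hold in all items at least.
#'
#' @param eigenvalue_lists A list of numeric vectors (one per MTS item, sorted
#'   nonincreasing), or a single numeric vector.
#' @param threshold Retained-variance fraction in (0, 1); the test is strict
#'   (`> threshold`). Default 0.9.
#' @return Integer `p`, `1 <= p <= n`.
#' @examples
#' choose_num_components(list(c(8, 1.5, 0.5)), threshold = 0.9)  # 2
#' choose_num_components(list(c(9, 1), c(5, 5)), threshold = 0.9)  # 2
#' @export
choose_num_components <- function(eigenvalue_lists, threshold = 0.9) {
  if (is.numeric(eigenvalue_lists)) eigenvalue_lists <- list(eigenvalue_lists)
  if (!length(eigenvalue_lists)) stop("'eigenvalue_lists' is empty")
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("'threshold' must lie in (0, 1)")
  fracs <- lapply(eigenvalue_lists, function(v) {
    if (!length(v)) stop("empty eigenvalue list")
    cumsum(v) / sum(v)
  })
  n <- min(lengths(fracs))
  for (p in seq_len(n)) {
    if (all(vapply(fracs, function(f) f[[p]] > threshold, logical(1))))
      return(p)
  }
  n
}

#' Principal-component series of an item
#'
#' The first `p` columns of the projected coordinates `D = X C`: column `i`
#' is the i-th principal-component series.
#'
#' @param item An [mts_item()].
#' @param pca Its [fit_pca()] result (or one whose eigenvectors should be
#'   applied, e.g. a long series' basis when projecting a query; the stored
#'   `center` is used).
#' @param p Number of components to keep, `1 <= p <= n`.
#' @return `m x p` numeric matrix.
#' @export
project_components <- function(item, pca, p) {
  if (!inherits(pca, "mts_pca")) stop("'pca' must be an mts_pca")
  n <- ncol(pca$eigenvectors)
  if (p < 1L || p > n) stop(sprintf("p = %d out of range 1..%d", p, n))
  X <- if (inherits(item, "mts_item")) item$values else as.matrix(item)
  if (ncol(X) != n) stop("item arity does not match the PCA basis")
  sweep(X, 2L, pca$center) %*% pca$eigenvectors[, seq_len(p), drop = FALSE]
}

#' Eigenvalue-derived dimension weights
#'
#' Aggregates, per retained component `i`, the variance vector `V_i` of i-th
#' eigenvalues across MTS items by a strategy `f` (min, mean or max), and
#' normalises: `w_i = f(V_i) / sum_j f(V_j)`. For subsequence matching each
#' `V_i` has a single element (the long series' eigenvalue), so the strategy
#' is immaterial. With `normalize = TRUE` each item's eigenvalue vector is
#' first divided by its own sum, making items of different overall scale
#' comparable.
#'
#' @param variances Either a list of `p` numeric vectors (`V_1 .. V_p`, the
#'   i-th component's eigenvalue across items) or a numeric matrix with one
#'   row per item and one column per component.
#' @param strategy Aggregation over items: `"mean"` (default), `"min"`, `"max"`.
#' @param normalize Divide each item's eigenvalue vector by its own sum before
#'   aggregating. Default `TRUE`.
#' @param p Number of leading components to weight; defaults to all columns
#'   supplied. When `p < ncol`, normalisation still uses the full row sums.
#' @return An object of class `weight_vector`: list with `weights` (length
#'   `p`, nonnegative, summing to 1), `strategy`, `normalized_inputs`.
#' @examples
#' compute_weights(list(4, 3, 2, 1))$weights        # 0.4 0.3 0.2 0.1
#' compute_weights(rbind(c(9, 1), c(6, 4)), strategy = "min")$weights
#' @export
compute_weights <- function(variances, strategy = c("mean", "min", "max"),
                            normalize = TRUE, p = NULL) {
  strategy <- match.arg(strategy)
  if (is.list(variances)) {
    len <- lengths(variances)
    if (!length(variances) || any(len == 0L)) stop("every V_i must be nonempty")
    if (length(unique(len)) != 1L)
      stop("all V_i must cover the same items (equal lengths)")
    V <- do.call(cbind, lapply(variances, as.numeric))   # items x components
  } else {
    V <- as.matrix(variances)
  }
  if (any(V < 0)) stop("eigenvalues must be nonnegative")
  if (is.null(p)) p <- ncol(V)
  if (p < 1L || p > ncol(V)) stop("'p' out of range")
  if (normalize) {
    rs <- rowSums(V)
    if (any(rs <= 0)) stop("cannot normalize an all-zero eigenvalue vector")
    V <- V / rs
  }
  Vp <- V[, seq_len(p), drop = FALSE]
  f <- switch(strategy,
              mean = colMeans(Vp),
              min = apply(Vp, 2L, min),
              max = apply(Vp, 2L, max))
  tot <- sum(f)
  if (tot <= 0) stop("all aggregated variances are zero; weights undefined")
  structure(list(weights = f / tot, strategy = strategy,
                 normalized_inputs = normalize),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("<weight_vector> strategy '%s'%s: %s\n", x$strategy,
              if (x$normalized_inputs) " (normalized inputs)" else "",
              paste(sprintf("%.4f", x$weights), collapse = " ")))
  invisible(x)
}
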