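#' Band width from a warping fraction
#'
#' The warping-window constraint is expressed as a fraction of series length:
#' the band covers cells whose index offset `|i - j|` is at most `w - 1`, with
#' `w = max(1, ceiling(band_fraction * max(length(a), length(b))))`. Width 1
#' admits the diagonal only, so on equal-length series the distance reduces to
#' the Euclidean distance. The default fraction is 0.05 (5% of the longer
#' series' length).
#'
#' @param la,lb Series lengths.
#' @param band_fraction Fraction of the longer length, in (0, 1].
#' @return Integer band width `w >= 1`.
#' @export
dtw_band_width <- function(la, lb, band_fraction = 0.05) {
  if (band_fraction <= 0 || band_fraction > 1)
    stop("'band_fraction' must lie in (0, 1]")
  max(1L, as.integer(ceiling(band_fraction * max(la, lb))))
}

#' Constrained dynamic time warping distance
#'
#' DTW with squared pointwise cost, symmetric steps (diagonal, vertical,
#' horizontal, no slope weights), a Sakoe-Chiba band, and the square root of
#' the accumulated cost as the reported distance. Symmetric in its arguments,
#' zero on identical series, and never increases as the band widens.
#'
#' @param a,b Numeric vectors (nonempty).
#' @param band_fraction Band as a fraction of the longer length; see
#'   [dtw_band_width()]. Ignored when `band` is given.
#' @param band Explicit integer band width (overrides `band_fraction`).
#' @return Nonnegative DTW distance.
#' @examples
#' dtw_distance(c(1, 2, 3), c(1, 1, 2, 2, 3, 3), band_fraction = 1)  # 0
#' @export
dtw_distance <- function(a, b, band_fraction = 0.05, band = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both series must be nonempty")
  w <- if (is.null(band)) dtw_band_width(length(a), length(b), band_fraction)
       else max(1L, as.integer(band))
  if (abs(length(a) - length(b)) > w - 1L)
    stop(sprintf(paste0("infeasible band: width %d admits no warping path ",
                        "between lengths %d and %d"), w, length(a), length(b)))
  dtw_dist_cpp(a, b, w)
}

match_frame <- function(dim = integer(0), source_id = character(0),
                        start = integer(0), length = integer(0),
                        distance = numeric(0)) {
  data.frame(dim = as.integer(dim), source_id = as.character(source_id),
             start = as.integer(start), length = as.integer(length),
             distance = as.numeric(distance), stringsAsFactors = FALSE)
}

#' Per-dimension kNN over whole items
#'
#' For one principal-component dimension, ranks every corpus item by the DTW
#' distance between its dim-th component series and the query's, and returns
#' the `kprime` closest as whole-sequence matches (start 1, length = item
#' length). The query itself plays the role of the self-match and is excluded
#' via `exclude_id`. Ties are broken by source id.
#'
#' @param query_pc Query `m x p` principal-component matrix.
#' @param items_pc Named list of `m_i x p` principal-component matrices.
#' @param dim Component index to search on.
#' @param kprime Number of neighbours to return (`k' >= k`).
#' @param band_fraction DTW band fraction (see [dtw_distance()]).
#' @param exclude_id Optional item id to exclude (the query itself).
#' @return A match data frame with columns `dim`, `source_id`, `start`,
#'   `length`, `distance`, ordered by nondecreasing distance.
#' @export
knn_whole_matching <- function(query_pc, items_pc, dim, kprime,
                               band_fraction = 0.05, exclude_id = NULL) {
  ids <- setdiff(names(items_pc), exclude_id)
  if (!length(ids)) stop("no candidate items to search")
  if (kprime > length(ids))
    stop(sprintf("kprime = %d exceeds the %d available items", kprime, length(ids)))
  q <- query_pc[, dim]
  d <- vapply(ids, function(id) {
    s <- items_pc[[id]][, dim]
    w <- dtw_band_width(length(q), length(s), band_fraction)
    if (abs(length(q) - length(s)) > w - 1L)
      w <- abs(length(q) - length(s)) + 1L  # lengths differ beyond the band: widen minimally
    dtw_dist_cpp(q, s, w)
  }, numeric(1))
  ord <- order(d, ids)
  top <- ord[seq_len(kprime)]
  match_frame(dim = rep(dim, kprime), source_id = ids[top],
              start = rep(1L, kprime),
              length = vapply(items_pc[ids[top]], nrow, integer(1)),
              distance = d[top])
}

#' Per-dimension kNN over sliding windows of a long series
#'
#' Computes the DTW distance between the query's component series and every
#' length-`l` window of the long series' same component, then greedily selects
#' the `kprime` best windows such that no two selected windows overlap by more
#' than `exclusion_zone` points (preventing near-duplicate shifts of a single
#' event). Windows overlapping the query's own position (`query_start`) by
#' more than the exclusion zone are skipped: that position is the self-match.
#'
#' @param query_dim Length-`l` numeric query component series.
#' @param long_dim Length-`M` numeric component series, `M >= l`.
#' @param kprime Number of matches to return.
#' @param band_fraction DTW band fraction.
#' @param exclusion_zone Maximum permitted overlap between returned windows,
#'   in points; defaults to `floor(l / 2)`.
#' @param query_start Optional 1-based start of the query inside `long_dim`.
#' @param dim Component index recorded in the result (bookkeeping only).
#' @param source_id Series id recorded in the result.
#' @return A match data frame ordered by nondecreasing distance; ties broken
#'   by earlier start.
#' @export
knn_subsequence <- function(query_dim, long_dim, kprime,
                            band_fraction = 0.05, exclusion_zone = NULL,
                            query_start = NULL, dim = 1L, source_id = "long") {
  q <- as.numeric(query_dim); s <- as.numeric(long_dim)
  l <- length(q); M <- length(s)
  if (l > M) stop("query longer than the series")
  if (kprime < 1L) stop("'kprime' must be at least 1")
  if (is.null(exclusion_zone)) exclusion_zone <- floor(l / 2)
  w <- dtw_band_width(l, l, band_fraction)
  d <- dtw_sliding_cpp(q, s, l, w)
  starts <- seq_len(M - l + 1L)
  ord <- order(d, starts)
  overlap <- function(t1, t2) max(0L, l - abs(t1 - t2))
  chosen <- integer(0)
  for (i in ord) {
    t <- starts[[i]]
    if (!is.null(query_start) && overlap(t, query_start) > exclusion_zone) next
    if (any(vapply(chosen, function(tc) overlap(t, tc) > exclusion_zone, logical(1))))
      next
    chosen <- c(chosen, t)
    if (length(chosen) == kprime) break
  }
  if (length(chosen) < kprime)
    stop(sprintf("only %d admissible windows for kprime = %d (exclusion zone %d)",
                 length(chosen), kprime, exclusion_zone))
  match_frame(dim = rep(as.integer(dim), kprime),
              source_id = rep(source_id, kprime),
              start = chosen, length = rep(l, kprime),
              distance = d[chosen])
}
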