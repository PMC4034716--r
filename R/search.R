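#' Search options for the dimension-combination pipeline
#'
#' Collects the tunable parameters of [knn_search()] with their defaults:
#' `measure` ("wborda" or "borda"), `kprime` (per-dimension neighbour count,
#' default `2 * k`), `threshold` (retained-variance fraction, default 0.9),
#' `strategy` and `normalize` (eigenvalue weight aggregation), `band_fraction`
#' (DTW warping window, default 0.05), `exclusion_zone` (subsequence overlap
#' suppression, default half the query length), `recompute_all` (truncation
#' distance reuse), and `p` (fixed component count overriding the threshold
#' rule).
#'
#' @param measure Ranking measure, `"wborda"` (weighted) or `"borda"`.
#' @param kprime Per-dimension neighbours `k'`; `NULL` means `2 * k`.
#' @param threshold Retained-variance fraction in (0, 1).
#' @param strategy Weight aggregation: `"mean"`, `"min"`, `"max"`.
#' @param normalize Normalise eigenvalue vectors before aggregation.
#' @param band_fraction DTW band fraction of the longer series length.
#' @param exclusion_zone Subsequence search overlap cap; `NULL` = `floor(l/2)`.
#' @param recompute_all Recompute all distances at aligned windows.
#' @param p Fixed retained component count; `NULL` = variance rule.
#' @return A named list of class `wborda_config`.
#' @export
search_config <- function(measure = c("wborda", "borda"), kprime = NULL,
                          threshold = 0.9, strategy = c("mean", "min", "max"),
                          normalize = TRUE, band_fraction = 0.05,
                          exclusion_zone = NULL, recompute_all = FALSE,
                          p = NULL) {
  structure(list(measure = match.arg(measure), kprime = kprime,
                 threshold = threshold, strategy = match.arg(strategy),
                 normalize = normalize, band_fraction = band_fraction,
                 exclusion_zone = exclusion_zone,
                 recompute_all = recompute_all, p = p),
            class = "wborda_config")
}

# Per-dimension rankings restricted to candidates with an original member in
# that dimension, ordered by the stored member distance (for the baseline
# measure's elimination-and-count semantics).
borda_dim_rankings <- function(grouped, cs) {
  p <- ncol(cs$dist)
  ids <- as.character(cs$candidates$group)
  lapply(seq_len(p), function(i) {
    mem <- grouped[grouped$dim == i, , drop = FALSE]
    mem <- mem[mem$group %in% cs$candidates$group, , drop = FALSE]
    if (!nrow(mem)) return(character(0))
    d <- vapply(split(mem$distance, mem$group), min, numeric(1))
    st <- vapply(split(mem$start, mem$group), min, numeric(1))
    g <- names(d)
    g[order(d, st, g)]
  })
}

#' k-nearest-neighbour search for a multivariate query
#'
#' Runs the full dimension-combination pipeline. The corpus is reduced to
#' principal-component series (covariance PCA per item for whole matching; a
#' single PCA of the long series, whose basis also projects the query, for
#' subsequence matching); the retained component count follows the
#' variance-retention rule unless fixed by `config$p`. A constrained-DTW kNN
#' search runs per component dimension; the per-dimension hits are truncated
#' (grouped by overlap, isolated groups deleted, groups aligned, candidates
#' reordered); and the candidates are ranked by the weighted BORDA score
#' ([s_wborda_rank()]) or the classical baseline ([s_borda_rank()]).
#'
#' If truncation leaves no candidate (possible when the per-dimension lists
#' are mutually disjoint), the search widens `k'` (doubling, up to the corpus
#' size) and retries, with a warning.
#'
#' @param query An [mts_item()] (its id is excluded from a whole-matching
#'   corpus).
#' @param corpus An [mts_dataset()] (whole matching) or [long_series()]
#'   (subsequence matching).
#' @param k Number of neighbours to return.
#' @param config A [search_config()].
#' @param query_start For subsequence matching only: the query's own 1-based
#'   position in the long series, if it was cut from it.
#' @return List of class `wborda_result`: `neighbors` (ranked data frame with
#'   scores), `p`, `weights`, `measure`, `candidates` (the scored candidate
#'   set), `matches` (raw per-dimension hits).
#' @export
knn_search <- function(query, corpus, k, config = search_config(),
                       query_start = NULL) {
  stopifnot(inherits(query, "mts_item"))
  kprime <- if (is.null(config$kprime)) 2L * k else config$kprime
  if (kprime < k) stop("'kprime' must be at least k")
  if (inherits(corpus, "mts_dataset"))
    knn_search_whole(query, corpus, k, kprime, config)
  else if (inherits(corpus, "long_series"))
    knn_search_subseq(query, corpus, k, kprime, config, query_start)
  else stop("'corpus' must be an mts_dataset or a long_series")
}

knn_search_whole <- function(query, corpus, k, kprime, config) {
  items <- corpus$items
  items[[query$id]] <- NULL            # the query plays the role of s_0
  if (!length(items)) stop("pca_weights: corpus holds only the query itself")
  pcas <- lapply(items, fit_pca)
  qpca <- fit_pca(query)
  eig <- lapply(c(pcas, list(qpca)), `[[`, "eigenvalues")
  p <- if (is.null(config$p)) choose_num_components(eig, config$threshold)
       else config$p
  items_pc <- lapply(pcas, function(z) z$projected[, seq_len(p), drop = FALSE])
  query_pc <- qpca$projected[, seq_len(p), drop = FALSE]
  eigmat <- do.call(rbind, lapply(pcas, `[[`, "eigenvalues"))
  weights <- compute_weights(eigmat, strategy = config$strategy,
                             normalize = config$normalize, p = p)
  kp <- min(kprime, length(items))
  repeat {
    matches <- do.call(rbind, lapply(seq_len(p), function(j)
      knn_whole_matching(query_pc, items_pc, dim = j, kprime = kp,
                         band_fraction = config$band_fraction)))
    grouped <- tryCatch(group_matches(matches),
                        error = function(e) stop("truncation: ", conditionMessage(e)))
    surv <- delete_isolated(grouped, n_dims = p)
    cs <- align_groups(surv, query_pc, items_pc,
                       band_fraction = config$band_fraction,
                       recompute_all = config$recompute_all)
    if (nrow(cs$candidates) > 0L || kp >= length(items)) break
    kp <- min(2L * kp, length(items))
    warning(sprintf("no candidate survived truncation; widening k' to %d", kp))
  }
  finish_search(cs, surv, weights, k, kp, config$measure, p, matches)
}

knn_search_subseq <- function(query, series, k, kprime, config, query_start) {
  l <- nrow(query$values)
  if (l > nrow(series$values)) stop("query longer than the series")
  spca <- fit_pca(mts_item(series$values, id = series$id))
  p <- if (is.null(config$p))
    choose_num_components(list(spca$eigenvalues), config$threshold)
  else config$p
  long_pc <- spca$projected[, seq_len(p), drop = FALSE]
  query_pc <- project_components(query, spca, p)
  weights <- compute_weights(matrix(spca$eigenvalues, nrow = 1),
                             strategy = config$strategy,
                             normalize = config$normalize, p = p)
  matches <- do.call(rbind, lapply(seq_len(p), function(j)
    knn_subsequence(query_pc[, j], long_pc[, j], kprime = kprime,
                    band_fraction = config$band_fraction,
                    exclusion_zone = config$exclusion_zone,
                    query_start = query_start, dim = j,
                    source_id = series$id)))
  grouped <- group_matches(matches, l = l)
  surv <- delete_isolated(grouped, n_dims = p)
  cs <- align_groups(surv, query_pc, long_pc,
                     band_fraction = config$band_fraction,
                     recompute_all = config$recompute_all)
  finish_search(cs, surv, weights, k, kprime, config$measure, p, matches)
}

finish_search <- function(cs, grouped, weights, k, kprime, measure, p, matches) {
  neighbors <- if (measure == "wborda") {
    s_wborda_rank(cs, weights, k)
  } else {
    rk <- borda_dim_rankings(grouped, cs)
    sb <- s_borda_rank(rk, n_dims = p, k = k,
                       tie_order = as.character(
                         cs$candidates$group[order(cs$candidates$start,
                                                   cs$candidates$group)]))
    idx <- match(as.integer(sb$id), cs$candidates$group)
    whole <- all(cs$candidates$start == 1L)
    data.frame(id = if (whole) cs$candidates$source_id[idx]
               else sprintf("%d@%s", cs$candidates$start[idx],
                            cs$candidates$source_id[idx]),
               source_id = cs$candidates$source_id[idx],
               start = cs$candidates$start[idx],
               length = cs$candidates$length[idx],
               score = sb$score, stringsAsFactors = FALSE)
  }
  structure(list(neighbors = neighbors, p = p, weights = weights,
                 measure = measure, kprime = kprime,
                 candidates = cs, matches = matches),
            class = "wborda_result")
}

#' @export
print.wborda_result <- function(x, ...) {
  cat(sprintf("<wborda_result> measure %s, p = %d, k' = %d\n",
              toupper(x$measure), x$p, x$kprime))
  print(x$neighbors)
  invisible(x)
}
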