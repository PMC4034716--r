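#' Classical BORDA scores
#'
#' Each ranking awards linearly decreasing points by position: the candidate
#' ranked first earns `top_points`, the second `top_points - 1`, and so on.
#' A candidate's BORDA score is the sum of its points across rankings;
#' candidates absent from a ranking earn nothing from it.
#'
#' @param rankings List of character vectors, each an ordered preference list
#'   (most preferred first, no duplicates within a list).
#' @param top_points Points awarded to the first position; every ranking must
#'   have at most `top_points` entries.
#' @return Named numeric vector of scores, sorted nonincreasing (ties in
#'   lexicographic candidate order).
#' @examples
#' rounds <- list(c("r1","r2","r3","r4"), c("r2","r1","r4","r3"),
#'                c("r4","r3","r1","r2"), c("r3","r4","r2","r1"))
#' borda_scores(rounds, top_points = 4)   # every runner ties at 10
#' @export
borda_scores <- function(rankings, top_points) {
  if (!length(rankings)) stop("'rankings' is empty")
  scores <- numeric(0)
  for (r in rankings) {
    r <- as.character(r)
    if (anyDuplicated(r))
      stop("duplicate candidate within one ranking: ",
           paste(unique(r[duplicated(r)]), collapse = ", "))
    if (length(r) > top_points)
      stop("a ranking has more candidates than 'top_points'")
    pts <- top_points - seq_along(r) + 1
    for (k in seq_along(r)) {
      cid <- r[[k]]
      scores[[cid]] <- (if (is.na(scores[cid])) 0 else scores[[cid]]) + pts[[k]]
    }
  }
  scores[order(-scores, names(scores))]
}

#' Weighted voting score of one neighbour
#'
#' The score interpolates linearly in the distance ratio `d_i / d_k'` between
#' the two anchors of the weighted scheme: a neighbour coinciding with the
#' query (`d_i = 0`) earns `w_j * (1 + k')`, matching the query's own anchor
#' score `k' + 1` at unit weight, and the k'-th (farthest) neighbour earns
#' `w_j * 1`. Unlike positional BORDA points, the score reflects the actual
#' similarity gaps: it depends on distances only through the ratio, so
#' rescaling all distances in a dimension leaves its scores unchanged.
#'
#' @param d_i Distance of the scored neighbour, `0 <= d_i <= d_kprime`.
#' @param d_kprime Distance of the k'-th neighbour (the list's largest).
#' @param kprime Neighbour count `k'`.
#' @param w_j Weight of the dimension casting this vote.
#' @return `w_j * (1 + kprime * (1 - d_i / d_kprime))`; when `d_kprime = 0`
#'   (all neighbours coincide with the query) `w_j * (1 + kprime)`.
#' @export
weighted_voting_score <- function(d_i, d_kprime, kprime, w_j = 1) {
  if (any(w_j < 0)) stop("'w_j' must be nonnegative")
  if (kprime < 1) stop("'kprime' must be at least 1")
  if (any(d_i < 0) || any(d_kprime < 0)) stop("distances must be nonnegative")
  if (any(d_i > d_kprime + 1e-12))
    stop("d_i exceeds d_kprime: the neighbour list ordering contract is violated")
  len <- max(length(d_i), length(d_kprime), length(w_j))
  d_i <- rep_len(d_i, len); dk <- rep_len(d_kprime, len)
  w <- rep_len(w_j, len)
  vs <- w * (1 + kprime)              # anchor: coincides with the query
  pos <- dk > 0
  vs[pos] <- w[pos] * (1 + kprime * (1 - d_i[pos] / dk[pos]))
  vs
}

#' Rank candidates by the classical BORDA measure
#'
#' The baseline dimension-combination measure: candidates appearing in fewer
#' than half of the dimensions' neighbour lists are eliminated, and the rest
#' are scored by positional BORDA points per dimension (the most similar
#' sequence in a list of `i` earns `i` points) and summed.
#'
#' @param per_dim_rankings List (one element per dimension) of ordered
#'   candidate-id character vectors, most similar first.
#' @param n_dims Number of dimensions `p` (elimination threshold `p / 2`).
#' @param k Number of winners to return.
#' @param tie_order Optional character vector of candidate ids fixing the
#'   tie-break order (e.g. by start time); defaults to lexicographic.
#' @return Data frame `id`, `score`, `votes`, ordered by decreasing score,
#'   at most `k` rows. If fewer than `k` candidates survive elimination, all
#'   survivors are returned with a warning.
#' @export
s_borda_rank <- function(per_dim_rankings, n_dims, k, tie_order = NULL) {
  all_ids <- unique(unlist(per_dim_rankings))
  votes <- vapply(all_ids, function(id)
    sum(vapply(per_dim_rankings, function(r) id %in% r, logical(1))), numeric(1))
  keep <- all_ids[2 * votes >= n_dims]
  scores <- stats::setNames(numeric(length(keep)), keep)
  for (r in per_dim_rankings) {
    r <- as.character(r)
    if (anyDuplicated(r)) stop("duplicate candidate within one dimension ranking")
    pts <- length(r) - seq_along(r) + 1   # most similar earns list-length points
    for (j in seq_along(r)) {
      if (r[[j]] %in% keep) scores[[r[[j]]]] <- scores[[r[[j]]]] + pts[[j]]
    }
  }
  tie <- if (is.null(tie_order)) keep[order(keep)] else tie_order
  ord <- order(-scores, match(keep, tie))
  res <- data.frame(id = keep[ord], score = unname(scores[ord]),
                    votes = unname(votes[keep][ord]), stringsAsFactors = FALSE)
  if (nrow(res) < k)
    warning(sprintf("only %d candidates survive elimination (k = %d)", nrow(res), k))
  utils::head(res, k)
}

#' Rank candidate multivariate sequences by the weighted BORDA measure
#'
#' Each dimension votes for every candidate with [weighted_voting_score()]:
#' the dimension's `d_k'` anchor is its largest candidate distance, `k'` is
#' the number of candidates it ranks, and the vote is scaled by the
#' dimension's eigenvalue weight. A candidate's weighted BORDA score is the
#' sum of its votes across dimensions; the top `k` are the search result.
#'
#' @param cs A `candidate_set` from [align_groups()] (every candidate has a
#'   finite distance in every dimension).
#' @param weights A [compute_weights()] `weight_vector` (or bare numeric
#'   vector summing to 1) of length `ncol(cs$dist)`.
#' @param k Number of winners to return.
#' @return Data frame `id` (source id for whole matching, `start@source` for
#'   subsequences), `source_id`, `start`, `length`, `score`, ordered by
#'   decreasing score with ties broken by earlier start then group id.
#' @export
s_wborda_rank <- function(cs, weights, k) {
  stopifnot(inherits(cs, "candidate_set"))
  w <- if (inherits(weights, "weight_vector")) weights$weights else as.numeric(weights)
  p <- ncol(cs$dist)
  if (length(w) != p) stop("weight vector length does not match the dimensions")
  nc <- nrow(cs$candidates)
  if (!nc) {
    warning("empty candidate set")
    return(data.frame(id = character(0), source_id = character(0),
                      start = integer(0), length = integer(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  score <- numeric(nc)
  for (i in seq_len(p)) {
    d <- cs$dist[, i]
    score <- score + weighted_voting_score(d, max(d), kprime = nc, w_j = w[[i]])
  }
  ord <- order(-score, cs$candidates$start, cs$candidates$group)
  whole <- all(cs$candidates$start == 1L)
  res <- data.frame(
    id = if (whole) cs$candidates$source_id
         else sprintf("%d@%s", cs$candidates$start, cs$candidates$source_id),
    source_id = cs$candidates$source_id,
    start = cs$candidates$start, length = cs$candidates$length,
    score = score, stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(res) <- NULL
  utils::head(res, k)
}
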