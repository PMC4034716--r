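overlap_len <- function(s1, l1, s2, l2) {
  # half-open windows [s, s+l)
  max(0L, min(s1 + l1, s2 + l2) - max(s1, s2))
}

#' Group per-dimension matches by temporal overlap
#'
#' Two matches are neighbours when they come from the same source series and
#' their windows overlap by strictly more than half the sequence length `l`;
#' groups are the connected components of this relation, so every member of a
#' group can reach every other through a chain of overlapping members. A match
#' with no qualifying neighbour forms a singleton group. For whole matching,
#' where matches are entire items, groups coincide with item identity.
#'
#' @param matches Match data frame (columns `dim`, `source_id`, `start`,
#'   `length`, `distance`), as produced by [knn_whole_matching()] or
#'   [knn_subsequence()], typically row-bound across dimensions.
#' @param l Sequence length defining the "half length" threshold; defaults to
#'   the smallest match length present.
#' @return The same data frame with an integer `group` column; group ids are
#'   numbered by first appearance in row order.
#' @export
group_matches <- function(matches, l = NULL) {
  nm <- nrow(matches)
  if (!nm) return(cbind(matches, group = integer(0)))
  if (is.null(l)) l <- min(matches$length)
  parent <- seq_len(nm)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  for (i in seq_len(nm - 1L)) {
    for (j in seq.int(i + 1L, nm)) {
      if (matches$source_id[[i]] != matches$source_id[[j]]) next
      ov <- overlap_len(matches$start[[i]], matches$length[[i]],
                        matches$start[[j]], matches$length[[j]])
      if (2L * ov > l) {   # strictly over the half length
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[[rj]] <- ri
      }
    }
  }
  roots <- vapply(seq_len(nm), find, integer(1))
  matches$group <- match(roots, unique(roots))
  matches
}

#' Delete isolated groups
#'
#' A group whose member count is less than half the number of dimensions is
#' isolated: too few component series agree on that time region for it to be a
#' credible multivariate event. Kept iff `2 * members >= n_dims`.
#'
#' @param grouped Output of [group_matches()].
#' @param n_dims Number of retained component dimensions `p`.
#' @return The surviving rows, original order and group ids preserved.
#' @export
delete_isolated <- function(grouped, n_dims) {
  if (n_dims < 1L) stop("'n_dims' must be at least 1")
  if (!nrow(grouped)) return(grouped)
  sizes <- table(grouped$group)
  keep <- as.integer(names(sizes)[2L * as.integer(sizes) >= n_dims])
  grouped[grouped$group %in% keep, , drop = FALSE]
}

#' Align surviving groups into candidate multivariate sequences
#'
#' For each group the aligned start is the mean of the member starts, rounded
#' half up; the candidate is the multivariate window of length `l` at that
#' start. Per dimension, the candidate's distance to the query is the stored
#' member distance when the group contains a match in that dimension (kept as
#' is, to avoid recomputation, even though alignment may shift the window;
#' `recompute_all = TRUE` forces a fresh computation everywhere), otherwise it
#' is computed by DTW between the query's and the window's component series.
#' A group whose aligned window would run past the end of its source series is
#' dropped with a warning rather than clamped.
#'
#' @param grouped Surviving matches from [delete_isolated()].
#' @param query_pc Query `l x p` principal-component matrix.
#' @param data_pc Either a single `M x p` matrix (subsequence matching, all
#'   matches from one long series) or a named list of `m_i x p` matrices keyed
#'   by source id (whole matching).
#' @param band_fraction DTW band fraction for recomputed dimensions.
#' @param recompute_all Recompute every per-dimension distance at the aligned
#'   window instead of reusing stored member distances. Default `FALSE`.
#' @return An object of class `candidate_set`: list with `candidates` (data
#'   frame: `group`, `source_id`, `start`, `length`) and `dist` (matrix, one
#'   row per candidate, one column per dimension, all finite and nonnegative).
#' @export
align_groups <- function(grouped, query_pc, data_pc, band_fraction = 0.05,
                         recompute_all = FALSE) {
  p <- ncol(query_pc)
  pc_for <- function(id) {
    if (is.list(data_pc)) {
      if (is.null(data_pc[[id]])) stop("no component series for source '", id, "'")
      data_pc[[id]]
    } else data_pc
  }
  gids <- unique(grouped$group)
  cand <- list(); dmat <- list()
  for (g in gids) {
    mem <- grouped[grouped$group == g, , drop = FALSE]
    l <- min(mem$length)
    t0 <- floor(mean(mem$start) + 0.5)   # round half up
    src <- mem$source_id[[1L]]
    pcs <- pc_for(src)
    whole <- all(mem$start == 1L) && l == nrow(pcs)   # whole-item candidate
    if (t0 < 1L || t0 + l - 1L > nrow(pcs)) {
      warning(sprintf("group %d: aligned window [%d, %d) runs outside '%s'; dropped",
                      g, t0, t0 + l, src))
      next
    }
    win <- pcs[seq.int(t0, t0 + l - 1L), , drop = FALSE]
    dd <- numeric(p)
    for (i in seq_len(p)) {
      have <- mem$dim == i
      if (any(have) && !recompute_all) {
        dd[[i]] <- min(mem$distance[have])
      } else if (whole) {
        qi <- query_pc[, i]; si <- pcs[, i]
        w <- dtw_band_width(length(qi), length(si), band_fraction)
        if (abs(length(qi) - length(si)) > w - 1L)
          w <- abs(length(qi) - length(si)) + 1L
        dd[[i]] <- dtw_dist_cpp(qi, si, w)
      } else {
        dd[[i]] <- dtw_distance(query_pc[, i], win[, i],
                                band_fraction = band_fraction)
      }
    }
    cand[[length(cand) + 1L]] <- data.frame(
      group = g, source_id = src, start = t0, length = l,
      stringsAsFactors = FALSE)
    dmat[[length(dmat) + 1L]] <- dd
  }
  candidates <- if (length(cand)) do.call(rbind, cand)
                else data.frame(group = integer(0), source_id = character(0),
                                start = integer(0), length = integer(0))
  dist <- if (length(dmat)) do.call(rbind, dmat) else matrix(0, 0, p)
  structure(list(candidates = candidates, dist = dist), class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> %d candidates x %d dimensions\n",
              nrow(x$candidates), ncol(x$dist)))
  invisible(x)
}

#' Per-dimension candidate rankings
#'
#' Reorders the candidate sequences dimension by dimension by the distances
#' fixed at alignment. Ties are broken by earlier start, then by group id.
#'
#' @param cs A [align_groups()] `candidate_set`.
#' @return List of integer vectors, one per dimension: candidate row indices
#'   in nondecreasing order of that dimension's distance.
#' @export
reorder_candidates <- function(cs) {
  stopifnot(inherits(cs, "candidate_set"))
  p <- ncol(cs$dist)
  lapply(seq_len(p), function(i) {
    order(cs$dist[, i], cs$candidates$start, cs$candidates$group)
  })
}
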