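smooth_wave <- function(m, n_harm = 3L) {
  # seeded random sinusoid mixture, standardised to unit sd
  t <- seq_len(m) / m
  z <- rep(0, m)
  for (h in seq_len(n_harm)) {
    z <- z + stats::runif(1, 0.5, 1.5) *
      sin(2 * pi * stats::runif(1, 1, 4 + h) * t + stats::runif(1, 0, 2 * pi))
  }
  (z - mean(z)) / stats::sd(z)
}

time_warp <- function(x, max_frac = 0.05) {
  # smooth random time distortion of up to max_frac of the length, shared by
  # all columns (channels are recorded on one clock)
  x <- as.matrix(x)
  m <- nrow(x)
  t <- seq_len(m)
  amp <- stats::runif(1, 0, max_frac) * m
  shift <- amp * sin(2 * pi * stats::runif(1, 0.5, 1.5) * t / m +
                       stats::runif(1, 0, 2 * pi))
  tw <- pmin(pmax(t + shift, 1), m)
  apply(x, 2L, function(col) stats::approx(t, col, xout = tw)$y)
}

#' Specification of a synthetic labelled MTS collection
#'
#' Describes a multi-class collection whose classes differ in latent
#' (principal-component) structure: each class owns `latent_rank` smooth
#' template waveforms, mixed into the `n` observed channels by a loading
#' matrix shared across the collection; items add smooth within-class latent
#' variation (unit scale), per-item time-warp jitter of up to 5% of the
#' length (so elastic matching is actually exercised), and white Gaussian
#' observation noise.
#'
#' @param n_classes Number of classes.
#' @param items_per_class Items generated per class.
#' @param m Series length (time points).
#' @param n Number of observed variables (channels).
#' @param latent_rank Effective number of latent components per class
#'   (`<= n`).
#' @param separation Amplitude of the class template waveforms, in units of
#'   the within-class latent standard deviation; 0 makes classes
#'   statistically exchangeable.
#' @param noise_sd Standard deviation of the observation noise.
#' @param seed Integer seed; identical spec and seed give an identical
#'   dataset.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 3L, items_per_class = 20L, m = 60L,
                           n = 6L, latent_rank = 2L, separation = 10,
                           noise_sd = 0.1, seed = 1L) {
  stopifnot(latent_rank <= n, separation >= 0, noise_sd >= 0,
            n_classes >= 1, items_per_class >= 1, m >= 2)
  structure(list(n_classes = as.integer(n_classes),
                 items_per_class = as.integer(items_per_class),
                 m = as.integer(m), n = as.integer(n),
                 latent_rank = as.integer(latent_rank),
                 separation = separation, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a labelled synthetic MTS collection
#'
#' See [synthetic_spec()] for the generative model. Item `i` of class `c` is
#' `warp((separation * T_c + W_i)) A' + E_i`: class templates `T_c` (m x
#' latent_rank smooth unit-sd waveforms) scaled by the separation, plus
#' item-specific smooth latent variation `W_i` (unit sd), time-warp jittered,
#' mixed into the observed channels by a single loading matrix `A` (n x
#' latent_rank, unit-norm rows) shared by the whole collection — so classes
#' differ only in their latent waveforms and `separation = 0` makes them
#' statistically exchangeable — and degraded by white noise. With small noise
#' the first `latent_rank` eigenvalues of an item's covariance carry almost
#' all the variance, the regime the dimension-combination method assumes.
#'
#' @param spec A [synthetic_spec()].
#' @return A labelled [mts_dataset()] with ids `c<class>_i<item>` and labels
#'   `class<1..>`.
#' @export
generate_labeled_mts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  items <- list()
  # one loading matrix for the whole collection: classes differ only in their
  # latent waveforms, so separation = 0 makes them statistically exchangeable
  A <- matrix(stats::rnorm(spec$n * spec$latent_rank), spec$n)
  A <- A / sqrt(rowSums(A^2))                # unit-norm channel loadings
  for (cl in seq_len(spec$n_classes)) {
    Tc <- vapply(seq_len(spec$latent_rank), function(r) smooth_wave(spec$m),
                 numeric(spec$m))
    for (i in seq_len(spec$items_per_class)) {
      Wi <- vapply(seq_len(spec$latent_rank), function(r) smooth_wave(spec$m),
                   numeric(spec$m))
      lat <- time_warp(spec$separation * Tc + Wi)
      X <- lat %*% t(A) +
        matrix(stats::rnorm(spec$m * spec$n, sd = spec$noise_sd), spec$m)
      items[[length(items) + 1L]] <-
        mts_item(X, id = sprintf("c%d_i%02d", cl, i),
                 label = sprintf("class%d", cl))
    }
  }
  mts_dataset(items)
}

#' Generate a long series with planted multivariate motifs
#'
#' Builds a background of white Gaussian noise (unit sd per channel), draws a
#' smooth multivariate motif of length `l` (unit-sd smooth waveforms per
#' channel), and plants `n_motifs` noisy copies (noise sd `noise_sd`) at
#' seeded, mutually non-overlapping starts. The clean motif is returned as the
#' query, so ground truth is available for every planted occurrence.
#'
#' @param n_dims Number of channels.
#' @param M Length of the long series; requires `n_motifs * l <= M / 2`.
#' @param l Motif (and query) length.
#' @param n_motifs Number of planted copies (0 allowed).
#' @param noise_sd Noise added to each planted copy.
#' @param seed Integer seed.
#' @return List: `series` (a [long_series()]), `starts` (sorted 1-based starts
#'   of the planted copies), `query` (the clean motif as an [mts_item()]).
#' @export
generate_long_with_motifs <- function(n_dims = 3L, M = 600L, l = 50L,
                                      n_motifs = 3L, noise_sd = 0.05,
                                      seed = 1L) {
  if (n_motifs * l > M / 2)
    stop(sprintf("infeasible packing: %d motifs of length %d exceed M/2 = %g",
                 n_motifs, l, M / 2))
  set.seed(as.integer(seed))
  motif <- vapply(seq_len(n_dims), function(j) smooth_wave(l), numeric(l))
  bg <- matrix(stats::rnorm(M * n_dims), M, n_dims)
  starts <- integer(0)
  if (n_motifs > 0L) {
    for (tries in seq_len(10000L)) {
      cand <- sample.int(M - l + 1L, 1L)
      if (all(abs(cand - starts) >= l)) starts <- c(starts, cand)
      if (length(starts) == n_motifs) break
    }
    if (length(starts) < n_motifs)
      stop("could not place all motifs without overlap; lower n_motifs or l")
    for (t0 in starts) {
      bg[seq.int(t0, t0 + l - 1L), ] <- motif +
        matrix(stats::rnorm(l * n_dims, sd = noise_sd), l, n_dims)
    }
  }
  list(series = long_series(bg, id = sprintf("synthetic_motifs_seed%d", seed)),
       starts = sort(starts),
       query = mts_item(motif, id = "query"))
}
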