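# Independent oracles used across test files. These deliberately avoid the
# package's own algorithms: the DTW oracle enumerates complete warping paths,
# the eigen oracle solves the characteristic polynomial, and the voting
# oracles re-score candidates with plain loops.

# Minimum DTW cost by explicit enumeration of every monotone warping path
# from (1,1) to (la,lb) restricted to |i-j| <= width - 1. Exponential; only
# for short series.
dtw_brute <- function(a, b, width) {
  la <- length(a); lb <- length(b)
  off <- width - 1L
  if (abs(la - lb) > off) return(Inf)
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + (a[[i]] - b[[j]])^2
    if (i == la && j == lb) {
      if (acc < best) best <<- acc
      return(invisible())
    }
    if (i + 1L <= la && abs(i + 1L - j) <= off) walk(i + 1L, j, acc)
    if (j + 1L <= lb && abs(i - j - 1L) <= off) walk(i, j + 1L, acc)
    if (i + 1L <= la && j + 1L <= lb) walk(i + 1L, j + 1L, acc)
  }
  walk(1L, 1L, 0)
  sqrt(best)
}

# Eigenvalues of a symmetric 2x2 or 3x3 matrix from the characteristic
# polynomial (roots via polyroot), sorted nonincreasing.
eigen_charpoly <- function(S) {
  n <- nrow(S)
  stopifnot(n %in% c(2L, 3L))
  if (n == 2L) {
    coefs <- c(det(S), -(S[1, 1] + S[2, 2]), 1)
  } else {
    tr <- sum(diag(S))
    m2 <- det(S[c(1, 2), c(1, 2)]) + det(S[c(1, 3), c(1, 3)]) +
      det(S[c(2, 3), c(2, 3)])
    # characteristic polynomial: -x^3 + tr x^2 - m2 x + det
    coefs <- c(det(S), -m2, tr, -1)
  }
  sort(Re(polyroot(coefs)), decreasing = TRUE)
}

# Plain-loop BORDA re-scoring: candidate score = sum over rankings of
# (points of its position), most similar earning the list length.
borda_brute <- function(per_dim_rankings, n_dims) {
  ids <- unique(unlist(per_dim_rankings))
  votes <- sapply(ids, function(id)
    sum(sapply(per_dim_rankings, function(r) id %in% r)))
  ids <- ids[votes[ids] * 2 >= n_dims]
  sc <- sapply(ids, function(id) {
    s <- 0
    for (r in per_dim_rankings) {
      pos <- match(id, r)
      if (!is.na(pos)) s <- s + (length(r) - pos + 1)
    }
    s
  })
  list(scores = sc, votes = votes[ids])
}

# Plain-loop weighted BORDA re-scoring from a distance matrix.
wborda_brute <- function(dist, w) {
  nc <- nrow(dist)
  sapply(seq_len(nc), function(c) {
    s <- 0
    for (j in seq_len(ncol(dist))) {
      dk <- max(dist[, j])
      s <- s + if (dk == 0) w[[j]] * (1 + nc)
      else w[[j]] * (1 + nc * (1 - dist[c, j] / dk))
    }
    s
  })
}

# 8-point orthogonal design with exactly the requested column variances and
# zero covariances (Hadamard columns rescaled); diagonal covariance by
# construction, so the eigenvalues are the variances.
item_with_variances <- function(vars, id = "design") {
  H <- matrix(1, 8, 8)
  for (k in c(1, 2, 4)) {
    blk <- H[1:k, 1:k, drop = FALSE]
    H[1:(2 * k), 1:(2 * k)] <- rbind(cbind(blk, blk), cbind(blk, -blk))
  }
  stopifnot(length(vars) <= 7)
  X <- H[, 1 + seq_along(vars), drop = FALSE]
  X <- sweep(X, 2, sqrt(unlist(vars) * 7 / 8), `*`)
  mts_item(X, id = id)
}

# Nine-match truncation scenario: three dimensions with three hits each on
# one long source (l = 20), laid out so that one group chains three
# overlapping hits, two groups pair two hits, and two hits are isolated
# singletons.
nine_match_scenario <- function(l = 20L) {
  data.frame(
    dim       = c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L),
    source_id = "long",
    start     = c(10L, 60L, 100L, 15L, 63L, 200L, 22L, 150L, 95L),
    length    = l,
    distance  = c(0.10, 0.20, 0.30, 0.12, 0.22, 0.32, 0.14, 0.24, 0.34),
    stringsAsFactors = FALSE)
}

rand_item <- function(m, n, id = "x", label = NULL) {
  mts_item(matrix(rnorm(m * n), m, n), id = id, label = label)
}
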