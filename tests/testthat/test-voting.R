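test_that("borda_scores awards linearly decreasing points", {
  expect_equal(borda_scores(list(c("a", "b", "c")), top_points = 3),
               c(a = 3, b = 2, c = 1))
  # two reversed rankings of four candidates tie everyone at 5
  sc <- borda_scores(list(letters[1:4], rev(letters[1:4])), top_points = 4)
  expect_equal(unname(sc), rep(5, 4))
  expect_error(borda_scores(list(c("a", "a", "b")), 3), "duplicate")
  expect_error(borda_scores(list(letters[1:5]), 3), "more candidates")
  # absentees earn nothing
  sc2 <- borda_scores(list(c("a", "b"), c("a", "c")), top_points = 2)
  expect_equal(sc2[["a"]], 4)
  expect_equal(sc2[["b"]], 1)
})

test_that("weighted voting score interpolates between its two anchors", {
  expect_equal(weighted_voting_score(0, 4, kprime = 3, w_j = 1), 4)   # k'+1
  expect_equal(weighted_voting_score(4, 4, kprime = 3, w_j = 1), 1)
  expect_equal(weighted_voting_score(c(1, 2, 4), 4, 3, 1), c(3.25, 2.5, 1))
  # coincident neighbour list: everyone at the query's anchor
  expect_equal(weighted_voting_score(0, 0, 3, 0.5), 0.5 * 4)
  # weight scales linearly
  expect_equal(weighted_voting_score(1, 4, 3, 0.25), 0.25 * 3.25)
  expect_error(weighted_voting_score(5, 4, 3, 1), "exceeds")
})

test_that("the weighted score is strictly decreasing and scale invariant", {
  d <- seq(0, 4, by = 0.5)
  vs <- weighted_voting_score(d, 4, kprime = 5, w_j = 0.3)
  expect_true(all(diff(vs) < 0))
  expect_true(all(vs >= 0.3 - 1e-12 & vs <= 0.3 * 6 + 1e-12))
  # multiplying all distances in a dimension by c > 0 changes nothing
  expect_equal(weighted_voting_score(7 * d, 7 * 4, 5, 0.3), vs)
})

test_that("s_borda_rank eliminates sparse candidates and matches the oracle", {
  rk <- list(c("a", "b", "c"), c("b", "a", "d"), c("a", "b", "d"))
  # c appears in 1 of 3 dims: eliminated
  res <- s_borda_rank(rk, n_dims = 3, k = 3)
  expect_false("c" %in% res$id)
  # a ranked 1st in two 3-long lists and 2nd in one: 3+3+2 = 8
  expect_equal(res$score[res$id == "a"], 8)
  # first place in all three 3-long lists scores 9
  res1 <- s_borda_rank(list(c("x", "y", "z"), c("x", "z", "y"),
                            c("x", "y", "z")), n_dims = 3, k = 1)
  expect_equal(res1$id, "x")
  expect_equal(res1$score, 9)
  # random instances against the plain-loop oracle
  set.seed(83)
  for (rep in 1:20) {
    ids <- paste0("c", 1:7)
    rk <- lapply(1:3, function(j) sample(ids, sample(3:6, 1)))
    got <- suppressWarnings(s_borda_rank(rk, n_dims = 3, k = 10))
    want <- borda_brute(rk, n_dims = 3)
    expect_setequal(got$id, names(want$scores))
    expect_equal(got$score, unname(sort(want$scores, decreasing = TRUE)))
    expect_equal(got$votes, unname(want$votes[got$id]))
    expect_true(all(diff(got$score) <= 0))
  }
})

test_that("s_wborda_rank reproduces hand-evaluated weighted scores", {
  dist <- rbind(c(1, 6), c(2, 3), c(4, 2), c(3, 6))
  cand <- data.frame(group = 1:4, source_id = paste0("it", 1:4),
                     start = 1L, length = 10L)
  cs <- structure(list(candidates = cand, dist = dist),
                  class = "candidate_set")
  w <- c(0.7, 0.3)
  got <- s_wborda_rank(cs, w, k = 4)
  want <- wborda_brute(dist, w)
  expect_equal(got$score, sort(want, decreasing = TRUE))
  expect_equal(got$id, paste0("it", order(-want)))
  # dominance: a candidate better in every dimension ranks higher
  cs2 <- structure(list(candidates = cand[1:2, ],
                        dist = rbind(c(1, 2), c(3, 4))),
                   class = "candidate_set")
  expect_equal(s_wborda_rank(cs2, c(0.5, 0.5), 2)$id[[1]], "it1")
  # a single candidate is returned regardless of score
  cs1 <- structure(list(candidates = cand[1, ], dist = dist[1, , drop = FALSE]),
                   class = "candidate_set")
  expect_equal(nrow(s_wborda_rank(cs1, w, 3)), 1L)
  # empty candidate set warns and returns nothing
  cs0 <- structure(list(candidates = cand[0, ], dist = dist[0, , drop = FALSE]),
                   class = "candidate_set")
  expect_warning(r0 <- s_wborda_rank(cs0, w, 3), "empty")
  expect_equal(nrow(r0), 0L)
})

test_that("weighted and classical rankings agree under symmetric conditions", {
  # same ranks in all dimensions with equally spaced distances
  set.seed(89)
  nc <- 5
  dist <- outer(seq_len(nc), rep(1, 3)) * 0.5    # identical spacing per dim
  cand <- data.frame(group = 1:nc, source_id = paste0("it", 1:nc),
                     start = 1L, length = 8L)
  cs <- structure(list(candidates = cand, dist = dist),
                  class = "candidate_set")
  ww <- s_wborda_rank(cs, rep(1 / 3, 3), k = nc)
  rk <- lapply(1:3, function(j) paste0("it", order(dist[, j])))
  bb <- s_borda_rank(rk, n_dims = 3, k = nc)
  expect_equal(ww$id, bb$id)   # order agreement, not score equality
})

test_that("distance gaps break ties the positional count cannot", {
  # four racers tie at 10 classical points across four rounds; distinct
  # per-round gaps must separate them in the weighted scheme
  rounds <- list(c("r1", "r2", "r3", "r4"), c("r2", "r1", "r4", "r3"),
                 c("r4", "r3", "r1", "r2"), c("r3", "r4", "r2", "r1"))
  expect_equal(unname(borda_scores(rounds, 4)), rep(10, 4))
  set.seed(97)
  ids <- c("r1", "r2", "r3", "r4")
  dist <- matrix(NA_real_, 4, 4, dimnames = list(ids, NULL))
  for (j in seq_along(rounds)) {
    dist[rounds[[j]], j] <- cumsum(runif(4, 0.1, 1))   # distinct gaps
  }
  cand <- data.frame(group = 1:4, source_id = ids, start = 1L, length = 5L)
  cs <- structure(list(candidates = cand, dist = dist),
                  class = "candidate_set")
  sc <- s_wborda_rank(cs, rep(0.25, 4), k = 4)$score
  expect_equal(length(unique(sc)), 4L)
})
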