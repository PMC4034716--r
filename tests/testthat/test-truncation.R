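test_that("grouping is a partition driven by the strict half-length rule", {
  l <- 20L
  # overlap exactly l/2 is not enough: two singletons
  m <- data.frame(dim = c(1L, 2L), source_id = "s", start = c(10L, 20L),
                  length = l, distance = c(0.1, 0.2))
  g <- group_matches(m, l = l)
  expect_equal(length(unique(g$group)), 2L)
  # one point more of overlap joins them
  m$start <- c(10L, 19L)
  g <- group_matches(m, l = l)
  expect_equal(length(unique(g$group)), 1L)
  # chain A-B, B-C with A,C disjoint is still one component
  m3 <- data.frame(dim = 1:3, source_id = "s", start = c(1L, 8L, 16L),
                   length = l, distance = 0.1)
  g3 <- group_matches(m3, l = l)
  expect_equal(length(unique(g3$group)), 1L)
  # matches from different sources never join
  m3$source_id <- c("s", "s", "t")
  g3 <- group_matches(m3, l = l)
  expect_equal(length(unique(g3$group)), 2L)
  # partition: every match appears exactly once
  expect_equal(nrow(g3), 3L)
})

test_that("connected components agree with the igraph oracle", {
  skip_if_not_installed("igraph")
  set.seed(61)
  l <- 10L
  for (rep in 1:20) {
    nm <- sample(4:12, 1)
    m <- data.frame(dim = sample(1:3, nm, TRUE), source_id = "s",
                    start = sample(1:60, nm, TRUE), length = l,
                    distance = runif(nm))
    got <- group_matches(m, l = l)
    adj <- outer(seq_len(nm), seq_len(nm), Vectorize(function(i, j) {
      ov <- max(0, min(m$start[i], m$start[j]) + l - max(m$start[i], m$start[j]))
      i != j && 2 * ov > l
    }))
    comp <- igraph::components(igraph::graph_from_adjacency_matrix(adj, "undirected"))
    # identical partitions: same pairs together
    same <- function(f) outer(f, f, "==")
    expect_equal(same(got$group), same(comp$membership), ignore_attr = TRUE)
  }
})

test_that("the nine-match scenario yields five groups, three surviving", {
  m <- nine_match_scenario()
  g <- group_matches(m, l = 20L)
  expect_equal(length(unique(g$group)), 5L)
  # membership by dim:start — chained triple, two pairs, two singletons
  sets <- lapply(split(seq_len(nrow(g)), g$group), function(i)
    sort(paste0(g$dim[i], ":", g$start[i])))
  has_set <- function(want) any(vapply(sets, identical, logical(1), sort(want)))
  expect_true(has_set(c("1:10", "2:15", "3:22")))
  expect_true(has_set(c("1:60", "2:63")))
  expect_true(has_set(c("1:100", "3:95")))
  expect_true(has_set("3:150"))
  expect_true(has_set("2:200"))
  surv <- delete_isolated(g, n_dims = 3L)
  expect_equal(length(unique(surv$group)), 3L)
  # exactly the two singletons were deleted
  expect_false(any(surv$start %in% c(150L, 200L)))
})

test_that("the isolated-group threshold is kept iff 2*members >= dims", {
  g <- group_matches(data.frame(dim = c(1L, 2L), source_id = "s",
                                start = c(5L, 6L), length = 10L,
                                distance = 0.1), l = 10L)
  expect_equal(nrow(delete_isolated(g, n_dims = 3L)), 2L)  # 2*2 >= 3: kept
  expect_equal(nrow(delete_isolated(g, n_dims = 4L)), 2L)  # 2*2 >= 4: kept
  expect_equal(nrow(delete_isolated(g, n_dims = 5L)), 0L)  # 2*2 <  5: deleted
  # deletion monotonicity: raising the dimension count never adds survivors
  set.seed(67)
  m <- data.frame(dim = sample(1:4, 10, TRUE), source_id = "s",
                  start = sample(1:50, 10), length = 10L, distance = runif(10))
  g <- group_matches(m, l = 10L)
  nsurv <- sapply(1:6, function(nd)
    length(unique(delete_isolated(g, nd)$group)))
  expect_true(all(diff(nsurv) <= 0))
})

test_that("alignment averages starts (half up), reuses stored distances", {
  set.seed(71)
  l <- 12L
  long_pc <- matrix(rnorm(200 * 2), 200, 2)
  qpc <- matrix(rnorm(l * 2), l, 2)
  m <- data.frame(dim = c(1L, 2L), source_id = "long", start = c(10L, 20L),
                  length = l, distance = c(0.25, 0.5))
  g <- group_matches(m, l = l)       # overlap 2 <= 6: actually two groups
  # force one group to exercise the mean rule
  g$group <- 1L
  cs <- align_groups(g, qpc, long_pc)
  expect_equal(cs$candidates$start, 15L)         # mean(10, 20) = 15
  expect_equal(cs$dist[1, ], c(0.25, 0.5))       # both dims reused
  # half-up rounding: starts 10 and 21 average 15.5 -> 16
  g$start <- c(10L, 21L)
  expect_equal(align_groups(g, qpc, long_pc)$candidates$start, 16L)
  # a dimension with no member is recomputed by DTW at the aligned window
  g2 <- data.frame(dim = 1L, source_id = "long", start = 40L, length = l,
                   distance = 0.1, group = 1L)
  cs2 <- align_groups(g2, qpc, long_pc)
  expect_equal(cs2$dist[1, 1], 0.1)
  expect_equal(cs2$dist[1, 2],
               dtw_distance(qpc[, 2], long_pc[40:51, 2]))
  # recompute_all overrides the reuse
  cs3 <- align_groups(g2, qpc, long_pc, recompute_all = TRUE)
  expect_equal(cs3$dist[1, 1], dtw_distance(qpc[, 1], long_pc[40:51, 1]))
})

test_that("groups running past the series end are dropped with a warning", {
  l <- 12L
  long_pc <- matrix(rnorm(30 * 2), 30, 2)
  qpc <- matrix(rnorm(l * 2), l, 2)
  g <- data.frame(dim = 1L, source_id = "long", start = 25L, length = l,
                  distance = 0.1, group = 1L)
  expect_warning(cs <- align_groups(g, qpc, long_pc), "dropped")
  expect_equal(nrow(cs$candidates), 0L)
})

test_that("whole matching degenerates to item identity", {
  set.seed(73)
  items_pc <- list(a = matrix(rnorm(20), 10, 2), b = matrix(rnorm(20), 10, 2))
  m <- data.frame(dim = c(1L, 2L, 1L), source_id = c("a", "a", "b"),
                  start = 1L, length = 10L, distance = c(0.1, 0.2, 0.3))
  g <- group_matches(m)
  expect_equal(length(unique(g$group)), 2L)
  expect_equal(unique(split(g$source_id, g$group)[[1]]), "a")
  qpc <- matrix(rnorm(20), 10, 2)
  cs <- align_groups(delete_isolated(g, 2L), qpc, items_pc)
  # alignment is the identity: whole items at start 1
  expect_true(all(cs$candidates$start == 1L))
})

test_that("per-dimension reordering matches a brute-force sort", {
  set.seed(79)
  for (rep in 1:10) {
    nc <- 6
    cs <- structure(list(
      candidates = data.frame(group = 1:nc, source_id = "s",
                              start = sample(100, nc), length = 10L),
      dist = matrix(runif(nc * 3), nc, 3)), class = "candidate_set")
    rk <- reorder_candidates(cs)
    for (i in 1:3) {
      expect_equal(cs$dist[rk[[i]], i], sort(cs$dist[, i]))
    }
  }
  # ties break by earlier start
  cs <- structure(list(
    candidates = data.frame(group = 1:2, source_id = "s",
                            start = c(50L, 10L), length = 10L),
    dist = matrix(c(0.5, 0.5), 2, 1)), class = "candidate_set")
  expect_equal(reorder_candidates(cs)[[1]], c(2L, 1L))
})
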