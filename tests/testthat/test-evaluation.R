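worked_tm <- function() {
  vals <- matrix(c("A", "A", "B", "C"), ncol = 1,
                 dimnames = list(paste0("s", 1:4), "t1"))
  trait_matrix(vals)
}

test_that("WCE and its Gini twin reproduce the hand-computed example", {
  tm <- worked_tm()
  split2 <- c(1L, 1L, 2L, 2L)
  expect_equal(wce(tm, rep(1L, 4)), 1.5 * log(2))
  expect_equal(wce(tm, split2), 0.5 * log(2))
  expect_equal(gini_within(tm, rep(1L, 4)), 0.625)
  ## single-valued clusters and all-singleton partitions are at zero
  expect_equal(wce(tm, c(1L, 1L, 2L, 3L)), 0)
  expect_equal(wce(tm, 1:4), 0)
  expect_equal(gini_within(tm, c(1L, 1L, 2L, 3L)), 0)
  ## independent slow oracle agrees on random partitions
  big <- rand_tm(20, 5, K = 4, seed = 3)
  for (seed in 1:5) {
    set.seed(seed)
    part <- sample(1:4, 20, replace = TRUE)
    expect_equal(wce(big, part), naive_wce(big, part))
  }
  expect_error(wce(big, c(a = 1L)), "partition")
})

test_that("PSFE reproduces the worked value and its algebraic identities", {
  tm <- worked_tm()
  cuts <- list(`1` = rep(1L, 4), `2` = c(1L, 1L, 2L, 2L))
  expect_equal(unname(psfe(tm, cuts)), 4.0)
  ## a split with no reduction in variability scores 0
  vals <- matrix(c("A", "B", "A", "B"), ncol = 1,
                 dimnames = list(paste0("s", 1:4), "t1"))
  tm2 <- trait_matrix(vals)
  flat <- list(`1` = rep(1L, 4), `2` = c(1L, 1L, 2L, 2L))
  expect_equal(unname(psfe(tm2, flat)), 0)
  ## a perfect cut (WCE = 0 with structure present) is ranked infinite
  perfect <- list(`1` = rep(1L, 4), `2` = c(1L, 2L, 1L, 2L))
  expect_equal(unname(psfe(tm2, perfect)), Inf)
})

test_that("delta-WCE is the successive difference on consecutive cuts", {
  tm <- worked_tm()
  w <- c(wce(tm, rep(1L, 4)), wce(tm, c(1L, 1L, 2L, 2L)))
  d <- delta_wce(1:2, w)
  expect_equal(unname(d), log(2))
  expect_equal(names(d), "2")
  expect_error(delta_wce(c(1, 3), w), "consecutive")
  ## identical rows: no structure, all deltas zero
  flat <- trait_matrix(matrix("A", 4, 2,
                              dimnames = list(paste0("s", 1:4), c("a", "b"))))
  dg <- hierarchical_cluster(dissimilarity(flat, "sm"), "average")
  w <- vapply(1:3, function(k) wce(flat, cut_tree(dg, k)), 0)
  expect_equal(unname(delta_wce(1:3, w)), c(0, 0))
})

test_that("select_k takes the PSFE argmax with deterministic tie-breaks", {
  expect_equal(select_k(c(`2` = 1, `3` = 5, `4` = 2)), 3L)
  expect_equal(select_k(c(`2` = 5, `3` = 5, `4` = 2)), 2L)       # tie: smaller k
  expect_equal(select_k(c(`2` = 9, `3` = 5), k_range = 2), 2L)
  expect_equal(select_k(c(`2` = 9, `3` = 8, `4` = 7)), 2L)       # decreasing
  expect_equal(select_k(c(`2` = 1, `3` = Inf, `4` = 2)), 3L)     # perfect wins
  expect_error(select_k(c(`2` = NA_real_)), "undefined")
})

test_that("WCE never increases when a cluster is split further", {
  tm <- rand_tm(24, 5, K = 3, seed = 4)
  for (seed in 1:20) {
    set.seed(seed)
    part <- sample(1:3, 24, replace = TRUE)
    w0 <- wce(tm, part)
    ## split one nonempty cluster in two at random
    cl <- sample(unique(part), 1)
    rows <- which(part == cl)
    if (length(rows) < 2) next
    part2 <- part
    part2[sample(rows, ceiling(length(rows) / 2))] <- max(part) + 1L
    expect_lte(wce(tm, part2), w0 + 1e-12)
    expect_lte(gini_within(tm, part2), gini_within(tm, part) + 1e-12)
  }
})

test_that("adjusted Rand agrees with pair counting and reference code", {
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  for (seed in 1:10) {
    set.seed(seed)
    p1 <- sample(1:4, 50, replace = TRUE)
    p2 <- sample(1:3, 50, replace = TRUE)
    a <- adjusted_rand(p1, p2)
    expect_equal(a, pair_ari(p1, p2))
    if (requireNamespace("mclust", quietly = TRUE))
      expect_equal(a, mclust::adjustedRandIndex(p1, p2))
    ## symmetry and label-permutation invariance
    expect_equal(a, adjusted_rand(p2, p1))
    relab <- c(3, 1, 4, 2)[p1]
    expect_equal(adjusted_rand(relab, p2), a)
  }
  ## independent partitions hover around zero
  m <- mean(vapply(1:40, function(s) {
    set.seed(1000 + s)
    adjusted_rand(sample(1:3, 60, replace = TRUE),
                  sample(1:3, 60, replace = TRUE))
  }, 0))
  expect_lt(abs(m), 0.02)
  ## name-based alignment
  p1 <- c(a = 1, b = 1, c = 2)
  p2 <- c(c = 5, a = 7, b = 7)
  expect_equal(adjusted_rand(p1, p2), 1)
  expect_error(adjusted_rand(p1, c(a = 1, b = 1, z = 2)), "different")
})

test_that("the evaluation grid is complete and internally consistent", {
  g <- generate_traits(synthetic_spec(n_species = 40, n_traits = 6,
                                      categories = 3, theta = 0.9), seed = 19)
  ev <- evaluate_grid(g$tm, measures = c("sm", "goodall"),
                      linkages = c("complete", "average"), k_range = 2:6)
  expect_equal(nrow(ev), 2 * 2 * 5)
  ## WCE non-increasing in k within each combination; deltas consistent
  for (s in split(as.data.frame(ev), ev[c("measure", "linkage")])) {
    expect_true(all(diff(s$wce) <= 1e-12))
    expect_equal(-diff(s$wce), s$delta_wce[-1], tolerance = 1e-12)
    ## flagged optimum is the PSFE argmax
    expect_equal(s$k[s$optimal], select_k(stats::setNames(s$psfe, s$k)))
  }
  ## attached partitions match direct recomputation
  parts <- attr(ev, "partitions")
  d <- dissimilarity(g$tm, "goodall")
  expect_equal(parts[["goodall.average.3"]],
               cut_tree(hierarchical_cluster(d, "average"), 3))
})
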