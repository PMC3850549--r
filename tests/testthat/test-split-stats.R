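test_that("variance matches hand-computed values", {
  h <- toy_hierarchy()
  L <- rbind(close_labels(h, "A"), close_labels(h, "A"))
  expect_equal(variance(partition_stats(L, h$weights)), 0)

  # two examples {1,0} / {0,1}, unit weights: mean (.5,.5), Var = 0.5
  st <- partition_stats(rbind(c(1, 0), c(0, 1)), c(1, 1))
  expect_equal(variance(st), 0.5)

  # duplicating every example leaves the variance unchanged
  set.seed(3)
  L3 <- random_labels(7, 4)
  om <- runif(4, 0.2, 1)
  expect_equal(variance(partition_stats(L3, om)),
               variance(partition_stats(rbind(L3, L3), om)))

  expect_error(variance(partition_stats(L3[0, , drop = FALSE], om)), "empty")
})

test_that("autocorrelation hits its analytic endpoints and brute force", {
  om <- c(1, 1)
  # connected pairs identically labelled, >= 2 distinct vectors: A_Y = 1
  L <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  W <- matrix(0, 4, 4); W[1, 2] <- W[2, 1] <- 1; W[3, 4] <- W[4, 3] <- 1
  expect_identical(autocorrelation(partition_stats(L, om, W)), 1)

  # no edges: neutral 0.5
  expect_identical(autocorrelation(partition_stats(L, om, matrix(0, 4, 4))), 0.5)
  # single example / zero label variance: neutral 0.5
  expect_identical(autocorrelation(partition_stats(L[1, , drop = FALSE], om)), 0.5)
  expect_identical(
    autocorrelation(partition_stats(L[c(1, 1), ], om, random_adjacency(2, 1))),
    0.5)

  # 4-node path a-b-c-d, vectors [1,0],[1,0],[0,1],[0,1]: brute force
  Wp <- matrix(0, 4, 4)
  Wp[1, 2] <- Wp[2, 3] <- Wp[3, 4] <- 1
  Wp <- Wp + t(Wp)
  expect_equal(autocorrelation(partition_stats(L, om, Wp)),
               oracle_partition(L, om, Wp)$ay, tolerance = 1e-12)

  # invariant under uniform rescaling of all edge weights
  set.seed(8)
  for (r in 1:10) {
    Lr <- random_labels(12, 3)
    omr <- runif(3, 0.3, 1)
    Wr <- random_adjacency(12, 0.4, weighted = TRUE)
    a1 <- autocorrelation(partition_stats(Lr, omr, Wr))
    a2 <- autocorrelation(partition_stats(Lr, omr, 7.3 * Wr))
    expect_equal(a1, a2, tolerance = 1e-12)
  }
})

test_that("incremental moves agree with from-scratch recomputation", {
  set.seed(11)
  for (r in 1:30) {
    n <- sample(4:30, 1)
    K <- sample(2:10, 1)
    om <- runif(K, 0.1, 1)
    L <- random_labels(n, K)
    W <- random_adjacency(n, 0.3, weighted = r %% 2 == 0)
    sw <- split_sweep(L, om, W)
    # random move sequence, including back-and-forth moves
    for (m in 1:sample(3:12, 1)) {
      i <- sample(n, 1)
      if (sw$side[i] == 1L && sum(sw$side == 1L) > 1L) move_example(sw, i)
      else if (sw$side[i] == 2L) move_example(sw, i)
    }
    i1 <- which(sw$side == 1L); i2 <- which(sw$side == 2L)
    for (side in list(list(sw$s1, i1), list(sw$s2, i2))) {
      got <- side[[1]]; idx <- side[[2]]
      ref <- oracle_partition(L[idx, , drop = FALSE], om,
                              W[idx, idx, drop = FALSE])
      expect_equal(got$n, ref$n)
      expect_equal(got$ssd, ref$ssd, tolerance = 1e-9)
      expect_equal(got$w_sum, ref$w_sum, tolerance = 1e-9)
      expect_equal(got$wd_sum, ref$wd_sum, tolerance = 1e-9)
    }
  }
})

test_that("moving the sole example empties a partition; isolated moves leave edge sums", {
  om <- c(1, 0.5)
  L <- rbind(c(1, 0), c(0, 1), c(1, 1))
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 1  # example 3 isolated
  sw <- split_sweep(L, om, W, side = c(1L, 2L, 2L))
  move_example(sw, 1, to = 2L)
  expect_equal(sw$s1$n, 0L)
  expect_equal(sw$s1$ssd, 0)
  expect_equal(sw$s1$w_sum, 0)
  expect_equal(sw$s1$wd_sum, 0)

  # isolated example: edge sums unchanged, ssd changes
  before <- c(sw$s2$w_sum, sw$s2$wd_sum)
  ssd_before <- sw$s2$ssd
  move_example(sw, 3, to = 1L)
  expect_equal(c(sw$s2$w_sum, sw$s2$wd_sum), before)
  expect_false(isTRUE(all.equal(sw$s2$ssd, ssd_before)))

  expect_error(move_example(sw, 3, to = 1L), "already")
})

test_that("min-max normalization maps to [0,1] and is affine-invariant", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(5, 5)), c(0, 0))
  set.seed(4)
  v <- rnorm(20)
  expect_equal(minmax_normalize(v), minmax_normalize(3.2 * v + 17))
  expect_error(minmax_normalize(numeric(0)))
})
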