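test_that("class weights follow the decay recursion on trees and DAGs", {
  h <- parse_hierarchy(c("A", "B", "B/B1"), w0 = 0.75)
  expect_identical(h$classes, c("A", "B", "B1"))
  expect_equal(unname(h$weights), c(0.75, 0.75, 0.75^2))

  h1 <- parse_hierarchy("A", w0 = 0.3)
  expect_equal(unname(h1$weights), 0.3)

  # multi-parent class: w0 * mean of parent weights
  dag <- parse_hierarchy(data.frame(
    parent = c("root", "root", "B", "A", "B1"),
    child  = c("A", "B", "B1", "X", "X")), w0 = 0.5)
  expect_equal(dag$weights[["X"]], 0.5 * (0.5 + 0.25) / 2)  # 0.1875

  # weights strictly decrease from parent to child for w0 < 1
  cfg <- synth_config(depth = 3, branching = 2, seed = 4, dag_prob = 0.5)
  hd <- gen_hierarchy(cfg)
  for (cl in hd$classes) {
    for (p in hd$parents[[cl]]) {
      expect_lt(hd$weights[[cl]], hd$weights[[p]])
    }
  }
})

test_that("malformed hierarchies are rejected", {
  expect_error(parse_hierarchy(c("B/B1")), "undeclared parent")
  expect_error(parse_hierarchy(data.frame(parent = c("A", "B"),
                                          child = c("B", "A"))),
               "cycle")
  expect_error(parse_hierarchy(character(0)), "empty")
  expect_error(parse_hierarchy(c("A"), w0 = 1.2))
})

test_that("close_labels returns the ancestor closure and is idempotent", {
  h <- toy_hierarchy()
  v <- close_labels(h, "B1")
  expect_equal(unname(v), c(0L, 1L, 1L))
  expect_equal(unname(close_labels(h, character(0))), c(0L, 0L, 0L))
  # idempotent: closing an already-closed set reproduces it
  expect_identical(close_labels(h, h$classes[v > 0]), v)
  # monotone: superset input gives superset output
  v2 <- close_labels(h, c("A", "B1"))
  expect_true(all(v2 >= v))
  expect_error(close_labels(h, "Z"), "Z")
})

test_that("weighted distance matches the definition and is a metric", {
  h <- toy_hierarchy()
  v <- close_labels(h, "B1")
  expect_identical(weighted_distance(h, v, v), 0)
  expect_error(weighted_distance(h, c(1, 0), v), "length")

  # the printed 11-component example vectors differ in four components;
  # under uniform unit weights the distance is sqrt(4) = 2
  L1 <- c(1, 0, 0, 0, 1, 1, 1, 1, 0, 1, 1)
  L2 <- c(1, 1, 0, 0, 0, 0, 0, 1, 0, 1, 1)
  hu <- parse_hierarchy(paste0("k", 1:11), w0 = 0.75)
  hu$weights[] <- 1
  expect_equal(weighted_distance(hu, L1, L2), 2)

  # metric properties on random triples for strictly positive weights
  set.seed(1)
  h3 <- gen_hierarchy(synth_config(depth = 2, branching = 2, seed = 2))
  K <- length(h3$classes)
  for (r in 1:100) {
    a <- rbinom(K, 1, 0.5); b <- rbinom(K, 1, 0.5); c_ <- rbinom(K, 1, 0.5)
    dab <- weighted_distance(h3, a, b)
    dba <- weighted_distance(h3, b, a)
    expect_identical(dab, dba)
    expect_lte(weighted_distance(h3, a, c_), dab + weighted_distance(h3, b, c_) + 1e-12)
    if (all(a == b)) expect_identical(dab, 0) else expect_gt(dab, 0)
  }
})

test_that("most_specific_classes inverts close_labels", {
  h <- gen_hierarchy(synth_config(depth = 3, branching = 2, seed = 5))
  set.seed(2)
  for (r in 1:20) {
    picks <- sample(h$classes, sample(0:3, 1))
    v <- close_labels(h, picks)
    ms <- most_specific_classes(h, v)
    expect_identical(close_labels(h, ms), v)
  }
})
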