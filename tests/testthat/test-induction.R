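test_that("continuous tests are midpoints of consecutive distinct values", {
  tests <- enumerate_tests(c(1, 3, 3, 7))
  expect_equal(vapply(tests, `[[`, 0, "threshold"), c(2, 5))
  expect_length(enumerate_tests(c(4, 4, 4)), 0L)
  expect_length(enumerate_tests(c(NA_real_, NA_real_)), 0L)
  # missing values excluded from threshold computation
  tests2 <- enumerate_tests(c(1, NA, 3))
  expect_equal(tests2[[1L]]$threshold, 2)
})

test_that("discrete subsets form a greedy chain of proper subsets", {
  col <- c("a", "a", "b", "b", "c", "c")
  # score favouring {a, b}: greedy must start at a singleton, grow to
  # {a,b}, and never propose the full domain
  sc <- function(B) length(intersect(B, c("a", "b"))) - length(setdiff(B, c("a", "b")))
  tests <- enumerate_tests(col, score = sc)
  subsets <- lapply(tests, `[[`, "subset")
  expect_true(all(vapply(subsets, length, 0L) < 3L))
  expect_true(any(vapply(subsets, function(B) setequal(B, c("a", "b")), TRUE)))
  # without a score: singletons
  expect_equal(lapply(enumerate_tests(col), `[[`, "subset"),
               list("a", "b", "c"))
  expect_length(enumerate_tests(c("a", "a")), 0L)
})

test_that("F-test endpoints and level monotonicity", {
  expect_false(f_test_accept(1, 1, 50, 0.125))       # no reduction
  expect_true(f_test_accept(1, 0, 50, 0.001))        # perfect split
  expect_false(f_test_accept(0, 0, 50, 0.05))        # no variance at all
  # accepted at a stricter level implies accepted at a looser one
  levels <- c(0.001, 0.005, 0.01, 0.05, 0.1, 0.125)
  for (vc in c(0.5, 0.8, 0.9, 0.97)) {
    acc <- vapply(levels, function(s) f_test_accept(1, vc, 40, s), TRUE)
    expect_true(all(diff(acc) >= 0))  # once TRUE, stays TRUE as level grows
  }
})

test_that("pure nodes become single-leaf trees with the common vector", {
  h <- toy_hierarchy()
  L <- matrix(rep(close_labels(h, "B1"), 10), 10, byrow = TRUE)
  ds <- hmc_dataset(data.frame(x = rnorm(10)), L, h)
  fit <- build_tree(ds, alpha = 1)
  expect_true(fit$root$leaf)
  expect_equal(unname(fit$root$prototype), c(0, 1, 1))
})

test_that("a perfectly separating attribute is chosen at the root", {
  ds <- toy_dataset(6)
  fit <- build_tree(ds, alpha = 1, min_leaf = 2)
  expect_false(fit$root$leaf)
  expect_equal(fit$root$attr, "x1")
  expect_true(fit$root$left$leaf && fit$root$right$leaf)
  # child prototypes are the two pure class vectors
  expect_equal(sort(c(fit$root$left$prototype[["A"]],
                      fit$root$right$prototype[["A"]])), c(0, 1))
})

test_that("min_leaf bounds every leaf's training count", {
  b <- gen_benchmark(synth_config(seed = 21, n = 120))
  fit <- build_tree(b$dataset, b$network, alpha = 0.5, min_leaf = 7,
                    significance = 0.125)
  check <- function(node) {
    if (node$leaf) expect_gte(node$n, 7) else { check(node$left); check(node$right) }
  }
  check(fit$root)
})

test_that("alpha = 1 reproduces the variance-only learner exactly", {
  for (s in 31:34) {
    b <- gen_benchmark(synth_config(seed = s, n = 120))
    fit_a1 <- build_tree(b$dataset, b$network, alpha = 1, significance = 0.05)
    fit_var <- build_tree(b$dataset, NULL, heuristic = "variance",
                          significance = 0.05)
    strip <- function(n) {
      if (n$leaf) n else {
        n$h <- NULL
        n$left <- strip(n$left); n$right <- strip(n$right); n
      }
    }
    expect_identical(strip(fit_a1$root), strip(fit_var$root))
    expect_identical(predict(fit_a1, b$dataset$X), predict(fit_var, b$dataset$X))
  }
})

test_that("the heuristic is linear in alpha and matches from-scratch scoring", {
  b <- gen_benchmark(synth_config(seed = 41, n = 60))
  ds <- b$dataset
  test <- list(attr = "x1", kind = "continuous",
               threshold = median(ds$X$x1))
  h0 <- score_split(ds, test, b$network, alpha = 0)$h
  h1 <- score_split(ds, test, b$network, alpha = 1)$h
  h5 <- score_split(ds, test, b$network, alpha = 0.5)$h
  expect_equal(h5, (h0 + h1) / 2, tolerance = 1e-12)
  # alpha = 0 is the size-weighted mean child autocorrelation
  s <- score_split(ds, test, b$network, alpha = 0)
  expect_equal(h0, (s$n1 * s$ay1 + s$n2 * s$ay2) / (s$n1 + s$n2),
               tolerance = 1e-12)
})

test_that("training with alpha < 1 demands a network", {
  ds <- toy_dataset()
  expect_error(build_tree(ds, NULL, alpha = 0.5), "network")
  expect_silent(build_tree(ds, NULL, alpha = 1))
})

test_that("missing values route to the larger child and do not break prediction", {
  h <- toy_hierarchy()
  x <- c(1:8, NA, NA)
  L <- rbind(matrix(rep(close_labels(h, "A"), 5), 5, byrow = TRUE),
             matrix(rep(close_labels(h, "B1"), 5), 5, byrow = TRUE))
  ds <- hmc_dataset(data.frame(x = x), L, h)
  fit <- build_tree(ds, alpha = 1, min_leaf = 2, significance = 0.125)
  p <- predict(fit, data.frame(x = NA_real_))
  expect_false(anyNA(p))
})
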