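#' Predict per-class membership scores
#'
#' Routes each example down the tree and returns the prototype (mean
#' training class vector) of the leaf it reaches. Scores inherit the
#' ancestor-monotonicity of averaged closed label vectors:
#' score(ancestor) >= score(descendant) along every hierarchy edge, so
#' thresholding at any scalar cut yields an ancestor-closed label set.
#'
#' @param object a `pct` model.
#' @param newdata data.frame of attributes with the training schema
#'   (missing values allowed; extra columns ignored).
#' @param ... unused.
#' @return numeric matrix (examples x classes) of scores in [0, 1],
#'   colnames = class identifiers.
#' @export
predict.pct <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata, stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(object$schema), names(newdata))
  if (length(missing_cols) > 0L) {
    stop("newdata lacks attribute(s): ", paste(missing_cols, collapse = ", "))
  }
  K <- length(object$hierarchy$classes)
  out <- matrix(NA_real_, nrow(newdata), K,
                dimnames = list(rownames(newdata), object$hierarchy$classes))
  for (i in seq_len(nrow(newdata))) {
    node <- object$root
    while (!node$leaf) {
      v <- newdata[[node$attr]][i]
      go_left <- if (is.na(v)) {
        node$missing_route == "left"
      } else if (node$kind == "continuous") {
        if (!is.numeric(v)) stop("attribute '", node$attr, "' must be numeric")
        v <= node$threshold
      } else {
        as.character(v) %in% node$subset
      }
      node <- if (go_left) node$left else node$right
    }
    out[i, ] <- node$prototype
  }
  out
}

#' Threshold membership scores into a hierarchy-consistent label set
#'
#' A class is predicted when its score strictly exceeds its threshold.
#' With a scalar threshold the result is automatically ancestor-closed
#' (scores are monotone along the hierarchy); a per-class threshold map
#' must satisfy tau(ancestor) <= tau(descendant) and is rejected
#' otherwise.
#'
#' @param scores numeric vector of per-class scores (or a matrix, one row
#'   per example) aligned with the hierarchy.
#' @param tau scalar in [0, 1], or a named numeric vector over the classes.
#' @param hierarchy the `class_hierarchy` (needed to validate per-class
#'   thresholds; optional for scalar `tau` on named scores).
#' @return 0/1 vector (or matrix) of predicted labels.
#' @export
binarize <- function(scores, tau, hierarchy = NULL) {
  if (length(tau) > 1L) {
    if (is.null(hierarchy)) stop("per-class thresholds require the hierarchy")
    tau <- tau[hierarchy$classes]
    if (anyNA(tau)) stop("per-class thresholds must cover every class")
    for (cl in hierarchy$classes) {
      for (a in hierarchy$ancestors[[cl]]) {
        if (tau[[a]] > tau[[cl]]) {
          stop("threshold for ancestor '", a, "' exceeds threshold for '",
               cl, "'; ancestor thresholds must not be larger")
        }
      }
    }
  } else {
    stopifnot(tau >= 0, tau <= 1)
  }
  if (is.matrix(scores)) {
    pred <- matrix(0L, nrow(scores), ncol(scores), dimnames = dimnames(scores))
    pred[sweep(scores, 2L, rep_len(tau, ncol(scores)), ">")] <- 1L
    pred
  } else {
    as.integer(scores > rep_len(tau, length(scores)))
  }
}

#' Per-class precision-recall curve over the threshold grid
#'
#' Sweeps the decision threshold tau over `[0, 1]` with the given step
#' (both endpoints included; the default step 0.02 gives 51 points) and
#' records (recall, precision) of the resulting binary predictions for
#' one class. Precision at zero predicted positives is defined as 1. The
#' area is the trapezoidal integral over recall after adding the
#' (0, 1) anchor, de-duplicating points and sorting by recall.
#'
#' @param scores numeric vector of per-example scores for the class.
#' @param truth 0/1 vector of per-example ground truth for the class.
#' @param tau_step grid step, default 0.02.
#' @return list with `points` (data.frame tau/precision/recall) and
#'   `area` (`NA` when the class has no positive example).
#' @export
pr_curve <- function(scores, truth, tau_step = 0.02) {
  stopifnot(length(scores) == length(truth), length(scores) >= 1L)
  taus <- seq(0, 1, by = tau_step)
  P <- sum(truth > 0)
  prec <- rec <- numeric(length(taus))
  for (i in seq_along(taus)) {
    pred <- scores > taus[i]
    tp <- sum(pred & truth > 0)
    pp <- sum(pred)
    prec[i] <- if (pp == 0L) 1 else tp / pp
    rec[i] <- if (P == 0L) NA_real_ else tp / P
  }
  pts <- data.frame(tau = taus, precision = prec, recall = rec)
  if (P == 0L) return(list(points = pts, area = NA_real_))
  # trapezoid over recall; anchor precision 1 at recall 0
  rp <- unique(data.frame(recall = c(0, rec), precision = c(1, prec)))
  rp <- rp[order(rp$recall, -rp$precision), ]
  area <- 0
  for (i in seq_len(nrow(rp) - 1L)) {
    area <- area + (rp$recall[i + 1L] - rp$recall[i]) *
      (rp$precision[i + 1L] + rp$precision[i]) / 2
  }
  list(points = pts, area = area)
}

#' Average per-class AUPRC
#'
#' @param areas numeric vector of per-class areas; `NA` marks a class
#'   excluded from evaluation (no positive test examples).
#' @param mode `"uniform"` (each included class weighs 1/|C|) or
#'   `"frequency"` (classes weighted by their positive counts).
#' @param positives per-class positive counts, required for
#'   `"frequency"`.
#' @return scalar in [0, 1].
#' @export
aupr_average <- function(areas, mode = c("uniform", "frequency"),
                         positives = NULL) {
  mode <- match.arg(mode)
  inc <- !is.na(areas)
  if (!any(inc)) stop("no class has a defined PR area")
  if (mode == "uniform") {
    mean(areas[inc])
  } else {
    if (is.null(positives)) stop("frequency weighting needs positive counts")
    stopifnot(length(positives) == length(areas))
    w <- positives[inc]
    sum(areas[inc] * w) / sum(w)
  }
}

#' Evaluate score matrices against ground truth
#'
#' Builds the per-class PR curves and their averaged area. Classes with
#' no positive example in `truth` are excluded from the average (|C|
#' counts included classes only).
#'
#' @param scores numeric matrix (examples x classes).
#' @param truth 0/1 matrix of the same shape.
#' @param tau_step threshold grid step, default 0.02.
#' @param mode averaging mode, see [aupr_average()].
#' @return an `hmc_evaluation`: list with `per_class` (data.frame of
#'   class, positives, area), `average`, `mode`, `n_included`,
#'   `n_excluded`, `tau_step` and `curves` (per-class PR points).
#' @export
evaluate_scores <- function(scores, truth, tau_step = 0.02,
                            mode = c("uniform", "frequency")) {
  mode <- match.arg(mode)
  stopifnot(identical(dim(scores), dim(truth)))
  classes <- colnames(scores)
  curves <- vector("list", ncol(scores))
  areas <- numeric(ncol(scores))
  pos <- colSums(truth > 0)
  for (k in seq_len(ncol(scores))) {
    pr <- pr_curve(scores[, k], truth[, k], tau_step)
    curves[[k]] <- pr$points
    areas[k] <- pr$area
  }
  names(curves) <- classes
  per_class <- data.frame(class = classes, positives = as.integer(pos),
                          area = areas, stringsAsFactors = FALSE)
  structure(list(per_class = per_class,
                 average = aupr_average(areas, mode, positives = pos),
                 mode = mode,
                 n_included = sum(!is.na(areas)),
                 n_excluded = sum(is.na(areas)),
                 tau_step = tau_step,
                 curves = curves),
            class = "hmc_evaluation")
}

#' @export
print.hmc_evaluation <- function(x, ...) {
  cat("HMC evaluation: averaged AUPRC = ", format(x$average, digits = 4),
      " (", x$mode, " weights, ", x$n_included, " classes included, ",
      x$n_excluded, " excluded)\n", sep = "")
  invisible(x)
}

#' Select the F-test significance level by internal cross-validation
#'
#' Runs a seeded k-fold cross-validation on the training data for each
#' candidate level and returns the level with the largest mean averaged
#' AUPRC; ties go to the smaller level (the stronger pruning).
#'
#' @param dataset training `hmc_dataset`.
#' @param network training `hmc_network` or `NULL`.
#' @param levels candidate levels, default
#'   `c(0.001, 0.005, 0.01, 0.05, 0.1, 0.125)`.
#' @param folds number of folds, default 3.
#' @param seed integer seed for the fold shuffle.
#' @param ... passed to [build_tree()] (alpha, min_leaf, heuristic).
#' @return the selected level.
#' @export
select_significance <- function(dataset, network = NULL,
                                levels = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.125),
                                folds = 3L, seed = 1L, ...) {
  n <- length(dataset$ids)
  stopifnot(n >= folds)
  if (length(levels) == 1L) return(levels)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), n))
  score <- numeric(length(levels))
  for (li in seq_along(levels)) {
    aucs <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- which(fold_of != f)
      te <- which(fold_of == f)
      ds_tr <- dataset_subset(dataset, tr)
      net_tr <- if (!is.null(network)) network_subgraph(network, ds_tr$ids)
      fit <- build_tree(ds_tr, net_tr, significance = levels[li], ...)
      sc <- predict(fit, dataset$X[te, , drop = FALSE])
      tru <- dataset$labels[te, , drop = FALSE]
      aucs[f] <- if (all(colSums(tru > 0) == 0)) 0
                 else evaluate_scores(sc, tru)$average
    }
    score[li] <- mean(aucs)
  }
  # ties (within numerical noise) go to the smallest level
  ord <- order(levels)
  levels <- levels[ord]; score <- score[ord]
  levels[which.max(score > max(score) - 1e-12)]
}

# induced subgraph on the given ids (both endpoints inside)
network_subgraph <- function(net, ids) {
  keep <- net$edges$u %in% ids & net$edges$v %in% ids
  out <- net
  out$edges <- net$edges[keep, , drop = FALSE]
  out$nodes <- intersect(net$nodes, ids)
  out
}

#' Train/test holdout evaluation protocol
#'
#' Splits the dataset into a seeded training fraction (default 2/3) and a
#' held-out test part, restricts the network to training ids only (no
#' edge incident to a test example ever enters the training statistics),
#' trains a tree, and evaluates averaged AUPRC on the test part.
#' Alternatively, explicit id sets can be supplied for cross-network
#' scenarios such as training on highly connected genes and testing on
#' the weakly connected remainder.
#'
#' @param dataset an `hmc_dataset`.
#' @param network an `hmc_network` or `NULL`.
#' @param alpha,min_leaf,heuristic passed to [build_tree()].
#' @param significance a fixed F-test level, or `"cv"` to select one by
#'   internal 3-fold cross-validation over `levels`.
#' @param levels candidate levels for `significance = "cv"`.
#' @param train_frac training fraction, default 2/3.
#' @param train_ids,test_ids optional explicit id vectors overriding the
#'   random split.
#' @param tau_step,mode evaluation settings, see [evaluate_scores()].
#' @param seed integer seed for the split (and CV folds).
#' @return list with `model`, `evaluation`, `train_ids`, `test_ids`,
#'   `significance`.
#' @export
holdout_protocol <- function(dataset, network = NULL, alpha = 0.5,
                             min_leaf = 5L, significance = 0.05,
                             levels = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.125),
                             heuristic = "combined", train_frac = 2 / 3,
                             train_ids = NULL, test_ids = NULL,
                             tau_step = 0.02, mode = "uniform", seed = 1L) {
  n <- length(dataset$ids)
  if (is.null(train_ids)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    n_train <- round(train_frac * n)
    train_ids <- sort(sample(dataset$ids, n_train))
    test_ids <- setdiff(dataset$ids, train_ids)
  } else if (is.null(test_ids)) {
    test_ids <- setdiff(dataset$ids, train_ids)
  }
  tr_idx <- match(train_ids, dataset$ids)
  te_idx <- match(test_ids, dataset$ids)
  if (anyNA(tr_idx) || anyNA(te_idx)) stop("split ids not found in dataset")
  ds_tr <- dataset_subset(dataset, tr_idx)
  net_tr <- if (!is.null(network)) network_subgraph(network, ds_tr$ids)
  if (identical(significance, "cv")) {
    significance <- select_significance(ds_tr, net_tr, levels = levels,
                                        seed = seed, alpha = alpha,
                                        min_leaf = min_leaf,
                                        heuristic = heuristic)
  }
  model <- build_tree(ds_tr, net_tr, alpha = alpha, min_leaf = min_leaf,
                      significance = significance, heuristic = heuristic)
  scores <- predict(model, dataset$X[te_idx, , drop = FALSE])
  ev <- evaluate_scores(scores, dataset$labels[te_idx, , drop = FALSE],
                        tau_step = tau_step, mode = mode)
  list(model = model, evaluation = ev, train_ids = train_ids,
       test_ids = test_ids, significance = significance)
}

# save/restore .Random.seed so protocol seeding does not clobber the
# caller's RNG stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
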