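#' Candidate split tests for one attribute column
#'
#' Continuous attributes yield binary tests `X <= beta` where the
#' thresholds are the midpoints between consecutive distinct observed
#' values (b distinct values give b - 1 thresholds, in ascending order);
#' missing values are excluded from threshold computation. Discrete
#' attributes yield tests `X %in% B` with `B` a non-empty proper subset of
#' the active domain, grown greedily: starting from the best-scoring
#' single value, values are added while the supplied score improves. The
#' full domain is never a candidate. When no `score` function is given,
#' the singleton subsets are returned (in domain order).
#'
#' @param column attribute values over the examples at a node.
#' @param score optional function(subset) -> numeric used as the greedy
#'   criterion for discrete attributes (larger is better; `NA` to mark an
#'   inadmissible subset).
#' @return a list of tests, each a list with `kind`
#'   (`"continuous"`/`"discrete"`) and `threshold` or `subset`; empty when
#'   the column admits no test (constant or all missing).
#' @export
enumerate_tests <- function(column, score = NULL) {
  if (is.numeric(column)) {
    v <- sort(unique(column[!is.na(column)]))
    if (length(v) < 2L) return(list())
    mids <- (v[-length(v)] + v[-1L]) / 2
    lapply(mids, function(b) list(kind = "continuous", threshold = b))
  } else {
    dom <- sort(unique(as.character(column[!is.na(column)])))
    if (length(dom) < 2L) return(list())
    if (is.null(score)) {
      return(lapply(dom, function(v) list(kind = "discrete", subset = v)))
    }
    # greedy subset growth; proper subsets only
    best_v <- NULL
    best_s <- -Inf
    chain <- list()
    for (v in dom) {
      s <- score(v)
      chain[[length(chain) + 1L]] <- list(kind = "discrete", subset = v)
      if (!is.na(s) && s > best_s) { best_s <- s; best_v <- v }
    }
    if (is.null(best_v)) return(chain)
    B <- best_v
    repeat {
      remaining <- setdiff(dom, B)
      if (length(remaining) <= 1L) break  # adding the last value = full domain
      gain_v <- NULL
      gain_s <- best_s
      for (v in remaining) {
        cand <- sort(c(B, v))
        s <- score(cand)
        chain[[length(chain) + 1L]] <- list(kind = "discrete", subset = cand)
        if (!is.na(s) && s > gain_s) { gain_s <- s; gain_v <- v }
      }
      if (is.null(gain_v)) break
      B <- sort(c(B, gain_v))
      best_s <- gain_s
    }
    chain
  }
}

#' F-test acceptance of a variance reduction
#'
#' Decides whether splitting a node reduced the class-vector variance
#' significantly, using the one-way ANOVA convention for a binary split:
#' the between/within ratio
#' `F = (n - 2) * (var_parent - var_children_pooled) / var_children_pooled`
#' must exceed the upper critical value of the F distribution with
#' `(1, n - 2)` degrees of freedom at the given level. A split with no
#' reduction never passes; a perfect split (pooled child variance 0 with
#' positive parent variance) is always accepted; acceptance is monotone
#' in the significance level.
#'
#' @param var_parent variance at the node.
#' @param var_children_pooled size-weighted mean of the child variances.
#' @param n number of examples at the node (>= 2).
#' @param significance level in (0, 1).
#' @return logical.
#' @export
f_test_accept <- function(var_parent, var_children_pooled, n, significance) {
  stopifnot(n >= 2L, significance > 0, significance < 1)
  if (var_parent <= 0) return(FALSE)
  if (var_children_pooled <= 0) return(TRUE)
  if (var_children_pooled >= var_parent) return(FALSE)
  f_stat <- (n - 2) * (var_parent - var_children_pooled) / var_children_pooled
  f_stat > stats::qf(1 - significance, 1, n - 2)
}

# -- node-level split search ------------------------------------------------

# Evaluates all candidate tests at a node and returns the best admissible
# one together with its children statistics, or NULL.
#
# Two-pass scheme: pass 1 sweeps every candidate and records per-child
# sizes, variances and autocorrelations; min-max normalization of the
# variance term is then taken over {Var(U)} union all candidate child
# variances, and pass 2 combines the terms into the heuristic h. With
# heuristic = "variance" the score is the raw variance reduction (the
# classical network-oblivious learner); this ranks tests identically to
# the combined heuristic at alpha = 1, whose normalization is a positive
# affine map of the same reduction.
best_split <- function(ds, idx, W, params) {
  L <- ds$labels[idx, , drop = FALSE]
  omega <- ds$hierarchy$weights
  n_all <- length(idx)
  Wn <- if (!is.null(W)) W[idx, idx, drop = FALSE] else NULL
  node_stats <- partition_stats(L, omega, Wn)
  var_node <- variance(node_stats)
  use_net <- !is.null(Wn) && params$heuristic == "combined" && params$alpha < 1

  cands <- list()
  for (j in seq_along(ds$X)) {
    col <- ds$X[[j]][idx]
    obs <- which(!is.na(col))
    if (length(obs) < 2L) next
    n_miss <- n_all - length(obs)
    Lo <- L[obs, , drop = FALSE]
    Wo <- if (!is.null(Wn)) Wn[obs, obs, drop = FALSE] else NULL

    if (is.numeric(col)) {
      ord <- obs[order(col[obs])]
      vals <- col[ord]
      if (vals[1L] == vals[length(vals)]) next
      sw <- split_sweep(L[ord, , drop = FALSE], omega,
                        if (!is.null(Wn)) Wn[ord, ord, drop = FALSE],
                        side = rep(2L, length(ord)))
      for (t in seq_len(length(ord) - 1L)) {
        move_example(sw, t, to = 1L)  # sorted position t enters the left child
        if (vals[t] == vals[t + 1L]) next
        beta <- (vals[t] + vals[t + 1L]) / 2
        cands[[length(cands) + 1L]] <- list(
          attr = j, kind = "continuous", threshold = beta,
          n1 = sw$s1$n, n2 = sw$s2$n, n_miss = n_miss,
          var1 = variance_or0(sw$s1), var2 = variance_or0(sw$s2),
          ay1 = autocorrelation(sw$s1), ay2 = autocorrelation(sw$s2))
      }
    } else {
      dom <- sort(unique(as.character(col[obs])))
      if (length(dom) < 2L) next
      sw <- split_sweep(Lo, omega, Wo, side = rep(2L, length(obs)))
      colv <- as.character(col[obs])
      stash <- new.env(parent = emptyenv())
      score_subset <- function(B) {
        want1 <- colv %in% B
        for (t in which((sw$side == 1L) != want1)) {
          move_example(sw, t, to = if (want1[t]) 1L else 2L)
        }
        if (sw$s1$n == 0L || sw$s2$n == 0L) return(NA_real_)
        st <- list(n1 = sw$s1$n, n2 = sw$s2$n,
                   var1 = variance_or0(sw$s1), var2 = variance_or0(sw$s2),
                   ay1 = autocorrelation(sw$s1), ay2 = autocorrelation(sw$s2))
        stash[[paste(B, collapse = "\r")]] <- st
        # provisional score for greedy growth: same form as the final
        # heuristic, with the variance term normalized against the node
        # variance (final cross-attribute scoring re-normalizes globally)
        ntot <- st$n1 + st$n2
        red <- var_node - (st$n1 * st$var1 + st$n2 * st$var2) / ntot
        red_n <- if (var_node > 0) red / var_node else 0
        if (use_net) {
          (1 - params$alpha) * (st$n1 * st$ay1 + st$n2 * st$ay2) / ntot +
            params$alpha * red_n
        } else red_n
      }
      tests <- enumerate_tests(colv, score = score_subset)
      for (te in tests) {
        key <- paste(te$subset, collapse = "\r")
        st <- stash[[key]]
        if (is.null(st)) next
        cands[[length(cands) + 1L]] <- c(
          list(attr = j, kind = "discrete", subset = te$subset,
               n_miss = n_miss), st)
      }
    }
  }
  if (length(cands) == 0L) return(NULL)

  # min-max normalization of the variance term over all candidates + node
  all_var <- c(var_node,
               unlist(lapply(cands, function(cc) c(cc$var1, cc$var2))))
  dmin <- min(all_var); dmax <- max(all_var)
  normv <- function(v) if (dmax > dmin) (v - dmin) / (dmax - dmin) else 0

  best <- NULL
  for (cc in cands) {
    # route missing values to the child with more non-missing examples
    route <- if (cc$n1 >= cc$n2) "left" else "right"
    f1 <- cc$n1 + if (route == "left") cc$n_miss else 0L
    f2 <- cc$n2 + if (route == "right") cc$n_miss else 0L
    if (f1 < params$min_leaf || f2 < params$min_leaf) next
    ntot <- cc$n1 + cc$n2
    pooled <- (cc$n1 * cc$var1 + cc$n2 * cc$var2) / ntot
    if (!f_test_accept(var_node, pooled, n_all, params$significance)) next
    h <- if (params$heuristic == "variance") {
      var_node - pooled
    } else {
      (1 - params$alpha) * (cc$n1 * cc$ay1 + cc$n2 * cc$ay2) / ntot +
        params$alpha *
          (normv(var_node) - (cc$n1 * normv(cc$var1) + cc$n2 * normv(cc$var2)) / ntot)
    }
    cc$h <- h
    cc$route <- route
    cc$pooled_var <- pooled
    # strict > keeps the earliest candidate on ties: candidates are
    # generated in (attribute, threshold / subset-order) order, which is
    # exactly the documented deterministic tie-break
    if (is.null(best) || h > best$h) best <- cc
  }
  if (is.null(best)) return(NULL)
  best$var_node <- var_node
  best$ay_node <- autocorrelation(node_stats)
  best$norm_range <- c(dmin, dmax)
  best
}

variance_or0 <- function(stats) if (stats$n >= 1L) variance(stats) else 0

#' Score a single candidate split from scratch
#'
#' Reference (non-incremental) evaluation of the combined heuristic for
#' one test: both children's statistics are computed directly and
#' combined as
#' `h = alpha * (Var'(U) - (|U1| Var'(U1) + |U2| Var'(U2)) / |U|) +
#'     (1 - alpha) * (|U1| A_Y(U1) + |U2| A_Y(U2)) / |U|`.
#' `norm_range` supplies the (delta_min, delta_max) of the min-max
#' normalization of the variance term — during induction it spans the
#' child variances of all candidate tests at the node; when `NULL`, raw
#' (unnormalized) variances are used. `h` is linear in `alpha`.
#'
#' @param dataset an `hmc_dataset`.
#' @param test a list with `attr` (column name), `kind`, and `threshold`
#'   or `subset` (as produced by [enumerate_tests()]).
#' @param network an `hmc_network` or `NULL`.
#' @param alpha mixing coefficient in [0, 1].
#' @param idx optional row indices restricting the evaluation to a node.
#' @param norm_range optional `c(delta_min, delta_max)` for the variance
#'   normalization.
#' @return list with `h`, `n1`, `n2`, `var_node`, `var1`, `var2`, `ay1`,
#'   `ay2`; `h` is `NA` when a child is empty.
#' @export
score_split <- function(dataset, test, network = NULL, alpha = 0.5,
                        idx = seq_along(dataset$ids), norm_range = NULL) {
  col <- dataset$X[[test$attr]][idx]
  go_left <- if (test$kind == "continuous") col <= test$threshold
             else as.character(col) %in% test$subset
  keep <- !is.na(go_left)
  idx <- idx[keep]; go_left <- go_left[keep]
  omega <- dataset$hierarchy$weights
  W <- if (!is.null(network)) restrict(network, dataset$ids[idx])
  L <- dataset$labels[idx, , drop = FALSE]
  i1 <- which(go_left); i2 <- which(!go_left)
  if (length(i1) == 0L || length(i2) == 0L) return(list(h = NA_real_))
  s0 <- partition_stats(L, omega, W)
  s1 <- partition_stats(L[i1, , drop = FALSE], omega,
                        if (!is.null(W)) W[i1, i1, drop = FALSE])
  s2 <- partition_stats(L[i2, , drop = FALSE], omega,
                        if (!is.null(W)) W[i2, i2, drop = FALSE])
  n1 <- s1$n; n2 <- s2$n; n <- n1 + n2
  nv <- function(v) {
    if (is.null(norm_range) || norm_range[2L] <= norm_range[1L]) v
    else (v - norm_range[1L]) / (norm_range[2L] - norm_range[1L])
  }
  h <- (1 - alpha) * (n1 * autocorrelation(s1) + n2 * autocorrelation(s2)) / n +
    alpha * (nv(variance(s0)) - (n1 * nv(variance(s1)) +
                                 n2 * nv(variance(s2))) / n)
  list(h = h, n1 = n1, n2 = n2, var_node = variance(s0),
       var1 = variance(s1), var2 = variance(s2),
       ay1 = autocorrelation(s1), ay2 = autocorrelation(s2))
}

# -- tree construction ------------------------------------------------------

#' Learn a predictive clustering tree for HMC
#'
#' Top-down induction: at each node every candidate test on every
#' attribute is scored with the combined heuristic
#' `h = alpha * (Var'(U) - (|U1| Var'(U1) + |U2| Var'(U2)) / |U|) +
#'     (1 - alpha) * (|U1| A_Y(U1) + |U2| A_Y(U2)) / |U|`
#' so that `alpha = 1` degenerates to pure (normalized) variance
#' reduction — the classical network-oblivious learner — and `alpha = 0`
#' to pure autocorrelation. `Var'` is the min-max normalization of the
#' class-vector variance
#' over all candidate tests at the node and `A_Y` the network
#' autocorrelation of each child. A node becomes a leaf when its labels
#' are pure, when no admissible test leaves both children with at least
#' `min_leaf` examples, or when no test reduces variance significantly by
#' the F-test at level `significance`. Leaves store the mean class vector
#' of their training examples — per-class membership scores used for
#' prediction. The network influences only training: predictions depend
#' on attributes alone.
#'
#' @param dataset an `hmc_dataset` with ancestor-closed labels.
#' @param network an `hmc_network`, or `NULL`. Required when `alpha < 1`
#'   under the combined heuristic.
#' @param alpha mixing coefficient in [0, 1]: 1 = pure variance reduction
#'   (the classical network-oblivious learner), 0 = pure autocorrelation.
#'   Default 0.5.
#' @param min_leaf minimum training examples per leaf, default 5.
#' @param significance F-test level for pre-pruning, default 0.05.
#' @param heuristic `"combined"` (default) or `"variance"` — the latter
#'   scores raw variance reduction and ignores the network entirely.
#' @return an object of class `pct`: the tree (`root`), the hierarchy,
#'   the parameters, the attribute schema, and a per-node log of chosen
#'   tests with their heuristic components.
#' @export
build_tree <- function(dataset, network = NULL, alpha = 0.5, min_leaf = 5L,
                       significance = 0.05,
                       heuristic = c("combined", "variance")) {
  heuristic <- match.arg(heuristic)
  stopifnot(alpha >= 0, alpha <= 1, min_leaf >= 1)
  if (heuristic == "combined" && alpha < 1 && is.null(network)) {
    stop("alpha < 1 requires a network; pass one or set alpha = 1 ",
         "(variance-reduction only)")
  }
  params <- list(alpha = alpha, min_leaf = as.integer(min_leaf),
                 significance = significance, heuristic = heuristic)
  W <- if (!is.null(network)) restrict(network, dataset$ids) else NULL
  log_rows <- list()
  node_id <- 0L

  grow <- function(idx, depth) {
    node_id <<- node_id + 1L
    this_id <- node_id
    L <- dataset$labels[idx, , drop = FALSE]
    pure <- all(L[rep(1L, nrow(L)), , drop = FALSE] == L)
    make_leaf <- function() {
      list(leaf = TRUE, prototype = colMeans(L), n = length(idx))
    }
    if (pure || length(idx) < 2L * params$min_leaf) return(make_leaf())
    sp <- best_split(dataset, idx, W, params)
    if (is.null(sp)) return(make_leaf())
    col <- dataset$X[[sp$attr]][idx]
    go_left <- if (sp$kind == "continuous") col <= sp$threshold
               else as.character(col) %in% sp$subset
    go_left[is.na(go_left)] <- sp$route == "left"
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      node = this_id, depth = depth, n = length(idx),
      attribute = names(dataset$X)[sp$attr], kind = sp$kind,
      test = if (sp$kind == "continuous") format(sp$threshold)
             else paste(sp$subset, collapse = ","),
      h = sp$h, var_node = sp$var_node, pooled_var = sp$pooled_var,
      ay1 = sp$ay1, ay2 = sp$ay2,
      delta_min = sp$norm_range[1L], delta_max = sp$norm_range[2L],
      stringsAsFactors = FALSE)
    list(leaf = FALSE,
         attr = names(dataset$X)[sp$attr],
         kind = sp$kind,
         threshold = if (sp$kind == "continuous") sp$threshold else NULL,
         subset = if (sp$kind == "discrete") sp$subset else NULL,
         missing_route = sp$route,
         h = sp$h,
         n = length(idx),
         left = grow(idx[go_left], depth + 1L),
         right = grow(idx[!go_left], depth + 1L))
  }

  root <- grow(seq_along(dataset$ids), 0L)
  schema <- lapply(dataset$X, function(cl) {
    if (is.numeric(cl)) list(type = "numeric")
    else list(type = "discrete", levels = sort(unique(as.character(cl[!is.na(cl)]))))
  })
  structure(list(root = root,
                 hierarchy = dataset$hierarchy,
                 params = params,
                 schema = schema,
                 n_train = length(dataset$ids),
                 log = if (length(log_rows)) do.call(rbind, log_rows)
                       else data.frame()),
            class = "pct")
}

#' @export
print.pct <- function(x, ...) {
  cat("Predictive clustering tree for HMC\n")
  cat("  classes: ", length(x$hierarchy$classes),
      ", training examples: ", x$n_train, "\n", sep = "")
  cat("  alpha = ", x$params$alpha, ", min_leaf = ", x$params$min_leaf,
      ", F-test level = ", x$params$significance,
      ", heuristic = ", x$params$heuristic, "\n", sep = "")
  cat("  internal nodes: ", nrow(x$log), ", leaves: ",
      count_leaves(x$root), "\n", sep = "")
  invisible(x)
}

count_leaves <- function(node) {
  if (node$leaf) 1L else count_leaves(node$left) + count_leaves(node$right)
}
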