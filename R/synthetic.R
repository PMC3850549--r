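#' Configuration for the synthetic HMC benchmark generator
#'
#' The generator emulates the three ingredients of a gene-function
#' prediction task: a class hierarchy (FunCat-like tree, optionally a
#' GO-like DAG), a labelled dataset whose attributes are informative
#' about the classes, and an example-linkage network with planted
#' guilt-by-association structure — examples sharing a most-specific
#' class are linked with probability `p_in`, all other pairs with
#' `p_out`. Tying edge planting to most-specific classes (rather than any
#' shared ancestor) makes autocorrelation strongest for the deepest,
#' most local annotations, mirroring how functional coherence in PPI
#' networks concentrates in specific complexes and pathways.
#'
#' @param depth hierarchy depth D (>= 1).
#' @param branching branching factor b (>= 1).
#' @param n number of examples.
#' @param m_cont,m_disc numbers of continuous / discrete attributes.
#' @param pi_child probability a child class is kept given its parent
#'   (top-level classes kept with the same probability).
#' @param delta attribute effect size: positives of a class shift the
#'   mean of its associated continuous attributes by `delta` over
#'   unit-variance noise.
#' @param p_in,p_out edge probabilities for pairs that do / do not share a
#'   most-specific class (`0 <= p_out <= p_in <= 1`).
#' @param rho label-noise rate: fraction of label bits flipped before
#'   re-closing (`0 <= rho < 0.5`).
#' @param dag_prob probability that a non-top class gains a second parent
#'   from the previous level (0 = strict tree).
#' @param seed global integer seed; fans out to fixed per-component
#'   sub-seeds so e.g. adding attributes does not perturb network draws.
#' @return a `synth_config` list.
#' @export
synth_config <- function(depth = 2L, branching = 2L, n = 200L,
                         m_cont = 8L, m_disc = 2L, pi_child = 0.5,
                         delta = 1, p_in = 0.3, p_out = 0.01,
                         rho = 0.05, dag_prob = 0, seed = 1L) {
  stopifnot(depth >= 1, branching >= 1, n >= 1,
            p_out >= 0, p_in >= p_out, p_in <= 1,
            rho >= 0, rho < 0.5, pi_child > 0, pi_child <= 1,
            dag_prob >= 0, dag_prob <= 1)
  structure(list(depth = as.integer(depth), branching = as.integer(branching),
                 n = as.integer(n), m_cont = as.integer(m_cont),
                 m_disc = as.integer(m_disc), pi_child = pi_child,
                 delta = delta, p_in = p_in, p_out = p_out, rho = rho,
                 dag_prob = dag_prob, seed = as.integer(seed)),
            class = "synth_config")
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed %% .Machine$integer.max)
  expr
}

#' Generate a synthetic class hierarchy
#'
#' A complete `branching`-ary tree of the configured depth; class `x` at
#' level l has children `x.1 ... x.b`. With `dag_prob > 0` each non-top
#' class independently gains one extra parent drawn from the remaining
#' classes of the previous level, giving a GO-like DAG.
#'
#' @param cfg a `synth_config`.
#' @param w0 weight decay factor, default 0.75.
#' @return a `class_hierarchy`.
#' @export
gen_hierarchy <- function(cfg, w0 = 0.75) {
  with_seed(cfg$seed + 11L, {
    parent <- character(0)
    child <- character(0)
    prev <- character(0)
    for (lev in seq_len(cfg$depth)) {
      if (lev == 1L) {
        cur <- paste0("c", seq_len(cfg$branching))
        parent <- c(parent, rep("root", length(cur)))
        child <- c(child, cur)
      } else {
        cur <- character(0)
        for (p in prev) {
          kids <- paste0(p, ".", seq_len(cfg$branching))
          parent <- c(parent, rep(p, length(kids)))
          child <- c(child, kids)
          cur <- c(cur, kids)
        }
        if (cfg$dag_prob > 0 && length(prev) > 1L) {
          for (k in cur) {
            if (stats::runif(1) < cfg$dag_prob) {
              own <- parent[child == k]
              pool <- setdiff(prev, own)
              if (length(pool) > 0L) {
                extra <- pool[sample.int(length(pool), 1L)]
                parent <- c(parent, extra)
                child <- c(child, k)
              }
            }
          }
        }
      }
      prev <- cur
    }
    parse_hierarchy(data.frame(parent = parent, child = child,
                               stringsAsFactors = FALSE), w0 = w0)
  })
}

#' Generate a synthetic labelled HMC dataset
#'
#' Labels are sampled by top-down path propagation: each top-level class
#' is kept with probability `pi_child`, and each child with probability
#' `pi_child` given its parent was kept; the kept set is then
#' ancestor-closed. Each class is associated with a random subset of the
#' continuous attributes, whose means shift by `delta` for its positive
#' examples over standard normal noise; discrete attributes are tilted
#' towards a class-specific preferred category. Finally a fraction `rho`
#' of label bits is flipped and the labels are re-closed.
#'
#' @param h a `class_hierarchy` (typically from [gen_hierarchy()]).
#' @param cfg a `synth_config`.
#' @return an `hmc_dataset` with ids `e1 ... en`.
#' @export
gen_dataset <- function(h, cfg) {
  K <- length(h$classes)
  n <- cfg$n
  L <- with_seed(cfg$seed + 23L, {
    L <- matrix(0L, n, K, dimnames = list(NULL, h$classes))
    top <- h$classes[lengths(h$parents) == 0L]
    for (i in seq_len(n)) {
      kept <- character(0)
      frontier <- top[stats::runif(length(top)) < cfg$pi_child]
      while (length(frontier) > 0L) {
        kept <- c(kept, frontier)
        nxt <- character(0)
        for (p in frontier) {
          ch <- h$children[[p]]
          if (length(ch) > 0L) {
            nxt <- c(nxt, ch[stats::runif(length(ch)) < cfg$pi_child])
          }
        }
        frontier <- setdiff(unique(nxt), kept)
      }
      if (length(kept) > 0L) L[i, ] <- close_labels(h, kept)
    }
    L
  })
  X <- with_seed(cfg$seed + 37L, {
    Xc <- NULL
    if (cfg$m_cont > 0L) {
      # class -> attribute association map; every class touches >= 1 attribute
      A <- matrix(0, K, cfg$m_cont)
      for (k in seq_len(K)) {
        picks <- which(stats::runif(cfg$m_cont) < 0.25)
        if (length(picks) == 0L) picks <- sample.int(cfg$m_cont, 1L)
        A[k, picks] <- cfg$delta
      }
      Xc <- matrix(stats::rnorm(n * cfg$m_cont), n, cfg$m_cont) + L %*% A
      colnames(Xc) <- paste0("x", seq_len(cfg$m_cont))
    }
    Xd <- NULL
    if (cfg$m_disc > 0L) {
      lv <- c("a", "b", "c")
      Xd <- matrix("", n, cfg$m_disc)
      for (j in seq_len(cfg$m_disc)) {
        cls <- sample.int(K, 1L)           # the class this attribute reflects
        pref <- lv[sample.int(3L, 1L)]
        for (i in seq_len(n)) {
          p_pref <- if (L[i, cls] > 0) 0.3 + cfg$delta / (2 * (1 + cfg$delta))
                    else 1 / 3
          p_pref <- min(0.95, p_pref)
          Xd[i, j] <- if (stats::runif(1) < p_pref) pref
                      else sample(setdiff(lv, pref), 1L)
        }
      }
      colnames(Xd) <- paste0("d", seq_len(cfg$m_disc))
    }
    X <- as.data.frame(if (is.null(Xd)) Xc else if (is.null(Xc)) Xd
                       else cbind(as.data.frame(Xc), as.data.frame(Xd)),
                       stringsAsFactors = FALSE)
    X
  })
  if (cfg$rho > 0) {
    L <- with_seed(cfg$seed + 41L, {
      flip <- matrix(stats::runif(n * K) < cfg$rho, n, K)
      L2 <- ifelse(flip, 1L - L, L)
      for (i in seq_len(n)) {
        present <- h$classes[L2[i, ] > 0]
        L2[i, ] <- if (length(present) > 0L) close_labels(h, present)
                   else 0L
      }
      dimnames(L2) <- dimnames(L)
      L2
    })
  }
  hmc_dataset(X, L, h, ids = paste0("e", seq_len(n)))
}

#' Generate a synthetic example-linkage network
#'
#' Planted-partition surrogate for a PPI network: each unordered pair of
#' examples is linked with probability `p_in` when their label vectors
#' share at least one most-specific class, and with `p_out` otherwise.
#' All edges have weight 1.
#'
#' @param dataset an `hmc_dataset`.
#' @param cfg a `synth_config`.
#' @return an `hmc_network` (possibly with zero edges).
#' @export
gen_network <- function(dataset, cfg) {
  h <- dataset$hierarchy
  n <- length(dataset$ids)
  MS <- matrix(0L, n, length(h$classes), dimnames = list(NULL, h$classes))
  for (i in seq_len(n)) {
    ms <- most_specific_classes(h, dataset$labels[i, ])
    if (length(ms) > 0L) MS[i, ms] <- 1L
  }
  share <- (MS %*% t(MS)) > 0
  with_seed(cfg$seed + 53L, {
    u <- character(0); v <- character(0)
    if (n >= 2L) {
      pr <- ifelse(share, cfg$p_in, cfg$p_out)
      draws <- matrix(stats::runif(n * n), n, n)
      hit <- which(upper.tri(pr) & draws < pr, arr.ind = TRUE)
      if (nrow(hit) > 0L) {
        u <- dataset$ids[hit[, 1L]]
        v <- dataset$ids[hit[, 2L]]
      }
    }
    net <- if (length(u) > 0L) new_network(u, v, rep(1, length(u)))
           else structure(list(edges = data.frame(u = character(0),
                                                  v = character(0),
                                                  w = numeric(0),
                                                  stringsAsFactors = FALSE),
                               nodes = character(0)),
                          class = "hmc_network")
    net$mode <- "binary"
    net
  })
}

#' Generate a full synthetic benchmark instance
#'
#' Convenience wrapper producing the hierarchy, dataset and network of
#' one simulation run.
#'
#' @param cfg a `synth_config`.
#' @param w0 hierarchy weight decay, default 0.75.
#' @return list with `hierarchy`, `dataset`, `network`, `config`.
#' @export
gen_benchmark <- function(cfg = synth_config(), w0 = 0.75) {
  h <- gen_hierarchy(cfg, w0 = w0)
  ds <- gen_dataset(h, cfg)
  net <- gen_network(ds, cfg)
  list(hierarchy = h, dataset = ds, network = net, config = cfg)
}
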