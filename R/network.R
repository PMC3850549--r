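#' Example-linkage networks
#'
#' An `hmc_network` is an undirected, strictly-positively weighted graph
#' over example identifiers — typically a protein-protein interaction
#' network linking the genes of an HMC dataset. The network acts as
#' training-time background knowledge only: it shapes the split heuristic
#' through the autocorrelation term but is never consulted at prediction
#' time.
#'
#' @name hmc_network
NULL

new_network <- function(u, v, w) {
  # canonical unordered storage: u < v lexicographically
  swap <- u > v
  tmp <- u[swap]; u[swap] <- v[swap]; v[swap] <- tmp
  key <- paste(u, v, sep = "\r")
  if (anyDuplicated(key)) {
    # duplicate observations of the same interaction: keep the max weight
    w <- vapply(split(w, key), max, numeric(1L))[unique(key)]
    u <- u[!duplicated(key)]
    v <- v[!duplicated(key)]
  }
  structure(list(edges = data.frame(u = u, v = v, w = w,
                                    stringsAsFactors = FALSE),
                 nodes = sort(unique(c(u, v)))),
            class = "hmc_network")
}

#' Read an undirected edge list
#'
#' Parses whitespace-delimited `u v [w]` lines, the de-facto interchange
#' format of PPI exports. Lines starting with `#` and blank lines are
#' skipped. Self-loops are dropped with a warning; duplicate edges are
#' merged keeping the maximum weight. In `"binary"` mode (the default,
#' matching the usual treatment of PPI data) all retained edges get
#' weight 1 regardless of the weight column.
#'
#' @param path file path, or a character vector of lines.
#' @param mode `"binary"` or `"weighted"`.
#' @return an `hmc_network`.
#' @export
load_edgelist <- function(path, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines_raw <- lines
  keep <- !grepl("^\\s*(#|$)", lines_raw)
  idx <- which(keep)
  u <- character(0); v <- character(0); w <- numeric(0)
  drop_self <- 0L
  for (i in idx) {
    f <- strsplit(trimws(lines_raw[i]), "\\s+")[[1L]]
    if (length(f) < 2L || length(f) > 3L) {
      stop("malformed edge-list line ", i, ": '", lines_raw[i], "'")
    }
    wt <- if (length(f) == 3L) suppressWarnings(as.numeric(f[3L])) else 1
    if (is.na(wt)) stop("malformed weight on line ", i, ": '", lines_raw[i], "'")
    if (wt <= 0) stop("non-positive weight on line ", i, ": '", lines_raw[i], "'")
    if (f[1L] == f[2L]) { drop_self <- drop_self + 1L; next }
    u <- c(u, f[1L]); v <- c(v, f[2L]); w <- c(w, wt)
  }
  if (drop_self > 0L) {
    warning("dropped ", drop_self, " self-loop(s)")
  }
  if (mode == "binary") w <- rep(1, length(w))
  net <- new_network(u, v, w)
  net$mode <- mode
  net
}

#' Build a network from an edge data.frame
#'
#' @param edges data.frame with columns `u`, `v` and optionally `w`
#'   (default 1). Self-loops are rejected.
#' @return an `hmc_network`.
#' @export
as_network <- function(edges) {
  w <- if ("w" %in% names(edges)) as.numeric(edges$w) else rep(1, nrow(edges))
  if (any(w <= 0)) stop("edge weights must be strictly positive")
  u <- as.character(edges$u); v <- as.character(edges$v)
  if (any(u == v)) stop("self-loops are not allowed")
  new_network(u, v, w)
}

#' @export
print.hmc_network <- function(x, ...) {
  cat("Example-linkage network: ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges",
      if (!is.null(x$mode)) paste0(" (", x$mode, " weights)"), "\n", sep = "")
  invisible(x)
}

#' Restrict a network to an ordered set of example identifiers
#'
#' Returns the symmetric adjacency matrix over `ids`: entry (i, j) is the
#' edge weight between `ids[i]` and `ids[j]`, and 0 when the pair is not
#' linked or either endpoint lies outside `ids`. Edges crossing the
#' boundary of the id set therefore contribute nothing — the semantics
#' used when a tree node evaluates autocorrelation within a data
#' partition.
#'
#' @param net an `hmc_network`.
#' @param ids character vector of unique example identifiers.
#' @return a dense numeric `length(ids)` x `length(ids)` matrix with zero
#'   diagonal, dimnames = ids.
#' @export
restrict <- function(net, ids) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("ids must be unique")
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  iu <- match(net$edges$u, ids)
  iv <- match(net$edges$v, ids)
  keep <- !is.na(iu) & !is.na(iv)
  if (any(keep)) {
    W[cbind(iu[keep], iv[keep])] <- net$edges$w[keep]
    W[cbind(iv[keep], iu[keep])] <- net$edges$w[keep]
  }
  W
}

# degree of each id (number of incident edges), ids absent from the
# network have degree 0
network_degree <- function(net, ids) {
  ids <- as.character(ids)
  tab <- table(c(net$edges$u, net$edges$v))
  d <- as.integer(tab[ids])
  d[is.na(d)] <- 0L
  stats::setNames(d, ids)
}

#' Filter example ids by network connectivity
#'
#' Selects the ids with at least `min_degree` incident interactions — the
#' "highly connected" subset when `min_degree = 15`, the convention for
#' separating well-characterised hub genes from sparsely covered ones.
#' The complement of the result is the weakly connected subset.
#'
#' @param ids character vector of example identifiers.
#' @param net an `hmc_network`.
#' @param min_degree nonnegative integer, default 15.
#' @return the subset of `ids` meeting the degree threshold, in input order.
#' @export
degree_filter <- function(ids, net, min_degree = 15L) {
  stopifnot(min_degree >= 0)
  ids[network_degree(net, ids) >= min_degree]
}

#' Descriptive statistics of a network over a labelled dataset
#'
#' Computes the coverage descriptors used to characterise how informative
#' a PPI network is for a given annotation task:
#' \itemize{
#'   \item `pct_connected`: percent of dataset ids with at least one edge;
#'   \item `pct_function_relevant`: percent of edges (both endpoints in the
#'     dataset) whose two endpoints share at least one annotated class.
#'     Shared classes are counted over the full ancestor closure excluding
#'     the virtual root, which every example shares trivially;
#'   \item `avg_degree`: mean number of incident edges over dataset ids.
#' }
#'
#' @param net an `hmc_network`.
#' @param labels 0/1 label matrix with rownames = example ids (ancestor
#'   closed, columns = classes).
#' @return named list with the three statistics (percent scales 0-100).
#' @export
network_stats <- function(net, labels) {
  ids <- rownames(labels)
  if (is.null(ids) || nrow(labels) == 0L) stop("labels must be a non-empty matrix with id rownames")
  deg <- network_degree(net, ids)
  in_ds <- net$edges$u %in% ids & net$edges$v %in% ids
  eu <- net$edges$u[in_ds]
  ev <- net$edges$v[in_ds]
  if (length(eu) > 0L) {
    shared <- rowSums(labels[eu, , drop = FALSE] * labels[ev, , drop = FALSE]) > 0
    pct_rel <- 100 * mean(shared)
  } else {
    pct_rel <- 0
  }
  list(pct_connected = 100 * mean(deg >= 1L),
       pct_function_relevant = pct_rel,
       avg_degree = mean(deg))
}
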