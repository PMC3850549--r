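#' Class hierarchies for hierarchical multi-label classification
#'
#' A `class_hierarchy` represents the partially ordered label set of an HMC
#' task: a tree or DAG of classes rooted at an implicit virtual root
#' (`"root"`). Each class carries a positive weight used by the weighted
#' Euclidean distance between label vectors: top-level classes receive
#' `w0`, and every other class receives `w0` times the arithmetic mean of
#' its parents' weights, so weights decay with depth and deep, specific
#' annotations count less than broad ones.
#'
#' The virtual root is not a component of label vectors: it is present in
#' every annotation and would contribute nothing to distances or variances.
#'
#' @param spec either a character vector of slash-delimited class paths
#'   (e.g. `c("A", "B", "B/B1")`; every prefix must itself be declared), or
#'   a two-column data.frame / matrix of `parent`, `child` pairs where the
#'   parent name `"root"` denotes the virtual root.
#' @param w0 per-level weight decay factor, a real in (0, 1). Default 0.75.
#' @return an object of class `class_hierarchy` with elements
#'   `classes` (ordered character vector of the K class identifiers),
#'   `parents` (named list; `character(0)` marks a top-level class),
#'   `children`, `ancestors`, `descendants` (named lists, each excluding the
#'   class itself), `weights` (named numeric) and `w0`.
#' @examples
#' h <- parse_hierarchy(c("A", "B", "B/B1"), w0 = 0.75)
#' h$weights  # A = B = 0.75, B1 = 0.5625
#' @export
parse_hierarchy <- function(spec, w0 = 0.75) {
  stopifnot(is.numeric(w0), length(w0) == 1L, w0 > 0, w0 < 1)
  if (is.matrix(spec)) spec <- as.data.frame(spec, stringsAsFactors = FALSE)
  if (is.data.frame(spec)) {
    if (ncol(spec) < 2L) stop("parent-child spec needs two columns")
    parent <- as.character(spec[[1L]])
    child <- as.character(spec[[2L]])
    classes <- unique(child)
    if ("root" %in% classes) stop("'root' is reserved for the virtual root")
    parents <- lapply(classes, function(cl) {
      p <- unique(parent[child == cl])
      setdiff(p, "root")
    })
    names(parents) <- classes
    undeclared <- setdiff(unique(unlist(parents)), classes)
    if (length(undeclared) > 0L) {
      stop("undeclared parent class(es): ", paste(undeclared, collapse = ", "))
    }
  } else {
    spec <- as.character(spec)
    if (length(spec) == 0L) stop("empty hierarchy specification")
    classes <- character(0)
    parents <- list()
    for (path in spec) {
      parts <- strsplit(path, "/", fixed = TRUE)[[1L]]
      parts <- parts[nzchar(parts)]
      if (length(parts) == 0L) stop("empty class path")
      cl <- parts[length(parts)]
      par <- if (length(parts) > 1L) parts[length(parts) - 1L] else character(0)
      if (length(par) > 0L && !(par %in% classes)) {
        stop("undeclared parent class(es): ", par,
             " (declare ancestors before descendants)")
      }
      if (cl %in% classes) {
        parents[[cl]] <- unique(c(parents[[cl]], par))
      } else {
        classes <- c(classes, cl)
        parents[[cl]] <- par
      }
    }
    parents <- parents[classes]
  }
  h <- structure(list(classes = classes, parents = parents, w0 = w0),
                 class = "class_hierarchy")
  h$children <- hier_invert(classes, parents)
  h$ancestors <- hier_closure(classes, parents)
  h$descendants <- hier_invert_closure(classes, h$ancestors)
  h$weights <- hier_weights(h, w0)
  h
}

# children relation from the parent map
hier_invert <- function(classes, parents) {
  ch <- stats::setNames(vector("list", length(classes)), classes)
  for (cl in classes) ch[[cl]] <- character(0)
  for (cl in classes) for (p in parents[[cl]]) ch[[p]] <- c(ch[[p]], cl)
  ch
}

# transitive ancestor sets; detects cycles along the way
hier_closure <- function(classes, parents) {
  anc <- stats::setNames(vector("list", length(classes)), classes)
  state <- stats::setNames(integer(length(classes)), classes) # 0 new 1 open 2 done
  visit <- function(cl) {
    if (state[[cl]] == 1L) stop("cycle detected at class '", cl, "'")
    if (state[[cl]] == 2L) return(anc[[cl]])
    state[[cl]] <<- 1L
    out <- character(0)
    for (p in parents[[cl]]) out <- union(out, c(p, visit(p)))
    anc[[cl]] <<- out
    state[[cl]] <<- 2L
    out
  }
  for (cl in classes) visit(cl)
  anc
}

hier_invert_closure <- function(classes, ancestors) {
  dec <- stats::setNames(vector("list", length(classes)), classes)
  for (cl in classes) dec[[cl]] <- character(0)
  for (cl in classes) for (a in ancestors[[cl]]) dec[[a]] <- c(dec[[a]], cl)
  dec
}

# w(c) = w0 * mean(w(parents)); top-level classes get w0. Evaluated in
# topological order (ancestors are always computable first).
hier_weights <- function(h, w0) {
  w <- stats::setNames(rep(NA_real_, length(h$classes)), h$classes)
  pending <- h$classes
  while (length(pending) > 0L) {
    progressed <- FALSE
    for (cl in pending) {
      ps <- h$parents[[cl]]
      if (length(ps) == 0L) {
        w[[cl]] <- w0
        progressed <- TRUE
      } else if (!anyNA(w[ps])) {
        w[[cl]] <- w0 * mean(w[ps])
        progressed <- TRUE
      }
    }
    pending <- names(w)[is.na(w)]
    if (!progressed && length(pending) > 0L) {
      stop("cannot resolve weights; cycle at class '", pending[[1L]], "'")
    }
  }
  w
}

#' @export
print.class_hierarchy <- function(x, ...) {
  n_top <- sum(lengths(x$parents) == 0L)
  is_dag <- any(lengths(x$parents) > 1L)
  cat("Class hierarchy (", if (is_dag) "DAG" else "tree", "): ",
      length(x$classes), " classes, ", n_top, " top-level, w0 = ",
      x$w0, "\n", sep = "")
  invisible(x)
}

#' Ancestor closure of a set of classes
#'
#' Encodes a set of (possibly most-specific) classes as a binary label
#' vector satisfying the hierarchical constraint: whenever a class is
#' present, so are all of its ancestors. Idempotent on already-closed sets.
#'
#' @param h a `class_hierarchy`.
#' @param most_specific character vector of class identifiers (may be empty).
#' @return named integer vector of 0/1 over `h$classes`, in hierarchy order.
#' @export
close_labels <- function(h, most_specific) {
  most_specific <- as.character(most_specific)
  unknown <- setdiff(most_specific, h$classes)
  if (length(unknown) > 0L) {
    stop("unknown class identifier(s): ", paste(unknown, collapse = ", "))
  }
  keep <- unique(c(most_specific, unlist(h$ancestors[most_specific])))
  stats::setNames(as.integer(h$classes %in% keep), h$classes)
}

#' Hierarchy-weighted Euclidean distance between label vectors
#'
#' d(L1, L2) = sqrt(sum_k w(c_k) * (L1_k - L2_k)^2), where the class weights
#' decay with depth so disagreement on broad classes costs more than
#' disagreement on specific ones.
#'
#' @param h a `class_hierarchy`.
#' @param L1,L2 0/1 vectors aligned with `h$classes`.
#' @return a nonnegative scalar; 0 iff the vectors are equal.
#' @export
weighted_distance <- function(h, L1, L2) {
  if (length(L1) != length(h$classes) || length(L2) != length(h$classes)) {
    stop("label vector length does not match the hierarchy (K = ",
         length(h$classes), ")")
  }
  sqrt(sum(h$weights * (L1 - L2)^2))
}

#' Most specific classes of a closed label vector
#'
#' Returns the classes present in `bits` that have no present descendant,
#' i.e. the minimal generating set whose ancestor closure is `bits`.
#'
#' @param h a `class_hierarchy`.
#' @param bits 0/1 vector aligned with `h$classes`.
#' @return character vector of class identifiers.
#' @export
most_specific_classes <- function(h, bits) {
  present <- h$classes[bits > 0]
  keep <- vapply(present, function(cl) {
    !any(h$descendants[[cl]] %in% present)
  }, logical(1L))
  present[keep]
}

# checks that every row of a 0/1 label matrix is ancestor-closed
labels_closed <- function(h, L) {
  for (cl in h$classes) {
    for (p in h$parents[[cl]]) {
      if (any(L[, cl] > L[, p])) return(FALSE)
    }
  }
  TRUE
}
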