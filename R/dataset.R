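#' HMC dataset container
#'
#' Bundles a mixed-type attribute table, an ancestor-closed 0/1 label
#' matrix and the class hierarchy. Examples are identified by id;
#' networks reference examples by these ids, never by row order.
#'
#' @param X data.frame of descriptive attributes (numeric columns and
#'   character/factor columns; `NA` marks a missing value).
#' @param labels 0/1 matrix, one row per example, columns aligned with
#'   `hierarchy$classes`; every row must satisfy the hierarchical
#'   constraint (ancestors of any present class are present).
#' @param hierarchy a `class_hierarchy`.
#' @param ids character vector of unique example identifiers; defaults to
#'   rownames of `X` or the row index.
#' @return an object of class `hmc_dataset` with elements `X`, `labels`,
#'   `ids`, `hierarchy`.
#' @export
hmc_dataset <- function(X, labels, hierarchy, ids = NULL) {
  X <- as.data.frame(X, stringsAsFactors = FALSE)
  labels <- as.matrix(labels)
  if (is.null(ids)) {
    ids <- rownames(X)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  }
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("example ids must be unique")
  if (nrow(X) != nrow(labels) || nrow(X) != length(ids)) {
    stop("X, labels and ids disagree on the number of examples")
  }
  if (ncol(labels) != length(hierarchy$classes)) {
    stop("label matrix has ", ncol(labels), " columns but the hierarchy has ",
         length(hierarchy$classes), " classes")
  }
  colnames(labels) <- hierarchy$classes
  rownames(labels) <- ids
  rownames(X) <- ids
  if (!labels_closed(hierarchy, labels)) {
    stop("labels violate the hierarchical constraint (a class is set ",
         "without one of its ancestors)")
  }
  # normalise discrete columns to character
  for (j in seq_along(X)) {
    if (is.factor(X[[j]])) X[[j]] <- as.character(X[[j]])
  }
  structure(list(X = X, labels = labels, ids = ids, hierarchy = hierarchy),
            class = "hmc_dataset")
}

#' @export
print.hmc_dataset <- function(x, ...) {
  num <- vapply(x$X, is.numeric, logical(1L))
  cat("HMC dataset: ", length(x$ids), " examples, ",
      sum(num), " continuous + ", sum(!num), " discrete attributes, ",
      length(x$hierarchy$classes), " classes\n", sep = "")
  invisible(x)
}

# row subset preserving structure
dataset_subset <- function(ds, idx) {
  hmc_dataset(ds$X[idx, , drop = FALSE],
              ds$labels[idx, , drop = FALSE],
              ds$hierarchy,
              ids = ds$ids[idx])
}
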