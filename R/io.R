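#' Run configuration with field-standard defaults
#'
#' Collects the tunable parameters of a training/evaluation run. The
#' defaults follow the established experimental conventions for this
#' family of learners: minimum of 5 examples per leaf, F-test
#' significance candidates {0.001, 0.005, 0.01, 0.05, 0.1, 0.125}
#' selected by internal 3-fold cross-validation, decision thresholds from
#' 0 to 1 in steps of 0.02, uniform 1/|C| weighting of per-class AUPRC,
#' binary edge weights, alpha = 0.5 and w0 = 0.75.
#'
#' @param alpha heuristic mixing coefficient in [0, 1].
#' @param w0 class-weight decay factor in (0, 1).
#' @param min_leaf minimum examples per leaf.
#' @param significance_levels candidate F-test levels.
#' @param tau_step threshold grid step.
#' @param aupr_mode `"uniform"` or `"frequency"`.
#' @param edge_mode `"binary"` or `"weighted"`.
#' @param seed integer seed.
#' @return a `run_config` list.
#' @export
run_config <- function(alpha = 0.5, w0 = 0.75, min_leaf = 5L,
                       significance_levels = c(0.001, 0.005, 0.01,
                                               0.05, 0.1, 0.125),
                       tau_step = 0.02,
                       aupr_mode = c("uniform", "frequency"),
                       edge_mode = c("binary", "weighted"),
                       seed = 1L) {
  stopifnot(alpha >= 0, alpha <= 1, w0 > 0, w0 < 1, min_leaf >= 1,
            all(significance_levels > 0), all(significance_levels < 1),
            tau_step > 0, tau_step <= 1)
  structure(list(alpha = alpha, w0 = w0, min_leaf = as.integer(min_leaf),
                 significance_levels = significance_levels,
                 tau_step = tau_step,
                 aupr_mode = match.arg(aupr_mode),
                 edge_mode = match.arg(edge_mode),
                 seed = as.integer(seed)),
            class = "run_config")
}

# canonical slash path of a class via its first parent
class_path <- function(h, cl, parent = NULL) {
  p <- if (is.null(parent)) {
    ps <- h$parents[[cl]]
    if (length(ps) > 0L) ps[[1L]] else NULL
  } else parent
  if (is.null(p)) cl else paste0(class_path(h, p), "/", cl)
}

#' Read a parent-child hierarchy file
#'
#' Two-column whitespace/tab-delimited `parent child` lines, with
#' `"root"` naming the virtual root. `#` comments and blank lines are
#' skipped.
#'
#' @param path file path or character vector of lines.
#' @param w0 weight decay factor.
#' @return a `class_hierarchy`.
#' @export
read_hierarchy_tsv <- function(path, w0 = 0.75) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L) stop("malformed hierarchy line ", bad[1L])
  parse_hierarchy(data.frame(parent = vapply(parts, `[[`, "", 1L),
                             child = vapply(parts, `[[`, "", 2L),
                             stringsAsFactors = FALSE), w0 = w0)
}

#' Write a hierarchy as parent-child pairs
#' @param h a `class_hierarchy`.
#' @param path output file.
#' @export
write_hierarchy_tsv <- function(h, path) {
  lines <- unlist(lapply(h$classes, function(cl) {
    ps <- h$parents[[cl]]
    if (length(ps) == 0L) ps <- "root"
    paste(ps, cl, sep = "\t")
  }))
  writeLines(lines, path)
}

#' Read an ARFF file with a hierarchical class attribute
#'
#' Supports the CLUS-community ARFF dialect: one attribute is declared
#' `hierarchical` followed by a comma-separated list of slash-delimited
#' class paths (a class reached by several paths — a DAG — may be listed
#' once per parent). Data rows give an example's classes as an
#' `@`-separated list of class identifiers or paths, which are
#' ancestor-closed on load; `?` denotes a missing attribute value. An
#' attribute named `id` (string/character) supplies example identifiers;
#' otherwise the row index is used.
#'
#' @param path file path or character vector of lines.
#' @param w0 weight decay for the hierarchy built from the header.
#' @param hierarchy optional pre-built `class_hierarchy` overriding the
#'   header declaration.
#' @return list with `dataset` (an `hmc_dataset`) and `hierarchy`.
#' @export
read_arff_hmc <- function(path, w0 = 0.75, hierarchy = NULL) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[!grepl("^\\s*(%|$)", lines)]
  attr_lines <- grep("^\\s*@attribute\\s", lines, ignore.case = TRUE)
  data_at <- grep("^\\s*@data\\s*$", lines, ignore.case = TRUE)
  if (length(data_at) != 1L) stop("ARFF file needs exactly one @data section")
  attrs <- list()
  class_attr <- NULL
  for (i in attr_lines) {
    m <- regmatches(lines[i],
                    regexec("^\\s*@attribute\\s+(\\S+)\\s+(.*)$", lines[i],
                            ignore.case = TRUE))[[1L]]
    nm <- m[2L]
    decl <- trimws(m[3L])
    if (nm %in% vapply(attrs, `[[`, "", "name")) {
      stop("duplicate attribute name '", nm, "'")
    }
    if (grepl("^hierarchical\\s", decl, ignore.case = TRUE)) {
      if (!is.null(class_attr)) stop("multiple hierarchical attributes")
      paths <- trimws(strsplit(sub("^hierarchical\\s+", "", decl,
                                   ignore.case = TRUE), ",")[[1L]])
      class_attr <- list(name = nm, paths = paths[nzchar(paths)])
      attrs[[length(attrs) + 1L]] <- list(name = nm, type = "class")
    } else if (grepl("^(numeric|real|integer)$", decl, ignore.case = TRUE)) {
      attrs[[length(attrs) + 1L]] <- list(name = nm, type = "numeric")
    } else if (grepl("^string$", decl, ignore.case = TRUE)) {
      attrs[[length(attrs) + 1L]] <- list(name = nm, type = "string")
    } else if (grepl("^\\{.*\\}$", decl)) {
      lv <- trimws(strsplit(gsub("[{}]", "", decl), ",")[[1L]])
      attrs[[length(attrs) + 1L]] <- list(name = nm, type = "discrete",
                                          levels = lv)
    } else {
      stop("unsupported attribute declaration: ", decl)
    }
  }
  if (is.null(class_attr)) stop("no hierarchical class attribute declared")
  if (is.null(hierarchy)) hierarchy <- parse_hierarchy(class_attr$paths, w0 = w0)

  rows <- lines[(data_at + 1L):length(lines)]
  rows <- rows[nzchar(trimws(rows))]
  cells <- strsplit(rows, ",")
  p <- length(attrs)
  bad <- which(lengths(cells) != p)
  if (length(bad) > 0L) {
    stop("data row ", bad[1L], " has ", length(cells[[bad[1L]]]),
         " fields, expected ", p)
  }
  nmv <- vapply(attrs, `[[`, "", "name")
  cols <- vector("list", p)
  names(cols) <- nmv
  for (j in seq_len(p)) {
    raw <- trimws(vapply(cells, `[[`, "", j))
    cols[[j]] <- switch(attrs[[j]]$type,
      numeric = { x <- suppressWarnings(as.numeric(ifelse(raw == "?", NA, raw)))
                  if (any(is.na(x) & raw != "?")) {
                    stop("non-numeric value in numeric column '", nmv[j], "'")
                  }
                  x },
      class = raw,
      ifelse(raw == "?", NA_character_, raw))
  }
  label_raw <- cols[[class_attr$name]]
  K <- length(hierarchy$classes)
  L <- matrix(0L, length(rows), K, dimnames = list(NULL, hierarchy$classes))
  for (i in seq_along(label_raw)) {
    if (label_raw[i] %in% c("", "?", "root")) next
    toks <- strsplit(label_raw[i], "@", fixed = TRUE)[[1L]]
    cls <- vapply(toks, function(tk) {
      parts <- strsplit(tk, "/", fixed = TRUE)[[1L]]
      parts[length(parts)]
    }, "")
    if (!all(cls %in% hierarchy$classes)) {
      stop("data row ", i, ": undeclared class '",
           setdiff(cls, hierarchy$classes)[1L], "'")
    }
    L[i, ] <- close_labels(hierarchy, cls)
  }
  ids <- if ("id" %in% nmv && attrs[[which(nmv == "id")]]$type %in%
             c("string", "discrete")) {
    as.character(cols[["id"]])
  } else as.character(seq_along(rows))
  keep <- setdiff(nmv, c(class_attr$name, if ("id" %in% nmv) "id"))
  X <- as.data.frame(cols[keep], stringsAsFactors = FALSE, optional = TRUE)
  ds <- hmc_dataset(X, L, hierarchy, ids = ids)
  list(dataset = ds, hierarchy = hierarchy)
}

#' Write an HMC dataset in the hierarchical ARFF dialect
#'
#' Emits an `id` string attribute, the descriptive attributes, and the
#' hierarchical class attribute (one slash path per parent-child edge, in
#' class declaration order). Labels are written as the `@`-joined
#' most-specific classes of each example; missing attribute values as `?`.
#'
#' @param dataset an `hmc_dataset`.
#' @param path output file.
#' @param relation relation name, default `"hmc"`.
#' @export
write_arff_hmc <- function(dataset, path, relation = "hmc") {
  h <- dataset$hierarchy
  # one path per edge; classes in declaration order so a re-read aligns
  paths <- unlist(lapply(h$classes, function(cl) {
    ps <- h$parents[[cl]]
    if (length(ps) == 0L) cl
    else vapply(ps, function(p) paste0(class_path(h, p), "/", cl), "")
  }))
  out <- c(paste0("@relation ", relation), "",
           "@attribute id string")
  for (nm in names(dataset$X)) {
    col <- dataset$X[[nm]]
    out <- c(out, if (is.numeric(col)) paste0("@attribute ", nm, " numeric")
             else paste0("@attribute ", nm, " {",
                         paste(sort(unique(col[!is.na(col)])), collapse = ","),
                         "}"))
  }
  out <- c(out, paste0("@attribute class hierarchical ",
                       paste(paths, collapse = ",")),
           "", "@data")
  fmt_cell <- function(v) {
    if (is.na(v)) "?" else if (is.numeric(v)) format(v, digits = 17) else
      as.character(v)
  }
  for (i in seq_along(dataset$ids)) {
    ms <- most_specific_classes(h, dataset$labels[i, ])
    lab <- if (length(ms) == 0L) "root" else paste(ms, collapse = "@")
    cells <- vapply(names(dataset$X),
                    function(nm) fmt_cell(dataset$X[[nm]][i]), "")
    out <- c(out, paste(c(dataset$ids[i], cells, lab), collapse = ","))
  }
  writeLines(out, path)
}

#' Write a network as an edge list
#' @param net an `hmc_network`.
#' @param path output file.
#' @export
write_edgelist <- function(net, path) {
  writeLines(paste(net$edges$u, net$edges$v, format(net$edges$w, digits = 17)),
             path)
}

#' Write per-example scores as TSV
#'
#' One row per example: the id column followed by one score column per
#' class (header = class identifiers).
#'
#' @param scores numeric matrix with rownames = ids (or `ids` given).
#' @param path output file.
#' @param ids optional id vector overriding rownames.
#' @export
write_scores_tsv <- function(scores, path, ids = rownames(scores)) {
  if (is.null(ids)) ids <- as.character(seq_len(nrow(scores)))
  df <- data.frame(id = ids, scores, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a score TSV written by [write_scores_tsv()]
#' @param path input file.
#' @return numeric matrix with rownames = ids.
#' @export
read_scores_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  m
}

# -- model serialization ----------------------------------------------------

node_to_list <- function(node) {
  if (node$leaf) {
    list(leaf = TRUE, prototype = unname(node$prototype), n = node$n)
  } else {
    list(leaf = FALSE, attr = node$attr, kind = node$kind,
         threshold = node$threshold, subset = node$subset,
         missing_route = node$missing_route, h = node$h, n = node$n,
         left = node_to_list(node$left), right = node_to_list(node$right))
  }
}

node_from_list <- function(x, classes) {
  if (isTRUE(x$leaf)) {
    list(leaf = TRUE, prototype = stats::setNames(as.numeric(x$prototype),
                                                  classes),
         n = as.integer(x$n))
  } else {
    list(leaf = FALSE, attr = x$attr, kind = x$kind,
         threshold = if (!is.null(x$threshold)) as.numeric(x$threshold),
         subset = if (!is.null(x$subset)) as.character(x$subset),
         missing_route = x$missing_route, h = as.numeric(x$h),
         n = as.integer(x$n),
         left = node_from_list(x$left, classes),
         right = node_from_list(x$right, classes))
  }
}

#' Serialize a trained model to JSON
#'
#' Self-contained document: class hierarchy (classes in their canonical
#' order, parent map, w0), training parameters, attribute schema and the
#' tree with full-precision numbers, so that save -> load -> predict is
#' bit-identical in scores.
#'
#' @param model a `pct`.
#' @param path output file.
#' @export
save_model <- function(model, path) {
  h <- model$hierarchy
  doc <- list(
    format = "nhmc-pct",
    version = 1L,
    hierarchy = list(classes = h$classes,
                     parents = lapply(h$parents, as.list),
                     w0 = h$w0),
    params = model$params,
    schema = model$schema,
    n_train = model$n_train,
    tree = node_to_list(model$root))
  # I(17) significant digits: lossless double round-trip, so that
  # save -> load -> predict is bit-identical
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
}

#' Load a model serialized with [save_model()]
#' @param path input file.
#' @return a `pct`.
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "nhmc-pct")) stop("not an nhmc model file")
  classes <- unlist(doc$hierarchy$classes)
  pairs <- do.call(rbind, lapply(classes, function(cl) {
    ps <- unlist(doc$hierarchy$parents[[cl]])
    if (length(ps) == 0L) ps <- "root"
    data.frame(parent = ps, child = cl, stringsAsFactors = FALSE)
  }))
  h <- parse_hierarchy(pairs, w0 = doc$hierarchy$w0)
  stopifnot(identical(h$classes, classes))
  schema <- lapply(doc$schema, function(s) {
    list(type = s$type,
         levels = if (!is.null(s$levels)) unlist(s$levels))
  })
  structure(list(root = node_from_list(doc$tree, classes),
                 hierarchy = h,
                 params = lapply(doc$params, function(v) v),
                 schema = schema,
                 n_train = doc$n_train,
                 log = data.frame()),
            class = "pct")
}

#' Write an evaluation report as JSON
#' @param evaluation an `hmc_evaluation`.
#' @param path output file.
#' @export
write_report_json <- function(evaluation, path) {
  doc <- list(average_auprc = evaluation$average,
              mode = evaluation$mode,
              n_included = evaluation$n_included,
              n_excluded = evaluation$n_excluded,
              tau_step = evaluation$tau_step,
              per_class = evaluation$per_class)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
}
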