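#' Expression matrix with sample class labels
#'
#' Bundles a probe-by-sample matrix of expression intensities with probe
#' identifiers, sample identifiers and (optionally) a per-sample class label.
#' This is the container every analysis function in the package operates on.
#' Values are kept on the scale they were loaded on; no transformation or
#' renormalisation is applied.
#'
#' @param values Numeric matrix, probes in rows, samples in columns. Must be
#'   free of missing values.
#' @param probe_ids Character vector of unique probe identifiers, one per row.
#'   Defaults to the rownames of `values`.
#' @param sample_ids Character vector of unique sample identifiers, one per
#'   column. Defaults to the colnames of `values`.
#' @param labels Optional per-sample class, each `"control"` or `"case"`.
#'   Either unnamed (in column order) or named by sample id. When given, both
#'   classes must be non-empty. May be attached later with [set_labels()].
#'
#' @return An object of class `"ExpressionMatrix"`: a list with elements
#'   `values` (the matrix, dimnames set), `probe_ids`, `sample_ids` and
#'   `labels` (factor with levels control/case, or `NULL`).
#' @export
#' @examples
#' vals <- matrix(rnorm(24, 8), nrow = 6)
#' x <- ExpressionMatrix(vals,
#'   probe_ids = paste0("p", 1:6),
#'   sample_ids = paste0("s", 1:4),
#'   labels = c("control", "control", "case", "case")
#' )
#' x
ExpressionMatrix <- function(values, probe_ids = rownames(values),
                             sample_ids = colnames(values), labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  storage.mode(values) <- "double"
  m <- nrow(values)
  l <- ncol(values)
  if (m < 2L) stop("an expression matrix needs at least 2 probes, got ", m)
  if (l < 3L) stop("an expression matrix needs at least 3 samples, got ", l)
  if (is.null(probe_ids)) probe_ids <- paste0("probe_", seq_len(m))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(l))
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (length(probe_ids) != m) {
    stop("length of 'probe_ids' (", length(probe_ids),
         ") does not match the number of rows (", m, ")")
  }
  if (length(sample_ids) != l) {
    stop("length of 'sample_ids' (", length(sample_ids),
         ") does not match the number of columns (", l, ")")
  }
  dup <- probe_ids[duplicated(probe_ids)]
  if (length(dup)) {
    stop("duplicate probe ids: ", paste(utils::head(unique(dup), 5L), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression values contain missing or non-finite entries")
  }
  if (!is.null(labels)) labels <- check_labels(labels, sample_ids)
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(
    list(values = values, probe_ids = probe_ids, sample_ids = sample_ids,
         labels = labels),
    class = "ExpressionMatrix"
  )
}

check_labels <- function(labels, sample_ids) {
  l <- length(sample_ids)
  labels <- stats::setNames(as.character(labels), names(labels))
  if (!is.null(names(labels))) {
    missing_ids <- setdiff(sample_ids, names(labels))
    if (length(missing_ids)) {
      stop("no class label for sample(s): ",
           paste(utils::head(missing_ids, 5L), collapse = ", "))
    }
    labels <- unname(labels[sample_ids])
  } else if (length(labels) != l) {
    stop("length of 'labels' (", length(labels),
         ") does not match the number of samples (", l, ")")
  }
  bad <- setdiff(unique(labels), c("control", "case"))
  if (length(bad)) {
    stop("class labels must be 'control' or 'case'; found: ",
         paste(bad, collapse = ", "))
  }
  labels <- factor(labels, levels = c("control", "case"))
  if (any(table(labels) == 0L)) {
    stop("both classes must be non-empty; counts: control = ",
         sum(labels == "control"), ", case = ", sum(labels == "case"))
  }
  labels
}

#' Attach class labels to an expression matrix
#'
#' @param x An [ExpressionMatrix()].
#' @param labels Per-sample class labels; see [ExpressionMatrix()].
#' @return `x` with `labels` set.
#' @export
set_labels <- function(x, labels) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  x$labels <- check_labels(labels, x$sample_ids)
  x
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix: ", nrow(x$values), " probes x ", ncol(x$values),
      " samples\n", sep = "")
  if (!is.null(x$labels)) {
    cat("  classes: control = ", sum(x$labels == "control"),
        ", case = ", sum(x$labels == "case"), "\n", sep = "")
  } else {
    cat("  classes: <no labels attached>\n")
  }
  invisible(x)
}

#' Group samples with identical expression vectors
#'
#' Partitions the samples into equality groups under exact, value-wise
#' equality of their expression columns. No tolerance is applied: columns
#' differing in any entry, by however little, fall into different groups.
#' Unique samples form groups of size one.
#'
#' @param x An [ExpressionMatrix()].
#' @return A list of character vectors of sample ids, ordered by first
#'   occurrence; each vector is one equality group.
#' @export
#' @examples
#' vals <- cbind(a = c(1, 2), b = c(1, 2), c = c(1, 3))
#' vals <- rbind(vals, vals) # 4 probes
#' x <- ExpressionMatrix(vals, probe_ids = paste0("p", 1:4))
#' find_duplicate_samples(x) # list(c("a","b"), "c")
find_duplicate_samples <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- x$values
  l <- ncol(v)
  group <- integer(l)
  g <- 0L
  for (j in seq_len(l)) {
    if (group[j] > 0L) next
    g <- g + 1L
    group[j] <- g
    if (j < l) {
      for (k in seq.int(j + 1L, l)) {
        if (group[k] == 0L && all(v[, j] == v[, k])) group[k] <- g
      }
    }
  }
  unname(split(x$sample_ids, group))
}

#' Collapse duplicate samples to one representative each
#'
#' Samples whose expression vectors are exactly identical (see
#' [find_duplicate_samples()]) are collapsed to a single representative:
#' the first member in column order. Class labels are preserved; a duplicate
#' group whose members carry different class labels is an error, since the
#' same measurements cannot belong to both classes.
#'
#' The operation is idempotent, and the removed sample ids are recorded in
#' the `"removed_samples"` attribute of the result.
#'
#' @param x An [ExpressionMatrix()].
#' @return An [ExpressionMatrix()] without duplicate columns.
#' @export
collapse_duplicates <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  groups <- find_duplicate_samples(x)
  removed <- character(0)
  kept_for <- character(0)
  for (grp in groups) {
    if (length(grp) < 2L) next
    if (!is.null(x$labels)) {
      labs <- unique(as.character(x$labels[match(grp, x$sample_ids)]))
      if (length(labs) > 1L) {
        stop("duplicate samples ", paste(grp, collapse = ", "),
             " carry contradictory class labels (", paste(labs, collapse = ", "), ")")
      }
    }
    removed <- c(removed, grp[-1L])
    kept_for <- c(kept_for, rep(grp[1L], length(grp) - 1L))
  }
  if (length(removed)) {
    message("collapse_duplicates: removed ", length(removed), " duplicate sample(s): ",
            paste(removed, collapse = ", "))
  }
  keep <- !(x$sample_ids %in% removed)
  out <- ExpressionMatrix(
    x$values[, keep, drop = FALSE],
    probe_ids = x$probe_ids,
    sample_ids = x$sample_ids[keep],
    labels = if (is.null(x$labels)) NULL else as.character(x$labels)[keep]
  )
  attr(out, "removed_samples") <-
    if (length(removed)) data.frame(removed = removed, kept = kept_for,
                                    stringsAsFactors = FALSE)
    else data.frame(removed = character(0), kept = character(0))
  out
}
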