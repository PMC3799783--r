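#' Read an expression table from a TSV or GEO series-matrix file
#'
#' Two dialects are supported. `"plain-tsv"`: a header row of sample ids,
#' then one probe per row, the probe id in the first column. `"series-matrix"`:
#' the GEO series-matrix text export, in which metadata lines are prefixed
#' with `"!"` and the expression table is delimited by the
#' `!series_matrix_table_begin` / `!series_matrix_table_end` markers.
#' `"auto"` (the default) picks series-matrix when any `"!"`-prefixed line is
#' present.
#'
#' Values are used exactly as written; no log transform or renormalisation is
#' applied.
#'
#' @param path Path to the file.
#' @param dialect One of `"auto"`, `"plain-tsv"`, `"series-matrix"`.
#' @param missing What to do with rows containing a cell that does not parse
#'   as a finite number: `"error"` (default) fails naming the probe and
#'   sample of the first offending cell; `"drop"` removes such rows with a
#'   warning.
#' @return An [ExpressionMatrix()] without class labels (attach them with
#'   [set_labels()] or [read_class_labels()]). Row and column order of the
#'   file is preserved.
#' @export
read_expression_table <- function(path,
                                  dialect = c("auto", "plain-tsv", "series-matrix"),
                                  missing = c("error", "drop")) {
  dialect <- match.arg(dialect)
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (dialect == "auto") {
    dialect <- if (any(startsWith(lines, "!"))) "series-matrix" else "plain-tsv"
  }
  if (dialect == "series-matrix") {
    beg <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
    fin <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
    if (length(beg) != 1L || length(fin) != 1L || fin <= beg + 1L) {
      stop("malformed series-matrix file: table begin/end markers not found in ", path)
    }
    lines <- lines[seq.int(beg + 1L, fin - 1L)]
  }
  if (length(lines) < 2L) stop("no data rows in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- unquote_geo(fields[[1L]])
  width <- length(header)
  if (width < 2L) stop("header row of ", path, " has no sample columns")
  nf <- lengths(fields[-1L])
  if (any(nf != width)) {
    bad <- which(nf != width)[1L] + 1L
    stop("ragged row in ", path, ": line ", bad, " has ", nf[bad - 1L],
         " fields, expected ", width)
  }
  sample_ids <- header[-1L]
  body <- matrix(unlist(fields[-1L], use.names = FALSE),
                 ncol = width, byrow = TRUE)
  probe_ids <- unquote_geo(body[, 1L])
  if (anyDuplicated(probe_ids)) {
    stop("duplicate probe id(s) in ", path, ": ",
         paste(utils::head(unique(probe_ids[duplicated(probe_ids)]), 5L),
               collapse = ", "))
  }
  cells <- body[, -1L, drop = FALSE]
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- !is.finite(num)
  if (any(bad)) {
    if (missing == "error") {
      idx <- which(bad, arr.ind = TRUE)[1L, ]
      stop("non-numeric value ", dQuote(cells[idx[1L], idx[2L]]),
           " at probe ", probe_ids[idx[1L]], ", sample ", sample_ids[idx[2L]],
           " in ", path)
    }
    drop_rows <- unique(which(bad, arr.ind = TRUE)[, 1L])
    warning("dropping ", length(drop_rows),
            " row(s) with missing/non-numeric entries")
    keep <- setdiff(seq_len(nrow(num)), drop_rows)
    num <- num[keep, , drop = FALSE]
    probe_ids <- probe_ids[keep]
  }
  ExpressionMatrix(num, probe_ids = probe_ids, sample_ids = sample_ids)
}

# GEO series-matrix files quote identifiers; strip surrounding double quotes.
unquote_geo <- function(x) gsub('^"|"$', "", x)

#' Write an expression table as plain TSV
#'
#' Full `%.17g` precision is used, so a plain-TSV round trip through
#' [read_expression_table()] reproduces the values bit-exactly.
#'
#' @param x An [ExpressionMatrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("ID_REF", x$sample_ids), collapse = "\t"), con)
  body <- apply(x$values, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(x$probe_ids, body, sep = "\t"), con)
  invisible(path)
}

#' Read per-sample class labels
#'
#' Expects a two-column TSV `sample_id<TAB>class` with class `control` or
#' `case`; a header line is detected and skipped.
#'
#' @param path Path to the label file.
#' @return Named character vector mapping sample id to class.
#' @export
read_class_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("label file ", path, " must have two columns")
  if (nrow(tab) && (tolower(tab[1L, 1L]) %in% c("sample_id", "sample", "id") ||
                    tolower(tab[1L, 2L]) %in% c("class", "label"))) {
    tab <- tab[-1L, , drop = FALSE] # header
  }
  if (!nrow(tab)) stop("label file ", path, " has no entries")
  bad <- setdiff(unique(tab[[2L]]), c("control", "case"))
  if (length(bad)) {
    stop("label file ", path, " contains invalid class(es): ",
         paste(bad, collapse = ", "))
  }
  stats::setNames(tab[[2L]], tab[[1L]])
}

#' Read a probe-to-gene-symbol annotation table
#'
#' Expects a two-column TSV `probe_id<TAB>gene_symbol`. Composite symbols
#' (e.g. `"HP /// HPR"`) are kept verbatim. Probe ids must be unique;
#' probes absent from the table are simply unannotated.
#'
#' @param path Path to the annotation file.
#' @return Named character vector mapping probe id to gene symbol.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("annotation file ", path, " must have two columns")
  if (nrow(tab) && tolower(tab[1L, 1L]) %in% c("probe_id", "id_ref", "probe")) {
    tab <- tab[-1L, , drop = FALSE]
  }
  if (anyDuplicated(tab[[1L]])) {
    stop("annotation file ", path, " contains duplicate probe id(s): ",
         paste(utils::head(unique(tab[[1L]][duplicated(tab[[1L]])]), 5L),
               collapse = ", "))
  }
  stats::setNames(tab[[2L]], tab[[1L]])
}
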