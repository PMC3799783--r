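#' Run the full DEG-identification pipeline
#'
#' Orchestrates every stage: load the expression table and labels, collapse
#' exact duplicate samples, choose or apply the asymmetric weights (a, b),
#' decompose, score the probes on the discriminant component, call DEGs by
#' the half-range threshold, build the within-case co-expression network
#' over the called probes, and evaluate single-gene and per-component
#' combination ROC/AUC. Optionally writes all result tables and a
#' machine-parsable run log.
#'
#' @param expr An [ExpressionMatrix()] or a path readable by
#'   [read_expression_table()].
#' @param labels Per-sample class labels, or a path readable by
#'   [read_class_labels()]. Ignored when `expr` already carries labels.
#' @param annotation Optional named probe-to-symbol vector or a path
#'   readable by [read_annotation()].
#' @param out_dir Optional output directory for result tables
#'   ([write_result_tables()]).
#' @param a,b Preset asymmetric weights (used when `grid = FALSE`).
#' @param grid If `TRUE`, search `a_grid` x `b_grid` for the maximal-margin
#'   separable point ([select_params()]) instead of using the preset.
#' @param a_grid,b_grid Search grids (see [select_params()]).
#' @param k Discriminant component index (default 2).
#' @param theta Optional threshold override; default derives it from the
#'   scores ([score_threshold()]).
#' @param tau Co-expression edge threshold (default 0.9).
#' @param basis `"raw"` (default; the literal back-projection basis, on
#'   whose score scale the integer threshold is meaningful) or
#'   `"orthonormal"`.
#' @param dialect Passed to [read_expression_table()].
#' @return Invisibly, a list with `x` (collapsed matrix), `selection`,
#'   `fit`, `scores`, `theta`, `degs`, `network`, `roc_single`,
#'   `roc_combinations`, `log` (character vector of `key=value` lines) and
#'   `files` (paths written, when `out_dir` was given).
#' @export
apca_run <- function(expr, labels = NULL, annotation = NULL, out_dir = NULL,
                     a = 0.3, b = 20, grid = FALSE,
                     a_grid = seq(0.05, 0.95, by = 0.05),
                     b_grid = c(1, 2, 5, 10, 20, 30),
                     k = 2L, theta = NULL, tau = 0.9,
                     basis = c("raw", "orthonormal"),
                     dialect = "auto") {
  basis <- match.arg(basis)
  log <- character(0)
  note <- function(key, value) {
    log <<- c(log, paste0(key, "=", paste(value, collapse = ",")))
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }

  x <- stage("io_expr", {
    if (is.character(expr)) expr <- read_expression_table(expr, dialect = dialect)
    stopifnot(inherits(expr, "ExpressionMatrix"))
    if (is.null(expr$labels)) {
      if (is.null(labels)) stop("no class labels provided")
      if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
        labels <- read_class_labels(labels)
      }
      expr <- set_labels(expr, labels)
    }
    expr
  })
  if (is.character(annotation) && length(annotation) == 1L) {
    annotation <- stage("io_expr", read_annotation(annotation))
  }
  note("n_probes", nrow(x$values))
  note("n_samples_loaded", ncol(x$values))

  x <- stage("io_expr", collapse_duplicates(x))
  removed <- attr(x, "removed_samples")
  note("n_duplicates_removed", nrow(removed))
  if (nrow(removed)) note("removed_samples", removed$removed)
  note("n_samples", ncol(x$values))
  note("n_control", sum(x$labels == "control"))
  note("n_case", sum(x$labels == "case"))
  note("basis_mode", basis)

  selection <- stage("selection", {
    if (grid) select_params(x, a_grid = a_grid, b_grid = b_grid, basis = basis)
    else select_params(x, preset = c(a, b), basis = basis)
  })
  if (is.null(selection$chosen)) {
    stop("stage selection: no separable (a, b) found; pass a preset or widen the grids",
         call. = FALSE)
  }
  a_use <- selection$chosen$a
  b_use <- selection$chosen$b
  note("selection_mode", if (grid) "grid" else "preset")
  note("a", a_use)
  note("b", b_use)
  note("separation_margin", format(selection$chosen$margin))
  note("selection_status", selection$status)

  fit <- stage("apca_core", apca(x, a = a_use, b = b_use, basis = basis))
  note("rank", fit$rank)
  note("proportion_pc1", format(fit$proportions[1L]))
  note("proportion_pc2", format(fit$proportions[2L]))

  scores <- stage("apca_core", gene_scores(fit, k = k, annotation = annotation))
  note("discriminant_pc", k)
  note("sign_rule", "max-abs-coefficient-positive")
  note("max_abs_score", format(max(abs(scores$score))))

  degs <- stage("deg_calling", {
    if (is.null(theta)) theta <- score_threshold(scores)
    call_degs(scores, theta = theta)
  })
  note("theta", degs$theta)
  note("n_deg_probes", degs$n_probes)
  note("n_deg_genes", degs$n_genes)

  network <- NULL
  roc_single <- list()
  roc_combinations <- list()
  if (degs$n_probes >= 2L && sum(x$labels == "case") >= 3L) {
    network <- stage("evaluation", {
      cc <- within_class_cc(x, degs$calls$probe_id, group = "case")
      build_network(cc, tau = tau)
    })
    note("tau", tau)
    note("n_edges", nrow(network$edges))
    note("n_subnetworks", network$summary[["subnetworks"]])
    note("n_pairs", network$summary[["pairs"]])
    note("n_singletons", network$summary[["singletons"]])

    roc_single <- stage("evaluation", {
      out <- lapply(degs$calls$probe_id, function(p) {
        auc_single(x$values[p, ], x$labels)
      })
      names(out) <- degs$calls$probe_id
      out
    })
    roc_combinations <- stage("evaluation", {
      # the discriminant's global sign is arbitrary; orient the signature so
      # that it points towards the case class (relative signs stay as scored)
      fl_k <- factor_loadings(fit, k)
      flip <- stats::cor(fl_k, as.numeric(x$labels == "case"))
      flip <- if (!is.na(flip) && flip < 0) -1 else 1
      comps <- Filter(function(cmp) length(cmp) >= 2L, network$components)
      out <- lapply(comps, function(cmp) {
        ori <- flip * degs$calls$score[match(cmp, degs$calls$probe_id)]
        auc_combination(x, cmp, orientations = ori)
      })
      if (length(out)) {
        names(out) <- vapply(comps, function(cmp)
          paste0("combo_", cmp[1L], "_n", length(cmp)), "")
      }
      out
    })
    note("combination_rule", "mean-of-sign-aligned-z-scores")
    note("combination_orientation", "case-positive-discriminant")
    note("n_combinations", length(roc_combinations))
  } else {
    note("evaluation", "skipped-too-few-degs-or-case-samples")
  }

  res <- list(x = x, selection = selection, fit = fit, scores = scores,
              theta = degs$theta, degs = degs, network = network,
              roc_single = roc_single, roc_combinations = roc_combinations,
              log = log, files = character(0))
  if (!is.null(out_dir)) {
    res$files <- stage("io_expr", write_result_tables(res, out_dir))
  }
  invisible(res)
}

#' Write the pipeline result tables
#'
#' Writes TSV tables with headers and deterministic row order: the
#' decomposition variance table, the full score table (descending absolute
#' score, ties by probe id), the DEG table, the network edge list and
#' component membership, the ROC summary, and the run log.
#'
#' @param res A result list from [apca_run()].
#' @param out_dir Output directory (created if absent).
#' @return Character vector of the paths written.
#' @export
write_result_tables <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }

  put(variance_table(res$fit), "decomposition.tsv")

  sc <- res$scores
  sc <- sc[order(-abs(sc$score), sc$probe_id), , drop = FALSE]
  put(sc, "score_table.tsv")

  put(deg_table(res$degs), "deg_table.tsv")

  if (!is.null(res$network)) {
    put(res$network$edges, "network_edges.tsv")
    memb <- data.frame(probe_id = names(res$network$membership),
                       component = as.integer(res$network$membership),
                       stringsAsFactors = FALSE)
    memb <- memb[order(memb$component, memb$probe_id), , drop = FALSE]
    put(memb, "network_components.tsv")
  }

  roc_rows <- list()
  for (p in names(res$roc_single)) {
    r <- res$roc_single[[p]]
    roc_rows[[length(roc_rows) + 1L]] <-
      data.frame(unit = p, type = "single", n_genes = 1L,
                 auc = r$auc, p_value = format_pvalue(r$p_value),
                 stringsAsFactors = FALSE)
  }
  for (nm in names(res$roc_combinations)) {
    r <- res$roc_combinations[[nm]]
    roc_rows[[length(roc_rows) + 1L]] <-
      data.frame(unit = nm, type = "combination", n_genes = length(r$genes),
                 auc = r$auc, p_value = format_pvalue(r$p_value),
                 stringsAsFactors = FALSE)
  }
  if (length(roc_rows)) {
    put(do.call(rbind, roc_rows), "roc_summary.tsv")
  }

  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(res$log, log_path)
  c(paths, log_path)
}
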