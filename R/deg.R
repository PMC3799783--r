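#' Half-range calling threshold
#'
#' The calling threshold is half the numerical range of the discriminant
#' scores, floored to an integer:
#' \deqn{\theta = \lfloor |S_{max}| / 2 \rfloor,}
#' where `|S_max|` is the maximum absolute score. A maximum score of 11.02
#' therefore gives `theta = 5`.
#'
#' @param scores A [gene_scores()] table (or numeric vector of scores).
#' @return Nonnegative integer threshold. All-zero scores give 0 with a
#'   warning, since no probe can then exceed the threshold.
#' @export
score_threshold <- function(scores) {
  s <- if (is.data.frame(scores)) scores$score else scores
  if (!length(s)) stop("empty score table")
  if (any(!is.finite(s))) stop("scores contain non-finite values")
  smax <- max(abs(s))
  if (smax == 0) {
    warning("all scores are zero; threshold 0 cannot be exceeded by any probe")
    return(0L)
  }
  as.integer(floor(smax / 2))
}

#' Call differentially expressed genes by score threshold
#'
#' Probes whose absolute discriminant score is strictly greater than the
#' threshold are called. The probe-level calls are aggregated to gene level
#' on the verbatim gene-symbol string (composite symbols such as
#' `"HBA1 /// HBA2"` count as one gene; unannotated probes count as their
#' own gene, keyed by probe id).
#'
#' @param scores A [gene_scores()] table.
#' @param theta Nonnegative calling threshold; defaults to
#'   [score_threshold()] of the scores.
#' @return An object of class `"DEGCallResult"`: list with `theta`, `calls`
#'   (data.frame `probe_id`, `gene_symbol`, `score`, sorted by descending
#'   absolute score, ties by probe id), `n_probes` and `n_genes`.
#' @export
call_degs <- function(scores, theta = score_threshold(scores)) {
  stopifnot(is.data.frame(scores),
            all(c("probe_id", "score") %in% names(scores)))
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) || theta < 0) {
    stop("'theta' must be a single nonnegative number")
  }
  keep <- abs(scores$score) > theta
  calls <- scores[keep, , drop = FALSE]
  if (is.null(calls$gene_symbol)) calls$gene_symbol <- NA_character_
  calls <- calls[order(-abs(calls$score), calls$probe_id), , drop = FALSE]
  rownames(calls) <- NULL
  gene_key <- ifelse(is.na(calls$gene_symbol) | calls$gene_symbol == "",
                     calls$probe_id, calls$gene_symbol)
  structure(
    list(theta = theta,
         calls = data.frame(probe_id = calls$probe_id,
                            gene_symbol = calls$gene_symbol,
                            score = calls$score,
                            stringsAsFactors = FALSE),
         n_probes = nrow(calls),
         n_genes = length(unique(gene_key))),
    class = "DEGCallResult"
  )
}

#' @export
print.DEGCallResult <- function(x, ...) {
  cat("DEG calls: ", x$n_probes, " probes / ", x$n_genes,
      " genes with |score| > ", x$theta, "\n", sep = "")
  if (x$n_probes) print(utils::head(x$calls, 10L))
  invisible(x)
}

#' DEG table in reporting layout
#'
#' Numbers the called genes (one number per distinct symbol, in order of
#' first appearance by descending absolute score) the way a results table
#' lists multi-probe genes under a single entry.
#'
#' @param degs A [call_degs()] result.
#' @return A `data.frame` with columns `no`, `gene_symbol`, `probe_id`,
#'   `score`.
#' @export
deg_table <- function(degs) {
  stopifnot(inherits(degs, "DEGCallResult"))
  calls <- degs$calls
  gene_key <- ifelse(is.na(calls$gene_symbol) | calls$gene_symbol == "",
                     calls$probe_id, calls$gene_symbol)
  no <- match(gene_key, unique(gene_key))
  data.frame(no = no,
             gene_symbol = calls$gene_symbol,
             probe_id = calls$probe_id,
             score = calls$score,
             stringsAsFactors = FALSE)
}
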