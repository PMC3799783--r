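#' Within-class Pearson correlation of selected probes
#'
#' Correlates each pair of probes using only the samples of one class group
#' (typically the case group, where disease co-regulation is sought).
#'
#' @param x An [ExpressionMatrix()] with labels.
#' @param probes Character vector of probe ids to correlate.
#' @param group `"case"` (default) or `"control"`.
#' @return Symmetric correlation matrix with the probe ids as dimnames.
#'   Probes with zero variance within the group are excluded with a warning
#'   (their correlations are undefined).
#' @export
within_class_cc <- function(x, probes, group = c("case", "control")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  group <- match.arg(group)
  if (is.null(x$labels)) stop("expression matrix has no class labels")
  idx <- which(x$labels == group)
  if (length(idx) < 3L) {
    stop("need at least 3 samples in the ", group, " group, got ", length(idx))
  }
  missing_probes <- setdiff(probes, x$probe_ids)
  if (length(missing_probes)) {
    stop("probe(s) not present: ",
         paste(utils::head(missing_probes, 5L), collapse = ", "))
  }
  sub <- x$values[probes, idx, drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("excluding ", sum(sds == 0),
            " zero-variance probe(s) from the correlation: ",
            paste(utils::head(probes[sds == 0], 5L), collapse = ", "))
    sub <- sub[sds > 0, , drop = FALSE]
  }
  if (nrow(sub) < 2L) stop("fewer than 2 probes with nonzero variance")
  stats::cor(t(sub))
}

#' Threshold a correlation matrix into a co-expression network
#'
#' Edges connect probe pairs whose correlation is at least `tau`
#' (inclusive). Connected components are found on the thresholded graph and
#' classified by size: subnetworks (3 or more nodes), pairs (2 nodes) and
#' singletons.
#'
#' @param cc Symmetric correlation matrix with dimnames (e.g. from
#'   [within_class_cc()]).
#' @param tau Correlation threshold (default 0.9).
#' @return An object of class `"CorrelationNetwork"`: list with `nodes`,
#'   `tau`, `edges` (data.frame `probe_a`, `probe_b`, `cc`), `membership`
#'   (named integer component id per node), `components` (list of node
#'   vectors, decreasing size) and `summary` (counts of subnetworks, pairs,
#'   singletons).
#' @export
build_network <- function(cc, tau = 0.9) {
  cc <- as.matrix(cc)
  if (is.null(rownames(cc))) stop("'cc' must have probe ids as dimnames")
  nodes <- rownames(cc)
  ut <- which(upper.tri(cc) & cc >= tau, arr.ind = TRUE)
  edges <- data.frame(probe_a = nodes[ut[, 1L]],
                      probe_b = nodes[ut[, 2L]],
                      cc = cc[ut],
                      stringsAsFactors = FALSE)
  if (nrow(edges)) {
    edges <- edges[order(-edges$cc, edges$probe_a, edges$probe_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  g <- igraph::graph_from_data_frame(edges[, c("probe_a", "probe_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  membership <- comp$membership[nodes]
  components <- split(nodes, membership)
  components <- components[order(-lengths(components),
                                 vapply(components, `[`, "", 1L))]
  names(components) <- NULL
  sizes <- lengths(components)
  structure(
    list(nodes = nodes, tau = tau, edges = edges,
         membership = membership, components = components,
         summary = c(subnetworks = sum(sizes >= 3L),
                     pairs = sum(sizes == 2L),
                     singletons = sum(sizes == 1L))),
    class = "CorrelationNetwork"
  )
}

#' @export
print.CorrelationNetwork <- function(x, ...) {
  cat("Co-expression network (cc >= ", x$tau, "): ", length(x$nodes),
      " nodes, ", nrow(x$edges), " edges\n", sep = "")
  cat("  ", x$summary[["subnetworks"]], " subnetwork(s), ",
      x$summary[["pairs"]], " pair(s), ",
      x$summary[["singletons"]], " singleton(s)\n", sep = "")
  invisible(x)
}

#' ROC curve and AUC of a single marker
#'
#' The case class is the positive class. The AUC is computed as the
#' Mann-Whitney statistic `U / (n_pos * n_neg)` with ties counted half; the
#' two-sided p-value uses the normal approximation of the rank-sum test with
#' tie correction (no continuity correction).
#'
#' @param values Per-sample marker values (higher = more case-like for an
#'   AUC above 0.5).
#' @param labels Per-sample class labels.
#' @return An object of class `"apca_roc"`: list with `auc`, `p_value`,
#'   `curve` (data.frame `fpr`, `tpr`, from (0,0) to (1,1)), `n_pos`,
#'   `n_neg`.
#' @export
auc_single <- function(values, labels) {
  labels <- check_labels(labels, seq_along(values))
  if (length(values) != length(labels)) stop("'values' and 'labels' lengths differ")
  if (any(!is.finite(values))) stop("non-finite marker values")
  pos <- labels == "case"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  r <- rank(values)
  U <- sum(r[pos]) - n1 * (n1 + 1) / 2
  auc <- U / (n1 * n0)
  # normal approximation with tie correction
  N <- n1 + n0
  tie <- table(values)
  sigma2 <- n1 * n0 / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
  p <- if (sigma2 <= 0) 1 else 2 * stats::pnorm(-abs(U - n1 * n0 / 2) / sqrt(sigma2))
  p <- min(p, 1)
  # curve: sweep the threshold through the distinct values, high to low
  ord <- order(values, decreasing = TRUE)
  v <- values[ord]
  p_ord <- pos[ord]
  last <- cumsum(rle(v)$lengths)
  curve <- data.frame(fpr = c(0, cumsum(!p_ord)[last] / n0),
                      tpr = c(0, cumsum(p_ord)[last] / n1))
  structure(list(auc = auc, p_value = p, curve = curve, n_pos = n1, n_neg = n0),
            class = "apca_roc")
}

#' @export
print.apca_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (P = %s; %d case vs %d control)\n",
              x$auc, format_pvalue(x$p_value), x$n_pos, x$n_neg))
  invisible(x)
}

#' Format a p-value, never printing zero
#'
#' @param p Numeric p-value.
#' @return Character; values below 1e-15 are reported as `"<1e-15"`.
#' @export
format_pvalue <- function(p) {
  ifelse(p < 1e-15, "<1e-15", format(signif(p, 3L)))
}

#' ROC/AUC of a gene combination
#'
#' Combines several probes into one per-sample score: each probe's
#' expression is z-scored across all samples, sign-aligned with its
#' orientation (the sign of its discriminant score, so up- and
#' down-regulated markers pull the same way), and the aligned z-scores are
#' averaged. The combined score is then evaluated like a single marker
#' ([auc_single()]).
#'
#' @param x An [ExpressionMatrix()] with labels.
#' @param probes Character vector of probe ids (at least 2).
#' @param orientations Numeric vector of per-probe orientations; only the
#'   signs are used. Defaults to all `+1`.
#' @return An `"apca_roc"` object with an extra `genes` element listing the
#'   probes used. Zero-variance probes are excluded with a warning.
#' @export
auc_combination <- function(x, probes, orientations = rep(1, length(probes))) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (is.null(x$labels)) stop("expression matrix has no class labels")
  if (length(probes) < 2L) stop("a combination needs at least 2 probes")
  if (length(orientations) != length(probes)) {
    stop("'orientations' must match 'probes' in length")
  }
  s <- sign(orientations)
  if (any(s == 0)) stop("orientation 0 is ambiguous; provide signed scores")
  missing_probes <- setdiff(probes, x$probe_ids)
  if (length(missing_probes)) {
    stop("probe(s) not present: ",
         paste(utils::head(missing_probes, 5L), collapse = ", "))
  }
  sub <- x$values[probes, , drop = FALSE]
  mu <- rowMeans(sub)
  sds <- apply(sub, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("excluding ", sum(sds == 0),
            " zero-variance probe(s) from the combination")
    keep <- sds > 0
    sub <- sub[keep, , drop = FALSE]
    mu <- mu[keep]
    sds <- sds[keep]
    s <- s[keep]
    probes <- probes[keep]
    if (nrow(sub) < 1L) stop("no probes with nonzero variance in the combination")
  }
  z <- (sub - mu) / sds
  combined <- colMeans(z * s)
  out <- auc_single(combined, x$labels)
  out$genes <- probes
  out
}
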