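#' Project a wide matrix onto its sample-spanned subspace (Gram trick)
#'
#' For a probe-by-sample matrix `X` with far more probes than samples
#' (`m >> l`), the nonzero eigenstructure of the m-by-m scatter `X X^T` is
#' obtained from the small l-by-l Gram matrix `S = X^T X` (the snapshot
#' method): if `v` is an eigenvector of `S` with eigenvalue `lambda > 0`,
#' then `X v` is an (unnormalised, norm `sqrt(lambda)`) eigenvector of
#' `X X^T` with the same eigenvalue.
#'
#' Two basis conventions are available. `normalize = TRUE` scales each
#' column of `X %*% EIV_S` to unit length, yielding an orthonormal basis of
#' the column space (required for the usual PCA identities).
#' `normalize = FALSE` keeps the literal product `EIV_L = X %*% EIV_S`,
#' whose column norms are `sqrt(lambda)`; the projection then amplifies
#' high-variance directions, which is what concentrates the shared-baseline
#' axis on the first component in downstream weighted decompositions of raw
#' intensity data.
#'
#' @param values Numeric matrix (m probes x l samples).
#' @param tol Relative eigenvalue cutoff: basis columns with Gram eigenvalue
#'   `<= tol * max(eigenvalue)` are dropped (numerical rank deficiency, e.g.
#'   duplicate samples).
#' @param normalize Logical; normalise basis columns to unit length (see
#'   above).
#' @return List with `basis` (m x r), `projected` (`t(basis) %*% values`,
#'   r x l), `gram_eigenvalues` (all l, non-increasing) and `rank` (r, the
#'   number of retained columns).
#' @export
gram_project <- function(values, tol = 1e-10, normalize = TRUE) {
  values <- as.matrix(values)
  S <- crossprod(values)
  es <- eigen(S, symmetric = TRUE)
  lambda <- es$values
  if (!is.finite(lambda[1L]) || lambda[1L] <= 0) {
    stop("matrix has no nonzero singular values (zero matrix?)")
  }
  keep <- lambda > tol * lambda[1L]
  eivl <- values %*% es$vectors
  if (normalize) {
    norms <- sqrt(colSums(eivl^2))
    norms[norms == 0] <- 1
    eivl <- sweep(eivl, 2L, norms, "/")
  }
  basis <- eivl[, keep, drop = FALSE]
  projected <- crossprod(basis, values)
  list(basis = basis, projected = projected,
       gram_eigenvalues = lambda, rank = sum(keep))
}

#' Class-conditional and between-class scatter of projected samples
#'
#' Computes, in the projected sample space, the class-conditional covariance
#' matrices of the control and case samples and the between-class scatter of
#' the two class means. Divisors are the plain class sizes `n`, `d` and
#' `l = n + d` (maximum-likelihood style), not `n - 1`:
#' \deqn{C_{Sn} = \frac{1}{n} Y_{Sn} Y_{Sn}^T,\quad
#'       C_{Sd} = \frac{1}{d} Y_{Sd} Y_{Sd}^T,}
#' \deqn{C_S = \frac{1}{l}\left[n (M_{Sn}-M_S)(M_{Sn}-M_S)^T
#'       + d (M_{Sd}-M_S)(M_{Sd}-M_S)^T\right],}
#' where the `Y` are the class blocks centred on their class means `M`.
#'
#' @param projected Numeric matrix, dimensions x samples (e.g. the
#'   `projected` element of [gram_project()]).
#' @param labels Per-sample class factor/vector with values
#'   `"control"`/`"case"`; both classes must be non-empty.
#' @return List with symmetric PSD matrices `within_control` (`C_Sn`),
#'   `within_case` (`C_Sd`), `between` (`C_S`), and counts `n`, `d`.
#' @export
class_stats <- function(projected, labels) {
  projected <- as.matrix(projected)
  labels <- check_labels(labels, colnames(projected) %||% seq_len(ncol(projected)))
  ctrl <- labels == "control"
  case <- labels == "case"
  n <- sum(ctrl)
  d <- sum(case)
  l <- n + d
  if (l != ncol(projected)) stop("labels do not match the number of samples")
  Mn <- rowMeans(projected[, ctrl, drop = FALSE])
  Md <- rowMeans(projected[, case, drop = FALSE])
  M <- rowMeans(projected)
  Yn <- projected[, ctrl, drop = FALSE] - Mn
  Yd <- projected[, case, drop = FALSE] - Md
  list(
    within_control = tcrossprod(Yn) / n,
    within_case = tcrossprod(Yd) / d,
    between = (n * tcrossprod(Mn - M) + d * tcrossprod(Md - M)) / l,
    n = n, d = d
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Asymmetrically weighted covariance matrix
#'
#' Combines the two class-conditional covariances and the between-class
#' scatter into `C = a * C_Sn + (1 - a) * C_Sd + b * C_S`. A small `a`
#' up-weights the (typically minority) case class; a large `b` forces the
#' leading component to absorb the class-mean structure so that the second
#' component captures the dominant within-class difference.
#'
#' With `a = n/l` and `b = 1` the combination collapses to the ordinary
#' total covariance of the samples about their global mean — the standard
#' PCA scatter (see [pca_baseline()]).
#'
#' @param within_control,within_case,between Conformable symmetric matrices,
#'   e.g. from [class_stats()].
#' @param a Weight on the control-class covariance, in (0, 1).
#' @param b Weight on the between-class matrix, `>= 0` (default 20).
#' @return Symmetric PSD matrix `C`.
#' @export
weighted_covariance <- function(within_control, within_case, between,
                                a = 0.3, b = 20) {
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a <= 0 || a >= 1) {
    stop("'a' must be a single number in (0, 1), got ", deparse(a))
  }
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b < 0) {
    stop("'b' must be a single nonnegative number, got ", deparse(b))
  }
  C <- a * within_control + (1 - a) * within_case + b * between
  (C + t(C)) / 2
}

#' Eigendecomposition with variance proportions
#'
#' @param C Symmetric matrix with finite entries.
#' @return List with `eigenvalues` (non-increasing, clamped at 0),
#'   `eigenvectors` (columns), `proportions` (eigenvalue / trace) and
#'   `cumulative` (non-decreasing, ending at 1).
#' @export
decompose_covariance <- function(C) {
  C <- as.matrix(C)
  if (any(!is.finite(C))) stop("covariance matrix contains non-finite entries")
  ec <- eigen((C + t(C)) / 2, symmetric = TRUE)
  vals <- pmax(ec$values, 0)
  tot <- sum(vals)
  if (tot <= 0) stop("covariance matrix has zero trace; no components to extract")
  prop <- vals / tot
  list(eigenvalues = vals, eigenvectors = ec$vectors,
       proportions = prop, cumulative = cumsum(prop))
}

#' Asymmetric principal component analysis of an expression matrix
#'
#' Runs the full decomposition: (1) project the probe-by-sample matrix onto
#' the sample-spanned subspace via the Gram trick ([gram_project()]);
#' (2) form the class-conditional covariances and between-class scatter of
#' the projected samples ([class_stats()]) and combine them with asymmetric
#' weights ([weighted_covariance()]); (3) eigendecompose the weighted matrix
#' ([decompose_covariance()]). Gene-space components, per-probe scores and
#' factor loadings are then obtained with [gene_scores()] and
#' [factor_loadings()].
#'
#' @param x An [ExpressionMatrix()] with labels attached. Collapse exact
#'   duplicate samples first ([collapse_duplicates()]); residual numerical
#'   rank deficiency is handled by `tol`.
#' @param a Weight on the control-class covariance, in (0, 1).
#' @param b Weight on the between-class matrix (default 20).
#' @param basis `"orthonormal"` (default) normalises the back-projection
#'   basis to unit columns; `"raw"` keeps the literal product
#'   `X %*% EIV_S`, on whose scale the integer calling threshold of
#'   [score_threshold()] is meaningful.
#' @param tol Relative eigenvalue cutoff passed to [gram_project()].
#' @return An object of class `"apca"`: list with the inputs (`x`, `a`, `b`,
#'   `basis_mode`), `basis`, `projected`, `class_covs` ([class_stats()]
#'   output), `weighted` (the matrix `C`), `eigenvalues`, `eigenvectors`,
#'   `proportions`, `cumulative`, `gram_eigenvalues`, `rank`, `n`, `d`.
#' @export
#' @examples
#' sim <- simulate_expression(synthetic_config(m = 200, n_control = 8, n_case = 4))
#' fit <- apca(sim$x, a = 0.3, b = 20)
#' head(fit$proportions)
apca <- function(x, a = 0.3, b = 20, basis = c("orthonormal", "raw"),
                 tol = 1e-10) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  basis <- match.arg(basis)
  if (is.null(x$labels)) stop("expression matrix has no class labels; use set_labels()")
  gp <- gram_project(x$values, tol = tol, normalize = basis == "orthonormal")
  cs <- class_stats(gp$projected, x$labels)
  C <- weighted_covariance(cs$within_control, cs$within_case, cs$between,
                           a = a, b = b)
  dc <- decompose_covariance(C)
  structure(
    list(x = x, a = a, b = b, basis_mode = basis,
         basis = gp$basis, projected = gp$projected,
         class_covs = cs, weighted = C,
         eigenvalues = dc$eigenvalues, eigenvectors = dc$eigenvectors,
         proportions = dc$proportions, cumulative = dc$cumulative,
         gram_eigenvalues = gp$gram_eigenvalues, rank = gp$rank,
         n = cs$n, d = cs$d),
    class = "apca"
  )
}

#' @export
print.apca <- function(x, ...) {
  cat("APCA decomposition (a = ", x$a, ", b = ", x$b, ", basis = ",
      x$basis_mode, ")\n", sep = "")
  cat("  ", nrow(x$x$values), " probes, ", ncol(x$x$values),
      " samples (control = ", x$n, ", case = ", x$d, "), rank ", x$rank,
      "\n", sep = "")
  k <- min(5L, x$rank)
  cat("  leading variance proportions:",
      paste(sprintf("%.4f", x$proportions[seq_len(k)]), collapse = ", "), "\n")
  invisible(x)
}

#' Per-probe scores on a gene-space principal component
#'
#' Back-projects the k-th eigenvector of the weighted covariance to gene
#' space: `score = basis %*% v_k`, one signed score per probe. The second
#' component (`k = 2`) is the discriminant axis under a large between-class
#' weight `b`, and its scores feed the DEG calling rule
#' ([score_threshold()], [call_degs()]).
#'
#' Eigenvector signs being arbitrary, the score vector is oriented so that
#' its entry of maximum absolute value is positive.
#'
#' @param fit An [apca()] object.
#' @param k Component index, `1 <= k <= rank` (default 2, the discriminant).
#' @param annotation Optional named character vector probe id -> gene symbol
#'   ([read_annotation()]).
#' @return A `data.frame` of class `"GeneScoreTable"` with columns
#'   `probe_id`, `gene_symbol` (`NA` when unannotated) and `score`, one row
#'   per probe in input order.
#' @export
gene_scores <- function(fit, k = 2L, annotation = NULL) {
  stopifnot(inherits(fit, "apca"))
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > fit$rank) {
    stop("'k' must be a component index between 1 and ", fit$rank)
  }
  s <- unname(drop(fit$basis %*% fit$eigenvectors[, k]))
  i <- which.max(abs(s))
  if (s[i] < 0) s <- -s
  sym <- if (is.null(annotation)) NA_character_ else
    unname(annotation[fit$x$probe_ids])
  out <- data.frame(probe_id = fit$x$probe_ids,
                    gene_symbol = sym,
                    score = s,
                    stringsAsFactors = FALSE)
  class(out) <- c("GeneScoreTable", "data.frame")
  attr(out, "k") <- as.integer(k)
  attr(out, "basis_mode") <- fit$basis_mode
  out
}

#' Factor loadings of samples on a gene-space component
#'
#' The factor loading of a sample on a gene-space principal component is the
#' Pearson correlation between the sample's expression vector and the
#' component. The loadings of the first two components form the plane in
#' which case/control separability drives parameter selection
#' ([select_params()]).
#'
#' @param x An [ExpressionMatrix()] (or an [apca()] object, in which case
#'   `pc_gene` may be a component index).
#' @param pc_gene Numeric vector of length m (a gene-space component, e.g.
#'   the `score` column of [gene_scores()]), or a component index when `x`
#'   is an [apca()] object.
#' @return Named numeric vector of loadings in \[-1, 1\], one per sample.
#' @export
factor_loadings <- function(x, pc_gene) {
  if (inherits(x, "apca")) {
    fit <- x
    if (length(pc_gene) == 1L && is.numeric(pc_gene)) {
      pc_gene <- gene_scores(fit, k = pc_gene)$score
    }
    x <- fit$x
  }
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (length(pc_gene) != nrow(x$values)) {
    stop("'pc_gene' must have one entry per probe (", nrow(x$values), ")")
  }
  sds <- apply(x$values, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance sample column(s), loading undefined: ",
         paste(x$sample_ids[sds == 0], collapse = ", "))
  }
  if (stats::sd(pc_gene) == 0) stop("'pc_gene' has zero variance")
  drop(stats::cor(x$values, pc_gene))
}

#' Standard-PCA baseline via the weighted-covariance identity
#'
#' Ordinary PCA of the projected samples about their global mean is the
#' special case `a = n/l`, `b = 1` of the asymmetric weighting: the classes
#' are weighted by their sample counts and the between-class scatter enters
#' once, which reassembles the total covariance exactly. This baseline is
#' what the asymmetric decomposition is compared against.
#'
#' @param x An [ExpressionMatrix()] with labels.
#' @param basis,tol As in [apca()].
#' @return An [apca()] object with `a = n/l`, `b = 1`.
#' @export
pca_baseline <- function(x, basis = c("orthonormal", "raw"), tol = 1e-10) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  basis <- match.arg(basis)
  if (is.null(x$labels)) stop("expression matrix has no class labels; use set_labels()")
  n <- sum(x$labels == "control")
  l <- length(x$labels)
  apca(x, a = n / l, b = 1, basis = basis, tol = tol)
}

#' Export the variance table of a decomposition
#'
#' @param fit An [apca()] object.
#' @param n_pc Number of leading components to include (default all).
#' @return A `data.frame` with columns `pc`, `eigenvalue`, `proportion`,
#'   `cumulative`.
#' @export
variance_table <- function(fit, n_pc = fit$rank) {
  stopifnot(inherits(fit, "apca"))
  n_pc <- min(n_pc, length(fit$eigenvalues))
  idx <- seq_len(n_pc)
  data.frame(pc = idx,
             eigenvalue = fit$eigenvalues[idx],
             proportion = fit$proportions[idx],
             cumulative = fit$cumulative[idx])
}
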