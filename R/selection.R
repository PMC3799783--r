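#' Linear separability of two classes in the loading plane
#'
#' Tests whether the control and case samples can be separated by a straight
#' line in the 2-D plane of the first two factor loadings, and measures the
#' largest achievable hard margin (half the widest gap between the projected
#' classes over all directions), normalised by the pooled point spread (the
#' root-mean-square distance of all points from their centroid) so that the
#' value is scale-free.
#'
#' The scan over candidate directions is exact for the planar hard-margin
#' problem: the optimum is attained either perpendicular to the segment
#' joining one point of each class (vertex-vertex) or perpendicular to an
#' edge within one class (vertex-edge), so all cross-class difference
#' vectors and all within-class edge normals are examined.
#'
#' @param fl1,fl2 Per-sample loadings on the first and second component.
#' @param labels Per-sample class labels (`"control"`/`"case"`).
#' @return List with `separable` (logical) and `margin` (nonnegative;
#'   0 when not separable or degenerate).
#' @export
separable <- function(fl1, fl2, labels) {
  if (length(fl1) != length(fl2)) stop("'fl1' and 'fl2' must have equal length")
  labels <- check_labels(labels, seq_along(fl1))
  pts <- cbind(fl1, fl2)
  if (any(!is.finite(pts))) stop("non-finite loadings")
  A <- pts[labels == "control", , drop = FALSE]
  B <- pts[labels == "case", , drop = FALSE]
  centroid <- colMeans(pts)
  spread <- sqrt(mean(rowSums(sweep(pts, 2L, centroid)^2)))
  if (spread == 0) return(list(separable = FALSE, margin = 0))

  dirs <- matrix(numeric(0), ncol = 2L)
  # vertex-vertex: cross-class differences
  for (i in seq_len(nrow(A))) {
    dirs <- rbind(dirs, sweep(B, 2L, A[i, ]))
  }
  # vertex-edge: normals of within-class edges
  edge_normals <- function(P) {
    if (nrow(P) < 2L) return(matrix(numeric(0), ncol = 2L))
    out <- matrix(numeric(0), ncol = 2L)
    for (i in seq_len(nrow(P) - 1L)) {
      e <- sweep(P[seq.int(i + 1L, nrow(P)), , drop = FALSE], 2L, P[i, ])
      out <- rbind(out, cbind(-e[, 2L], e[, 1L]))
    }
    out
  }
  dirs <- rbind(dirs, edge_normals(A), edge_normals(B))
  len <- sqrt(rowSums(dirs^2))
  dirs <- dirs[len > 0, , drop = FALSE] / len[len > 0]
  if (!nrow(dirs)) return(list(separable = FALSE, margin = 0))

  pa <- A %*% t(dirs)
  pb <- B %*% t(dirs)
  gap <- pmax(apply(pb, 2L, min) - apply(pa, 2L, max),
              apply(pa, 2L, min) - apply(pb, 2L, max))
  best <- max(gap)
  list(separable = best > 0, margin = max(best, 0) / 2 / spread)
}

#' Select the asymmetric weights (a, b) by class separability
#'
#' Runs the full decomposition at every grid point and tests whether the two
#' classes are linearly separable in the plane of the first two factor
#' loadings ([separable()]) — the operational form of "the first two PCs
#' classify the samples correctly". Among the separable grid points the one
#' with the largest normalised margin is chosen; ties are broken by smaller
#' `b`, then smaller `a`, for determinism.
#'
#' @param x An [ExpressionMatrix()] with labels.
#' @param a_grid Candidate weights on the control-class covariance, all in
#'   (0, 1).
#' @param b_grid Candidate between-class weights.
#' @param preset Optional `c(a, b)`: bypass the search, evaluate and return
#'   these values as chosen.
#' @param basis,tol As in [apca()].
#' @return An object of class `"apca_selection"`: list with `chosen`
#'   (list `a`, `b`, `margin`; `NULL` when nothing separates), `feasible`
#'   (data.frame of separable grid points with margins), `all` (every grid
#'   point evaluated) and `status` (`"ok"` or `"no-separable-point"`).
#' @export
select_params <- function(x,
                          a_grid = seq(0.05, 0.95, by = 0.05),
                          b_grid = c(1, 2, 5, 10, 20, 30),
                          preset = NULL,
                          basis = c("raw", "orthonormal"),
                          tol = 1e-10) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  basis <- match.arg(basis)
  if (is.null(x$labels)) stop("expression matrix has no class labels; use set_labels()")
  if (!is.null(preset)) {
    if (length(preset) != 2L) stop("'preset' must be c(a, b)")
    a_grid <- preset[1L]
    b_grid <- preset[2L]
  }
  if (!length(a_grid) || !length(b_grid)) stop("parameter grids must be non-empty")
  if (any(a_grid <= 0 | a_grid >= 1)) stop("all 'a_grid' values must lie in (0, 1)")
  if (any(b_grid < 0)) stop("all 'b_grid' values must be nonnegative")

  gp <- gram_project(x$values, tol = tol, normalize = basis == "orthonormal")
  cs <- class_stats(gp$projected, x$labels)
  grid <- expand.grid(a = a_grid, b = b_grid, KEEP.OUT.ATTRS = FALSE)
  grid$separable <- FALSE
  grid$margin <- 0
  for (i in seq_len(nrow(grid))) {
    C <- weighted_covariance(cs$within_control, cs$within_case, cs$between,
                             a = grid$a[i], b = grid$b[i])
    dc <- decompose_covariance(C)
    pc1 <- drop(gp$basis %*% dc$eigenvectors[, 1L])
    pc2 <- drop(gp$basis %*% dc$eigenvectors[, 2L])
    fl1 <- factor_loadings(x, pc1)
    fl2 <- factor_loadings(x, pc2)
    sep <- separable(fl1, fl2, x$labels)
    grid$separable[i] <- sep$separable
    grid$margin[i] <- sep$margin
  }
  feasible <- grid[grid$separable, c("a", "b", "margin"), drop = FALSE]
  rownames(feasible) <- NULL
  chosen <- NULL
  status <- "no-separable-point"
  if (!is.null(preset)) {
    chosen <- list(a = preset[1L], b = preset[2L], margin = grid$margin[1L])
    status <- if (grid$separable[1L]) "ok" else "preset-not-separable"
  } else if (nrow(feasible)) {
    ord <- order(-feasible$margin, feasible$b, feasible$a)
    top <- feasible[ord[1L], ]
    chosen <- list(a = top$a, b = top$b, margin = top$margin)
    status <- "ok"
  } else {
    warning("no (a, b) grid point separates the classes in the FL1-FL2 plane")
  }
  structure(list(chosen = chosen, feasible = feasible, all = grid,
                 status = status),
            class = "apca_selection")
}

#' @export
print.apca_selection <- function(x, ...) {
  cat("APCA parameter selection: ", x$status, "\n", sep = "")
  if (!is.null(x$chosen)) {
    cat(sprintf("  chosen a = %g, b = %g (margin %.4g)\n",
                x$chosen$a, x$chosen$b, x$chosen$margin))
  }
  cat("  feasible points: ", nrow(x$feasible), " of ", nrow(x$all), "\n", sep = "")
  invisible(x)
}
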