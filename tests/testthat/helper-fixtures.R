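# Small builders and independent oracles shared across the test files.

make_em <- function(values, labels = NULL, probes = NULL, samples = NULL) {
  values <- as.matrix(values)
  ExpressionMatrix(
    values,
    probe_ids = probes %||% paste0("p", seq_len(nrow(values))),
    sample_ids = samples %||% paste0("s", seq_len(ncol(values))),
    labels = labels
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

quiet_collapse <- function(x) suppressMessages(collapse_duplicates(x))

# Brute-force AUC: fraction of case/control pairs won, ties counted half.
auc_brute <- function(values, labels) {
  pos <- values[labels == "case"]
  neg <- values[labels == "control"]
  mean(outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n)))
}

# Connected components by repeated label merging (transitive closure).
components_brute <- function(nodes, edges) {
  memb <- seq_along(nodes)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(edges))) {
      a <- match(edges$probe_a[i], nodes)
      b <- match(edges$probe_b[i], nodes)
      if (memb[a] != memb[b]) {
        memb[memb == memb[b]] <- memb[a]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(lapply(split(nodes, memb), sort))
}

# Exhaustive direction scan for planar hard-margin separability.
separable_scan <- function(fl1, fl2, labels, n_angles = 7200L) {
  pts <- cbind(fl1, fl2)
  A <- pts[labels == "control", , drop = FALSE]
  B <- pts[labels == "case", , drop = FALSE]
  best <- -Inf
  for (t in seq(0, pi, length.out = n_angles)) {
    w <- c(cos(t), sin(t))
    pa <- A %*% w
    pb <- B %*% w
    best <- max(best, min(pb) - max(pa), min(pa) - max(pb))
  }
  best
}
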