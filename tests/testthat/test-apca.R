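test_that("Gram projection reproduces the small worked example", {
  X <- matrix(c(1, 0, 1,
                0, 1, 1), ncol = 2) # columns (1,0,1), (0,1,1)
  gp <- gram_project(X)
  expect_equal(gp$gram_eigenvalues, c(3, 1))
  # normalized basis columns, up to sign
  b1 <- c(1, 1, 2) / sqrt(6)
  b2 <- c(1, -1, 0) / sqrt(2)
  expect_equal(abs(drop(crossprod(gp$basis[, 1], b1))), 1, tolerance = 1e-12)
  expect_equal(abs(drop(crossprod(gp$basis[, 2], b2))), 1, tolerance = 1e-12)
})

test_that("Gram eigenvalues equal the nonzero eigenvalues of the big scatter", {
  set.seed(42)
  for (i in 1:5) {
    X <- matrix(rnorm(18), 6, 3)
    small <- eigen(crossprod(X), symmetric = TRUE)$values
    big <- eigen(tcrossprod(X), symmetric = TRUE)$values
    expect_equal(small, big[1:3], tolerance = 1e-10)
  }
  expect_error(gram_project(matrix(0, 4, 3)), "zero matrix")
})

test_that("rank-deficient input drops the deficient direction", {
  set.seed(7)
  v <- matrix(rnorm(12), 6, 2)
  X <- cbind(v, v[, 1]) # identical columns
  gp <- gram_project(X)
  expect_lt(gp$rank, 3)
  expect_equal(crossprod(gp$basis), diag(gp$rank), tolerance = 1e-8)
})

test_that("class scatter matrices match the hand-computed toy example", {
  proj <- cbind(c(1, 0), c(-1, 0), c(0, 2), c(0, -2))
  cs <- class_stats(proj, c("control", "control", "case", "case"))
  expect_equal(cs$within_control, matrix(c(1, 0, 0, 0), 2), tolerance = 1e-14)
  expect_equal(cs$within_case, matrix(c(0, 0, 0, 4), 2), tolerance = 1e-14)
  expect_equal(cs$between, matrix(0, 2, 2), tolerance = 1e-14)
})

test_that("degenerate class layouts give zero scatter where expected", {
  # identical class means -> zero between-class scatter
  proj <- cbind(c(1, 1), c(-1, -1), c(2, 2), c(-2, -2))
  cs <- class_stats(proj, c("control", "control", "case", "case"))
  expect_equal(cs$between, matrix(0, 2, 2), tolerance = 1e-14)
  # single-sample class -> zero within-class covariance
  cs2 <- class_stats(cbind(c(1, 2), c(3, 4), c(5, 6)),
                     c("control", "control", "case"))
  expect_equal(cs2$within_case, matrix(0, 2, 2), tolerance = 1e-14)
})

test_that("weighted covariance combines terms with the stated arithmetic", {
  csn <- matrix(c(1, 0, 0, 0), 2)
  csd <- matrix(c(0, 0, 0, 1), 2)
  cs <- matrix(1, 2, 2)
  expect_equal(weighted_covariance(csn, csd, cs, a = 0.3, b = 20),
               matrix(c(20.3, 20, 20, 20.7), 2))
  z <- matrix(0, 2, 2)
  expect_equal(weighted_covariance(z, z, z, a = 0.5, b = 7), z)
  expect_error(weighted_covariance(csn, csd, cs, a = 1.2), "in \\(0, 1\\)")
  expect_error(weighted_covariance(csn, csd, cs, a = 0.3, b = -1), "nonnegative")
})

test_that("count-weighted combination equals the total covariance (PCA identity)", {
  set.seed(9)
  for (i in 1:5) {
    proj <- matrix(rnorm(7 * 12), 7, 12)
    labels <- rep(c("control", "case"), c(8, 4))
    cs <- class_stats(proj, labels)
    C <- weighted_covariance(cs$within_control, cs$within_case, cs$between,
                             a = 8 / 12, b = 1)
    Y <- proj - rowMeans(proj)
    expect_equal(C, tcrossprod(Y) / 12, tolerance = 1e-10)
  }
})

test_that("eigendecomposition reports sorted proportions summing to one", {
  dc <- decompose_covariance(diag(c(3, 1)))
  expect_equal(dc$proportions, c(0.75, 0.25))
  expect_equal(dc$cumulative, c(0.75, 1))
  dc3 <- decompose_covariance(diag(3))
  expect_equal(dc3$proportions, rep(1 / 3, 3))
  set.seed(2)
  A <- crossprod(matrix(rnorm(25), 5))
  dc5 <- decompose_covariance(A)
  expect_true(all(diff(dc5$eigenvalues) <= 0))
  expect_equal(sum(dc5$proportions), 1, tolerance = 1e-9)
  expect_true(all(diff(dc5$cumulative) >= -1e-12))
  expect_error(decompose_covariance(matrix(c(1, NA, NA, 1), 2)), "non-finite")
})

test_that("projected-route PCs match direct decomposition of the big scatter", {
  set.seed(31)
  for (i in 1:3) {
    m <- sample(10:50, 1)
    l <- sample(4:10, 1)
    n <- l - 2
    X <- matrix(rnorm(m * l), m, l)
    x <- make_em(X, labels = rep(c("control", "case"), c(n, 2)))
    fit <- apca(x, a = 0.4, b = 3, basis = "orthonormal")
    # oracle: same weighted covariance built in the full m-dim space
    cs <- class_stats(X, x$labels)
    Cbig <- weighted_covariance(cs$within_control, cs$within_case, cs$between,
                                a = 0.4, b = 3)
    eb <- eigen(Cbig, symmetric = TRUE)
    r <- fit$rank
    expect_equal(fit$eigenvalues[1:r], eb$values[1:r], tolerance = 1e-8)
    for (k in 1:2) {
      pc_fit <- unname(drop(fit$basis %*% fit$eigenvectors[, k]))
      align <- sign(sum(pc_fit * eb$vectors[, k]))
      expect_equal(pc_fit, align * eb$vectors[, k], tolerance = 1e-6)
    }
  }
})

test_that("gene scores are unit-norm, sign-oriented back-projections", {
  sim <- simulate_expression(synthetic_config(m = 120, n_control = 8, n_case = 4,
                                              n_de = 6, n_blocks = 0, seed = 2))
  fit <- apca(sim$x, a = 0.3, b = 20, basis = "orthonormal")
  for (k in c(1L, 2L, 3L)) {
    sc <- gene_scores(fit, k = k)
    expect_equal(sc$score, {
      s <- unname(drop(fit$basis %*% fit$eigenvectors[, k])) # brute-force product
      if (s[which.max(abs(s))] < 0) -s else s
    })
    expect_equal(sqrt(sum(sc$score^2)), 1, tolerance = 1e-8)
    expect_gt(sc$score[which.max(abs(sc$score))], 0)
  }
  expect_error(gene_scores(fit, k = 0), "between 1 and")
  expect_error(gene_scores(fit, k = fit$rank + 1), "between 1 and")
})

test_that("annotation symbols are carried into the score table", {
  sim <- simulate_expression(synthetic_config(m = 50, n_control = 5, n_case = 3,
                                              n_de = 0, n_blocks = 0, seed = 3))
  ann <- c(probe_00001 = "GENE1", probe_00002 = "HP /// HPR")
  sc <- gene_scores(apca(sim$x), annotation = ann)
  expect_equal(sc$gene_symbol[1:2], c("GENE1", "HP /// HPR"))
  expect_true(all(is.na(sc$gene_symbol[-(1:2)])))
})

test_that("factor loadings are Pearson correlations with the component", {
  set.seed(17)
  pc <- rnorm(50)
  vals <- cbind(2 * pc + 3, -pc, matrix(rnorm(150), 50, 3))
  x <- make_em(vals, labels = c("control", "control", "control", "case", "case"))
  fl <- factor_loadings(x, pc)
  expect_equal(unname(fl[1]), 1)
  expect_equal(unname(fl[2]), -1)
  # independent correlation oracle on the random columns
  for (j in 3:5) {
    v <- vals[, j]
    oracle <- sum((v - mean(v)) * (pc - mean(pc))) /
      sqrt(sum((v - mean(v))^2) * sum((pc - mean(pc))^2))
    expect_equal(unname(fl[j]), oracle, tolerance = 1e-12)
  }
  expect_true(all(abs(fl) <= 1))
  # zero-variance column is an error naming the sample
  bad <- vals; bad[, 2] <- 5
  xb <- make_em(bad)
  expect_error(factor_loadings(xb, pc), "zero-variance sample.*s2")
})

test_that("the PCA baseline equals an independent covariance eigendecomposition", {
  set.seed(23)
  X <- matrix(rnorm(200 * 12, 10), 200, 12)
  x <- make_em(X, labels = rep(c("control", "case"), c(8, 4)))
  base <- pca_baseline(x)
  Y <- X - matrix(rowMeans(X), 200, 12)
  ev <- eigen(crossprod(Y) / 12, symmetric = TRUE)$values # sample covariance route
  ev <- pmax(ev, 0)
  expect_equal(base$proportions, ev / sum(ev), tolerance = 1e-8)
  # balanced classes: a = 0.5, b = 1 is exactly the baseline
  xb <- make_em(X[, 1:8], labels = rep(c("control", "case"), each = 4))
  expect_equal(apca(xb, a = 0.5, b = 1)$eigenvalues,
               pca_baseline(xb)$eigenvalues, tolerance = 1e-12)
})

test_that("permuting samples with their labels leaves the fit invariant", {
  sim <- simulate_expression(synthetic_config(m = 150, n_control = 9, n_case = 5,
                                              n_de = 8, n_blocks = 0, seed = 4))
  x <- sim$x
  set.seed(1)
  perm <- sample(ncol(x$values))
  xp <- make_em(x$values[, perm], labels = as.character(x$labels)[perm],
                probes = x$probe_ids, samples = x$sample_ids[perm])
  f1 <- apca(x, a = 0.3, b = 20, basis = "orthonormal")
  f2 <- apca(xp, a = 0.3, b = 20, basis = "orthonormal")
  expect_equal(f1$eigenvalues, f2$eigenvalues, tolerance = 1e-8)
  expect_equal(gene_scores(f1, 2)$score, gene_scores(f2, 2)$score,
               tolerance = 1e-6)
})

test_that("rescaling the matrix scales eigenvalues by c^2 and nothing else", {
  sim <- simulate_expression(synthetic_config(m = 100, n_control = 7, n_case = 4,
                                              n_de = 5, n_blocks = 0, seed = 5))
  x <- sim$x
  cfac <- 3.7
  xs <- make_em(cfac * x$values, labels = as.character(x$labels),
                probes = x$probe_ids, samples = x$sample_ids)
  f1 <- apca(x, basis = "orthonormal")
  f2 <- apca(xs, basis = "orthonormal")
  expect_equal(f2$eigenvalues, cfac^2 * f1$eigenvalues, tolerance = 1e-8)
  expect_equal(f2$proportions, f1$proportions, tolerance = 1e-10)
  expect_equal(factor_loadings(f2, 2), factor_loadings(f1, 2), tolerance = 1e-8)
})
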