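test_that("within-class correlations follow affine relations exactly", {
  set.seed(12)
  g1 <- rnorm(10)
  vals <- rbind(g1, 2 * g1 + 3, -g1, matrix(rnorm(20), 2, 10))
  x <- make_em(vals, labels = rep(c("control", "case"), c(4, 6)))
  cc <- within_class_cc(x, x$probe_ids[1:3], group = "case")
  expect_equal(cc["p1", "p2"], 1, tolerance = 1e-12)
  expect_equal(cc["p1", "p3"], -1, tolerance = 1e-12)
  expect_equal(diag(cc), setNames(rep(1, 3), c("p1", "p2", "p3")))
})

test_that("within-class correlations match an independent oracle", {
  set.seed(13)
  vals <- matrix(rnorm(5 * 14), 5, 14)
  x <- make_em(vals, labels = rep(c("control", "case"), c(4, 10)))
  cc <- within_class_cc(x, x$probe_ids, group = "case")
  sub <- vals[, 5:14]
  for (i in 1:4) for (j in (i + 1):5) {
    a <- sub[i, ]; b <- sub[j, ]
    oracle <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(cc[i, j], oracle, tolerance = 1e-12)
  }
  # zero-variance probe in the group is excluded with a warning
  vals2 <- vals; vals2[2, 5:14] <- 7
  x2 <- make_em(vals2, labels = rep(c("control", "case"), c(4, 10)))
  expect_warning(cc2 <- within_class_cc(x2, x2$probe_ids, group = "case"),
                 "zero-variance probe")
  expect_equal(nrow(cc2), 4)
  # and the group must have at least 3 samples
  x3 <- make_em(vals, labels = rep(c("control", "case"), c(12, 2)))
  expect_error(within_class_cc(x3, x3$probe_ids, group = "case"), "at least 3")
})

test_that("network thresholding is inclusive and components are transitive", {
  cc <- diag(3)
  dimnames(cc) <- list(paste0("g", 1:3), paste0("g", 1:3))
  cc["g1", "g2"] <- cc["g2", "g1"] <- 0.95
  cc["g1", "g3"] <- cc["g3", "g1"] <- 0.1
  cc["g2", "g3"] <- cc["g3", "g2"] <- 0.2
  net <- build_network(cc, tau = 0.9)
  expect_equal(unname(net$summary), c(0L, 1L, 1L)) # one pair, one singleton
  # inclusive threshold: an edge exactly at tau stays
  expect_equal(nrow(build_network(cc, tau = 0.95)$edges), 1)

  # chain: components are transitive even though edges are not
  cc2 <- diag(3)
  dimnames(cc2) <- dimnames(cc)
  cc2["g1", "g2"] <- cc2["g2", "g1"] <- 0.92
  cc2["g2", "g3"] <- cc2["g3", "g2"] <- 0.92
  cc2["g1", "g3"] <- cc2["g3", "g1"] <- 0.1
  net2 <- build_network(cc2, tau = 0.9)
  expect_equal(length(net2$components), 1)
  expect_equal(sort(net2$components[[1]]), c("g1", "g2", "g3"))

  # vacuous threshold: edgeless graph, all singletons
  net3 <- build_network(cc2, tau = 1.01)
  expect_equal(nrow(net3$edges), 0)
  expect_equal(unname(net3$summary), c(0L, 0L, 3L))
})

test_that("component partition matches exhaustive closure on random graphs", {
  set.seed(14)
  for (i in 1:10) {
    nn <- sample(4:10, 1)
    nodes <- paste0("n", seq_len(nn))
    cc <- diag(nn)
    dimnames(cc) <- list(nodes, nodes)
    for (a in 1:(nn - 1)) for (b in (a + 1):nn) {
      v <- ifelse(runif(1) < 0.25, runif(1, 0.9, 1), runif(1, -1, 0.5))
      cc[a, b] <- cc[b, a] <- v
    }
    net <- build_network(cc, tau = 0.9)
    oracle <- components_brute(nodes, net$edges)
    got <- lapply(net$components, sort)
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(oracle, paste, collapse = ","))
    # partition: sizes sum to node count
    expect_equal(sum(lengths(net$components)), nn)
  }
})

test_that("AUC equals the Mann-Whitney pair count on worked examples", {
  lab4 <- c("case", "case", "control", "control")
  expect_equal(auc_single(c(4, 3, 2, 1), lab4)$auc, 1)
  expect_equal(auc_single(c(1, 1, 1, 1), lab4)$auc, 0.5)
  expect_equal(auc_single(c(3, 1, 2, 0), lab4)$auc, 0.75) # 3 of 4 pairs won
})

test_that("AUC matches brute-force pair counting and wilcox/pROC cross-checks", {
  set.seed(15)
  for (i in 1:10) {
    n1 <- sample(3:6, 1)
    n0 <- sample(3:6, 1)
    lab <- rep(c("case", "control"), c(n1, n0))
    v <- sample(1:5, n1 + n0, replace = TRUE) + rnorm(n1 + n0, 0, 0.01 * (i %% 2))
    r <- auc_single(v, lab)
    expect_equal(r$auc, auc_brute(v, lab), tolerance = 1e-12)
    w <- suppressWarnings(wilcox.test(v[lab == "case"], v[lab == "control"]))
    expect_equal(r$auc, unname(w$statistic) / (n1 * n0), tolerance = 1e-12)
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    v <- rnorm(12)
    lab <- rep(c("case", "control"), each = 6)
    r <- auc_single(v, lab)
    p <- pROC::roc(response = lab, predictor = v, levels = c("control", "case"),
                   direction = "<", quiet = TRUE)
    expect_equal(r$auc, as.numeric(pROC::auc(p)), tolerance = 1e-12)
  }
})

test_that("ROC curves run from (0,0) to (1,1) monotonically", {
  set.seed(16)
  v <- c(rnorm(5, 1), rnorm(7))
  lab <- rep(c("case", "control"), c(5, 7))
  cur <- auc_single(v, lab)$curve
  expect_equal(unlist(cur[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(cur[nrow(cur), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(cur$fpr) >= 0))
  expect_true(all(diff(cur$tpr) >= 0))
})

test_that("AUC symmetry and rank invariance hold", {
  set.seed(18)
  lab <- rep(c("case", "control"), c(5, 6))
  v <- rnorm(11) # tie-free
  expect_equal(auc_single(v, lab)$auc + auc_single(-v, lab)$auc, 1)
  expect_equal(auc_single(v, lab)$auc, auc_single(exp(v), lab)$auc)
  expect_equal(auc_single(v, lab)$auc, auc_single(rank(v), lab)$auc)
})

test_that("p-values are finite, never zero, and formatted with a floor", {
  v <- c(rnorm(50, 5), rnorm(50))
  lab <- rep(c("case", "control"), each = 50)
  r <- auc_single(v, lab)
  expect_gt(r$p_value, 0)
  expect_lt(r$p_value, 1e-10)
  expect_equal(format_pvalue(1e-20), "<1e-15")
  expect_equal(format_pvalue(0.004), "0.004")
})

test_that("combinations align orientations and can beat single markers", {
  set.seed(20)
  lab <- rep(c("control", "case"), c(10, 8))
  sig <- as.numeric(lab == "case")
  # two perfect markers with consistent orientation stay perfect
  v1 <- sig + 0.01 * rnorm(18)
  v2 <- 2 * sig + 0.01 * rnorm(18)
  x <- make_em(rbind(v1, v2, rnorm(18)), labels = lab)
  expect_equal(auc_combination(x, c("p1", "p2"), c(1, 1))$auc, 1)

  # a probe and its exact negation with opposite orientations rank like the probe
  x2 <- make_em(rbind(v1, -v1, rnorm(18)), labels = lab)
  expect_equal(auc_combination(x2, c("p1", "p2"), c(1, -1))$auc,
               auc_single(v1, lab)$auc)

  # two weak anticorrelated-noise markers combine to beat both singles
  e <- rnorm(18, 0, 3)
  w1 <- 0.8 * sig + e
  w2 <- 0.8 * sig - e
  x3 <- make_em(rbind(w1, w2, rnorm(18)), labels = lab)
  single_best <- max(auc_single(w1, lab)$auc, auc_single(w2, lab)$auc)
  combined <- auc_combination(x3, c("p1", "p2"), c(1, 1))$auc
  expect_gt(combined, single_best)

  # zero-variance probes are excluded with a warning
  x4 <- make_em(rbind(v1, rep(2, 18), rnorm(18)), labels = lab)
  expect_warning(r4 <- auc_combination(x4, c("p1", "p2"), c(1, 1)),
                 "zero-variance")
  expect_equal(r4$genes, "p1")
})
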