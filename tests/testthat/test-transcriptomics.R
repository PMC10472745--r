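# Differential expression, FDR, PLS-DA / VIP, and the panel ROC.

test_that("log transform is log2 with pseudo-count 1", {
  expect_equal(log_transform(matrix(0)), matrix(0))
  expect_equal(log_transform(matrix(1)), matrix(1))
  expect_equal(log_transform(matrix(1023)), matrix(10))
  expect_error(log_transform(matrix(-1)), "non-negative")
})

test_that("moderated t reduces to the ordinary t when d0 is forced to 0", {
  set.seed(21)
  mat <- matrix(rnorm(50 * 12, 5, 1), 50,
                dimnames = list(sprintf("G%02d", 1:50), NULL))
  groups <- rep(c("a", "b"), each = 6)
  de <- moderated_de(mat, groups, d0_override = 0)
  want <- tstat_bruteforce(mat, groups == "a")
  expect_equal(de$t, unname(want), tolerance = 1e-9)
  # and the p-values match the ordinary two-sided t on n - 2 df
  expect_equal(de$p_value, unname(2 * pt(abs(want), 10, lower.tail = FALSE)),
               tolerance = 1e-9)
})

test_that("moderated statistics agree with limma's empirical Bayes", {
  skip_if_not_installed("limma")
  set.seed(22)
  mat <- matrix(rnorm(200 * 10, 6, sqrt(rchisq(200, 4) / 4)), 200, 10)
  rownames(mat) <- sprintf("G%03d", 1:200)
  groups <- rep(c("a", "b"), each = 5)
  de <- moderated_de(mat, groups)
  design <- cbind(1, groups == "b")
  fit <- limma::eBayes(limma::lmFit(mat, design))
  expect_equal(attr(de, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(de, "s0_sq"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(de$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(de$p_value, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("null data give uniform p-values and no DEG-filter survivors", {
  set.seed(23)
  surv <- raw05 <- numeric(20)
  for (r in 1:20) {
    ex <- generate_expression(expr_config(n_genes = 300L,
                                          n_per_group = c(10L, 10L),
                                          planted_de_count = 0L,
                                          seed = 400L + r))
    de <- moderated_de(log_transform(ex$tpm), ex$groups)
    raw05[r] <- mean(de$p_value < 0.05, na.rm = TRUE)
    surv[r] <- nrow(de_filter(de)$genes)
  }
  expect_equal(mean(raw05), 0.05, tolerance = 0.3)
  expect_lt(mean(surv), 1)
})

test_that("planted effects are recovered with high sensitivity", {
  ex <- generate_expression(expr_config(n_genes = 800L,
                                        n_per_group = c(20L, 20L),
                                        planted_de_count = 40L,
                                        planted_log2fc = 2, sigma = 0.5,
                                        seed = 31L))
  de <- moderated_de(log_transform(ex$tpm), ex$groups)
  hits <- de_filter(de)$genes$gene_id
  sens <- mean(ex$planted$gene_id %in% hits)
  expect_gt(sens, 0.9)
  # recovered directions match the planted signs
  sub <- de[match(ex$planted$gene_id, de$gene_id), ]
  expect_true(all(sign(sub$log2fc) == sign(ex$planted$log2fc)))
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(24)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_fdr(p), bh_bruteforce(p), tolerance = 1e-12)
  }
  # idempotence (up to clipping)
  p <- runif(30)
  expect_equal(bh_fdr(bh_fdr(p)) >= bh_fdr(p), rep(TRUE, 30))
})

test_that("DE filter applies strict boundaries on both criteria", {
  de <- data.frame(gene_id = c("a", "b", "c", "d"),
                   log2fc = c(log2(5), 1.0, 3, -1.5),
                   t = 0, p_value = 0,
                   adj_p = c(0.0047, 0.01, 0.05, 0.01))
  class(de) <- c("de_result", "data.frame")
  out <- de_filter(de)
  expect_true("a" %in% out$genes$gene_id)       # 5-fold, adj p .0047
  expect_false("b" %in% out$genes$gene_id)      # |log2FC| = 1 exactly: excluded
  expect_false("c" %in% out$genes$gene_id)      # adj p = .05 exactly: excluded
  expect_true("d" %in% out$genes$gene_id)
  expect_equal(out$n_up, 1L)
  expect_equal(out$n_down, 1L)
})

test_that("PLS-DA: dominance, orthogonality, algebraic weight oracle", {
  set.seed(25)
  n <- 16L
  y <- rep(c(0, 1), each = 8)
  mat <- matrix(rnorm(10 * n), 10, n,
                dimnames = list(sprintf("G%02d", 1:10), NULL))
  mat[3, ] <- mat[3, ] * 0.05 + y * 5  # one near-perfectly separating gene
  m <- plsda_fit(mat, y, n_components = 2L)
  expect_equal(which.max(abs(m$weights[, 1L])), 3L)
  expect_lt(abs(sum(m$scores[, 1L] * m$scores[, 2L])), 1e-8)

  # component-1 weights equal the dominant eigenvector of X'yy'X (power
  # iteration oracle), up to sign
  X <- scale(t(mat))
  yc <- y - mean(y)
  M <- crossprod(X, yc) %*% crossprod(yc, X)   # X'y y'X
  v <- rnorm(10)
  for (i in 1:200) { v <- M %*% v; v <- v / sqrt(sum(v^2)) }
  w1 <- m$weights[, 1L]
  expect_equal(abs(sum(w1 * v)), 1, tolerance = 1e-6)

  expect_error(plsda_fit(mat, rep(1, n)), "both classes")
  expect_error(plsda_fit(mat, y, n_components = 50L), "rank")
  matc <- mat; matc[5, ] <- 2
  expect_warning(plsda_fit(matc, y), "constant")
})

test_that("VIP scores: symmetry, exact mean-square identity, selection rule", {
  # identical weights across genes (one component) -> all VIP exactly 1
  set.seed(26)
  y <- rep(c(0, 1), each = 10)
  base <- y * 2 + rnorm(20, 0, 0.5)
  mat <- rbind(base, base, base, base) +
    matrix(rnorm(80, 0, 1e-6), 4)     # four essentially identical genes
  rownames(mat) <- sprintf("G%d", 1:4)
  m1 <- plsda_fit(mat, y, n_components = 1L)
  expect_equal(unname(vip_scores(m1)), rep(1, 4), tolerance = 1e-3)

  # mean VIP^2 = 1 exactly on arbitrary fitted models
  for (s in 1:5) {
    set.seed(s)
    mm <- matrix(rnorm(30 * 14), 30, 14,
                 dimnames = list(sprintf("g%02d", 1:30), NULL))
    yy <- rep(c(0, 1), each = 7)
    fit <- plsda_fit(mm, yy, n_components = 2L)
    expect_equal(mean(vip_scores(fit)^2), 1, tolerance = 1e-12)
  }
})

test_that("panel AUC: perfect gene, permuted labels, bootstrap CI", {
  set.seed(27)
  y <- rep(c(0, 1), each = 15)
  mat <- matrix(rnorm(5 * 30, 5, 1), 5, 30,
                dimnames = list(sprintf("G%d", 1:5), sprintf("S%d", 1:30)))
  mat[2, ] <- y * 10 + rnorm(30, 0, 0.01)
  res <- panel_auc(mat, "G2", y, n_boot = 200L, seed = 9L)
  expect_equal(res$auroc, 1.0)
  expect_equal(unname(res$ci[2L]), 1.0)

  yp <- sample(y)
  res2 <- panel_auc(mat, c("G1", "G3", "G4"), yp, n_boot = 200L, seed = 9L)
  expect_lt(abs(res2$auroc - 0.5), 0.35)

  expect_error(panel_auc(mat, c("G2", "NOPE"), y), "NOPE")
  # deterministic given the seed
  expect_identical(panel_auc(mat, "G2", y, n_boot = 100L, seed = 5L)$ci,
                   panel_auc(mat, "G2", y, n_boot = 100L, seed = 5L)$ci)
})

test_that("robust prior fit resists outlier-variance genes", {
  set.seed(28)
  mat <- matrix(rnorm(200 * 10, 0, 0.5), 200, 10,
                dimnames = list(sprintf("G%03d", 1:200), NULL))
  mat[1:5, ] <- matrix(rnorm(50, 0, 20), 5)  # a few wild-variance genes
  grp <- rep(c("a", "b"), each = 5)
  plain <- moderated_de(mat, grp)
  rob <- moderated_de(mat, grp, robust = TRUE)
  # outlier variances fake between-gene heterogeneity, shrinking the plain
  # prior df; the winsorized fit sees a homogeneous background and recovers
  # the true background variance 0.25
  expect_gt(attr(rob, "d0"), attr(plain, "d0"))
  expect_lt(abs(attr(rob, "s0_sq") - 0.25), abs(attr(plain, "s0_sq") - 0.25))
  expect_equal(attr(rob, "s0_sq"), 0.25, tolerance = 0.1)
})
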