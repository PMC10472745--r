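# Responder-vs-nonresponder transcriptomics: log2(TPM+1) transformation,
# empirical-Bayes moderated-t differential expression, BH-FDR, fold-change
# filtering, PLS-DA with VIP gene reduction, and combined-panel ROC.

#' Log-transform a TPM matrix with a pseudo-count of 1
#'
#' Elementwise log2(x + 1). Base 2 makes the conventional "greater than
#' 2-fold change" filter equal to |log2FC| > 1.
#'
#' @param tpm non-negative numeric matrix (genes x samples).
#' @return matrix of the same shape.
#' @export
log_transform <- function(tpm) {
  tpm <- as.matrix(tpm)
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  log2(tpm + 1)
}

#' Empirical-Bayes moderated two-group differential expression
#'
#' Per gene, an ordinary two-group linear model (the two group means) is
#' fitted on the log scale; the residual variances s_g^2 (d_g = n - 2 df)
#' are shrunk toward a common prior by the standard empirical-Bayes scheme:
#' the prior df d0 and prior variance s0^2 are estimated by moments on the
#' scaled-F distribution of the s_g^2 (via the log-variance / trigamma
#' method), and the posterior variance is
#' s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g). The moderated t is
#' delta_mean / (s~_g sqrt(1/n1 + 1/n2)) on d0 + d_g df.
#'
#' @param log_mat log2(TPM+1) matrix, genes x samples (>= 10 genes).
#' @param groups factor/character of length ncol with exactly 2 levels;
#'   the log2 fold change is mean(level 2) - mean(level 1), i.e. for a
#'   factor with levels `c("nonresponder", "responder")` positive log2FC
#'   means higher in responders.
#' @param d0_override force the prior df (0 recovers the ordinary t-test;
#'   `Inf` gives the fully pooled statistic). `NULL` (default) estimates it.
#' @param robust if `TRUE`, the prior is fitted on winsorized log-variances
#'   (5th/95th percentile), which keeps a handful of outlier-variance genes
#'   from inflating the prior; the per-gene variances themselves are not
#'   altered.
#' @return data frame (class `de_result`) with one row per gene: `gene_id`,
#'   `log2fc`, `t`, `p_value`, `adj_p`, plus attributes `d0` and `s0_sq`.
#'   Genes with zero residual variance and zero prior get `NA` p-values.
#' @export
moderated_de <- function(log_mat, groups, d0_override = NULL, robust = FALSE) {
  log_mat <- as.matrix(log_mat)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly 2 levels")
  if (ncol(log_mat) != length(groups)) stop("groups length must match columns")
  n1 <- sum(groups == levels(groups)[1L])
  n2 <- sum(groups == levels(groups)[2L])
  if (n1 < 2L || n2 < 2L) stop("need >= 2 samples per group")
  if (nrow(log_mat) < 10L) stop("need >= 10 genes to estimate the prior")

  g1 <- groups == levels(groups)[1L]
  m1 <- rowMeans(log_mat[, g1, drop = FALSE])
  m2 <- rowMeans(log_mat[, !g1, drop = FALSE])
  ss <- rowSums((log_mat[, g1, drop = FALSE] - m1)^2) +
    rowSums((log_mat[, !g1, drop = FALSE] - m2)^2)
  dg <- n1 + n2 - 2L
  s2 <- ss / dg

  if (is.null(d0_override)) {
    fd <- fit_f_dist(s2, dg, robust = robust)
    d0 <- fd$d0; s0_sq <- fd$s0_sq
  } else {
    d0 <- d0_override
    s0_sq <- if (is.finite(d0) && d0 > 0) fit_f_dist(s2, dg, robust = robust)$s0_sq
    else if (is.infinite(d0)) mean(s2) else 0
  }

  post_var <- if (is.infinite(d0)) rep(s0_sq, length(s2))
  else (d0 * s0_sq + dg * s2) / (d0 + dg)
  se <- sqrt(post_var * (1 / n1 + 1 / n2))
  delta <- m2 - m1
  tstat <- ifelse(se > 0, delta / se, NA_real_)
  df_total <- if (is.infinite(d0)) Inf else d0 + dg
  p <- 2 * stats::pt(abs(tstat), df = df_total, lower.tail = FALSE)
  res <- data.frame(
    gene_id = if (is.null(rownames(log_mat))) sprintf("g%d", seq_len(nrow(log_mat)))
    else rownames(log_mat),
    log2fc = delta, t = tstat, p_value = p,
    adj_p = bh_fdr(p), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "d0") <- d0
  attr(res, "s0_sq") <- s0_sq
  class(res) <- c("de_result", "data.frame")
  res
}

# Method-of-moments fit of s^2 ~ s0^2 * F(dg, d0) on the log scale:
# z = log(s^2) has E[z] = log(s0^2) + digamma(dg/2) - log(dg/2)
#                        - digamma(d0/2) + log(d0/2)
# and Var[z] = trigamma(dg/2) + trigamma(d0/2), so d0 follows from the
# excess variance of z via the inverse trigamma and s0^2 from the mean.
fit_f_dist <- function(s2, dg, robust = FALSE) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2L) stop("too few positive variances to fit the prior")
  z <- log(s2)
  e <- z - digamma(dg / 2) + log(dg / 2)
  if (robust) {
    qs <- stats::quantile(e, c(0.05, 0.95), type = 7)
    e <- pmin(pmax(e, qs[1L]), qs[2L])
  }
  ev <- mean((e - mean(e))^2) * length(e) / (length(e) - 1L) - trigamma(dg / 2)
  if (ev > 0) {
    d0 <- 2 * trigamma_inverse(ev)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(mean(e))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton inversion of the trigamma function (monotone decreasing on (0, Inf)).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (k in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with cumulative-minimum enforcement; `NA`
#' p-values are left `NA` and excluded from the number of tests.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Filter a DE table by FDR and fold change
#'
#' Retains genes with adjusted p strictly below `alpha` AND absolute fold
#' change strictly greater than `fc_threshold` (i.e. |log2FC| > log2(fc)),
#' both boundaries exclusive.
#'
#' @param de a `de_result` from [moderated_de()].
#' @param fc_threshold fold-change threshold on the linear scale (default 2).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return list with `genes` (data frame of surviving rows, with
#'   `direction`), `n_up`, `n_down`.
#' @export
de_filter <- function(de, fc_threshold = 2, alpha = 0.05) {
  keep <- !is.na(de$adj_p) & de$adj_p < alpha &
    abs(de$log2fc) > log2(fc_threshold)
  g <- de[keep, , drop = FALSE]
  g$direction <- ifelse(g$log2fc > 0, "up", "down")
  list(genes = g, n_up = sum(g$direction == "up"),
       n_down = sum(g$direction == "down"))
}

#' PLS-DA fit (NIPALS PLS1 against a 0/1 class vector)
#'
#' Columns (genes) are mean-centered and, by default, scaled to unit
#' variance; the class vector is centered. Components are extracted by
#' NIPALS with X-deflation, so score vectors are mutually orthogonal and
#' the fit is deterministic. Constant gene columns are dropped with a
#' warning.
#'
#' @param log_mat log-scale matrix, genes x samples (typically restricted
#'   to the DEG set).
#' @param labels binary vector (1 = responder), length = ncol.
#' @param n_components number of latent components (default 2).
#' @param scale unit-variance scaling (default `TRUE`).
#' @return object of class `pls_model`: `weights` (p x A), `scores` (n x A),
#'   `loadings` (p x A), `ssy` (class variance explained per component),
#'   `genes`, plus the centering/scaling vectors.
#' @export
plsda_fit <- function(log_mat, labels, n_components = 2L, scale = TRUE) {
  X <- t(as.matrix(log_mat))            # samples x genes
  y <- as.numeric(labels)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2L) stop("need both classes")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene column(s) dropped")
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  p <- ncol(X); n <- nrow(X)
  if (n_components > min(n - 1L, p)) stop("n_components exceeds the rank bound")
  ctr <- colMeans(X)
  X <- sweep(X, 2L, ctr)
  scl <- if (scale) sds else rep(1, p)
  X <- sweep(X, 2L, scl, "/")
  yc <- y - mean(y)

  W <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  P <- matrix(0, p, n_components)
  ssy <- numeric(n_components)
  Xd <- X
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(Xd, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("no remaining covariance with the class at component ", a)
    w <- w / nw
    tvec <- drop(Xd %*% w)
    tt <- sum(tvec^2)
    pvec <- drop(crossprod(Xd, tvec)) / tt
    b <- sum(tvec * yc) / tt
    ssy[a] <- b^2 * tt                  # class variance explained by component a
    Xd <- Xd - tcrossprod(tvec, pvec)
    W[, a] <- w; Tm[, a] <- tvec; P[, a] <- pvec
  }
  structure(list(weights = W, scores = Tm, loadings = P, ssy = ssy,
                 genes = colnames(X), center = ctr, scale_vec = scl,
                 y_mean = mean(y), n_components = n_components),
            class = "pls_model")
}

#' Variable importance in projection (VIP) scores
#'
#' VIP_j = sqrt(p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a), where
#' SSY_a is the class variance explained by component a. The mean of the
#' squared VIPs is exactly 1 (sum VIP^2 = p), so VIP > 1 marks genes
#' contributing more than an average gene; that is the selection rule used
#' downstream.
#'
#' @param model a fitted [plsda_fit()] model.
#' @return named numeric vector of VIP scores (>= 0), one per gene.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  W <- model$weights
  ssy <- model$ssy
  tot <- sum(ssy)
  if (tot <= 0) stop("model explains zero class variance; VIP undefined")
  w2 <- sweep(W^2, 2L, colSums(W^2), "/")       # (w_ja/||w_a||)^2
  vip <- sqrt(nrow(W) * drop(w2 %*% ssy) / tot)
  stats::setNames(vip, model$genes)
}

# Component-1 composite score for new samples (columns of log_mat).
pls_predict_score <- function(model, log_mat) {
  X <- t(as.matrix(log_mat)[model$genes, , drop = FALSE])
  X <- sweep(X, 2L, model$center)
  X <- sweep(X, 2L, model$scale_vec, "/")
  drop(X %*% model$weights[, 1L])
}

#' Combined-panel ROC via the PLS composite score
#'
#' Fits a PLS-DA model on the panel genes and uses the first-component
#' score as the composite predictor; reports its AUROC with a stratified
#' percentile bootstrap confidence interval.
#'
#' @param log_mat log-scale matrix (genes x samples) containing the panel.
#' @param panel character vector of gene ids (non-empty).
#' @param labels binary labels (1 = responder).
#' @param n_boot bootstrap resamples (default 2000).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return list with `auroc`, `ci` (length-2), `scores` (the composite),
#'   `panel`.
#' @export
panel_auc <- function(log_mat, panel, labels, n_boot = 2000L, conf = 0.95,
                      seed = 1L) {
  if (!length(panel)) stop("panel is empty")
  absent <- setdiff(panel, rownames(log_mat))
  if (length(absent)) {
    stop("panel gene(s) absent from matrix: ", paste(absent, collapse = ", "))
  }
  labels <- as.integer(labels)
  sub <- log_mat[panel, , drop = FALSE]
  model <- plsda_fit(sub, labels, n_components = 1L)
  score <- pls_predict_score(model, sub)
  # orient the composite toward the positive class so AUROC >= 0.5 by fit
  if (stats::cor(score, labels) < 0) score <- -score
  auc <- roc_auc(score, labels)
  ipos <- which(labels == 1L); ineg <- which(labels == 0L)
  boots <- withr::with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(ipos, length(ipos), replace = TRUE),
             sample(ineg, length(ineg), replace = TRUE))
    roc_auc(score[idx], labels[idx])
  }, numeric(1L)))
  alpha <- (1 - conf) / 2
  list(auroc = auc,
       ci = unname(stats::quantile(boots, c(alpha, 1 - alpha), type = 7)),
       scores = score, panel = panel)
}
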