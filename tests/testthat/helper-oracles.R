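# Fixture builders and independent oracles used across tests. These are
# written from first principles (closed forms, brute force) and do not call
# into the package's own geometry helpers.

make_circle <- function(cx, cy, r, n = 360L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(t), cy + r * sin(t))
}

make_ellipse <- function(cx, cy, a, b, theta = 0, n = 360L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x <- a * cos(t); y <- b * sin(t)
  cbind(cx + x * cos(theta) - y * sin(theta),
        cy + x * sin(theta) + y * cos(theta))
}

make_square <- function(cx, cy, half) {
  cbind(cx + c(-half, half, half, -half), cy + c(-half, -half, half, half))
}

# Semicircular arc as an open polyline of n vertices.
make_semicircle <- function(r, n = 100L) {
  t <- seq(0, pi, length.out = n)
  cbind(r * cos(t), r * sin(t))
}

# Brute-force Benjamini-Hochberg: adj_i = min_{k : p_(k) >= p_i over the
# step-up path} (m * p_(k) / k), straight from the definition.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force all-pairs AUROC with half-credit for ties.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (s in pos) total <- total + sum(s > neg) + 0.5 * sum(s == neg)
  total / (length(pos) * length(neg))
}

# Brute-force minimum vertex-to-vertex distance between two point sets.
icd_bruteforce <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
    }
  }
  best
}

# Distance from the centre of an axis-aligned square (half-width h) to its
# boundary along direction angle th: h / max(|cos|, |sin|).
square_ray_gap_oracle <- function(h_outer, h_inner, n_rays = 72L) {
  th <- seq(0, 2 * pi, length.out = n_rays + 1L)[-(n_rays + 1L)]
  m <- pmax(abs(cos(th)), abs(sin(th)))
  mean(h_outer / m - h_inner / m)
}

# Ordinary two-sample equal-variance t statistic per gene (rows).
tstat_bruteforce <- function(mat, g1) {
  m1 <- rowMeans(mat[, g1, drop = FALSE])
  m2 <- rowMeans(mat[, !g1, drop = FALSE])
  n1 <- sum(g1); n2 <- sum(!g1)
  sp2 <- (rowSums((mat[, g1, drop = FALSE] - m1)^2) +
            rowSums((mat[, !g1, drop = FALSE] - m2)^2)) / (n1 + n2 - 2)
  (m2 - m1) / sqrt(sp2 * (1 / n1 + 1 / n2))
}
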