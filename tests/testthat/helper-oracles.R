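# Independent brute-force reference implementations. Everything here is
# written as plain nested loops over pixels, deliberately sharing no code
# with the package internals, so the fast implementations can be checked
# against them on small inputs.

# Replicate-boundary pixel lookup.
px <- function(x, i, j) {
  i <- min(max(i, 1L), nrow(x))
  j <- min(max(j, 1L), ncol(x))
  x[i, j]
}

# Maximum-symmetric-surround saliency: for each pixel the largest centred
# window that fits, mean normalized by window area, squared difference with
# the 3x3 binomial-smoothed value.
oracle_mss <- function(band) {
  h <- nrow(band); w <- ncol(band)
  out <- matrix(0, h, w)
  bw <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1) / 16, 3, 3)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      sm <- 0
      for (a in -1:1) for (b in -1:1)
        sm <- sm + bw[a + 2, b + 2] * px(band, i + a, j + b)
      m <- min(i - 1L, h - i)
      n <- min(j - 1L, w - j)
      tot <- 0
      for (a in (i - m):(i + m)) for (b in (j - n):(j + n))
        tot <- tot + band[a, b]
      mu <- tot / ((2 * m + 1) * (2 * n + 1))
      out[i, j] <- (sm - mu)^2
    }
  }
  out
}

# Sum of a map over an n x n patch at 1-based origin (r, c).
oracle_patch_sum <- function(map, r, c, n) {
  s <- 0
  for (a in r:(r + n - 1L)) for (b in c:(c + n - 1L)) s <- s + map[a, b]
  s
}

# Overlap-averaged reconstruction from per-patch pixel blocks.
oracle_overlap_average <- function(blocks, rows, cols, n, shape) {
  acc <- matrix(0, shape[1], shape[2])
  cnt <- matrix(0, shape[1], shape[2])
  for (k in seq_along(blocks)) {
    for (a in 0:(n - 1L)) {
      for (b in 0:(n - 1L)) {
        acc[rows[k] + a, cols[k] + b] <- acc[rows[k] + a, cols[k] + b] +
          blocks[[k]][a + 1L, b + 1L]
        cnt[rows[k] + a, cols[k] + b] <- cnt[rows[k] + a, cols[k] + b] + 1
      }
    }
  }
  acc / cnt
}

# Joint-histogram mutual information in bits, 0 log 0 = 0.
oracle_mi_pair <- function(x, y, bins) {
  joint <- matrix(0, bins, bins)
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      bx <- min(floor(x[i, j] * bins) + 1L, bins)
      by <- min(floor(y[i, j] * bins) + 1L, bins)
      joint[bx, by] <- joint[bx, by] + 1
    }
  }
  p <- joint / sum(joint)
  mi <- 0
  for (u in seq_len(bins)) {
    for (v in seq_len(bins)) {
      if (p[u, v] > 0) {
        pu <- sum(p[u, ]); pv <- sum(p[, v])
        mi <- mi + p[u, v] * log2(p[u, v] / (pu * pv))
      }
    }
  }
  mi
}

oracle_mi <- function(a, b, f, bins) {
  oracle_mi_pair(a, f, bins) + oracle_mi_pair(b, f, bins)
}

oracle_sd <- function(f) {
  v <- 0; n <- length(f)
  mu <- 0
  for (t in as.vector(f)) mu <- mu + t * 255 / n
  for (t in as.vector(f)) v <- v + (t * 255 - mu)^2 / n
  sqrt(v)
}

oracle_mean <- function(f) {
  s <- 0
  for (t in as.vector(f)) s <- s + t
  255 * s / length(f)
}

oracle_sf <- function(f) {
  g <- f * 255
  h <- nrow(g); w <- ncol(g)
  rf <- 0
  for (i in seq_len(h)) for (j in 2:w) rf <- rf + (g[i, j] - g[i, j - 1])^2
  rf <- rf / (h * (w - 1))
  cf <- 0
  for (i in 2:h) for (j in seq_len(w)) cf <- cf + (g[i, j] - g[i - 1, j])^2
  cf <- cf / ((h - 1) * w)
  sqrt(rf + cf)
}

# Scalar Sobel responses with replicate boundary.
oracle_sobel_at <- function(x, i, j) {
  gx <- -px(x, i - 1, j - 1) + px(x, i - 1, j + 1) -
    2 * px(x, i, j - 1) + 2 * px(x, i, j + 1) -
    px(x, i + 1, j - 1) + px(x, i + 1, j + 1)
  gy <- -px(x, i - 1, j - 1) - 2 * px(x, i - 1, j) - px(x, i - 1, j + 1) +
    px(x, i + 1, j - 1) + 2 * px(x, i + 1, j) + px(x, i + 1, j + 1)
  g <- sqrt(gx^2 + gy^2)
  alpha <- if (gx == 0) { if (gy == 0) 0 else sign(gy) * pi / 2 } else atan(gy / gx)
  c(g = g, alpha = alpha)
}

# Edge-preservation metric, per-pixel scalar arithmetic; sigmoids
# peak-normalized so self-fusion scores 1.
oracle_qabf <- function(a, b, f) {
  sig <- function(x, gamma, kappa, sigma) gamma / (1 + exp(kappa * (x - sigma)))
  qg1 <- sig(1, 0.9994, -15, 0.5)
  qa1 <- sig(1, 0.9879, -22, 0.8)
  num <- 0; den <- 0
  for (i in seq_len(nrow(f))) {
    for (j in seq_len(ncol(f))) {
      ef <- oracle_sobel_at(f, i, j)
      for (src in list(a, b)) {
        es <- oracle_sobel_at(src, i, j)
        G <- if (es["g"] > ef["g"]) {
          if (es["g"] > 0) ef["g"] / es["g"] else 0
        } else {
          if (ef["g"] > 0) es["g"] / ef["g"] else 1
        }
        A <- 1 - abs(es["alpha"] - ef["alpha"]) / (pi / 2)
        q <- min(1, sig(G, 0.9994, -15, 0.5) / qg1) *
          min(1, sig(A, 0.9879, -22, 0.8) / qa1)
        num <- num + q * es["g"]
        den <- den + es["g"]
      }
    }
  }
  if (den == 0) 0 else unname(num / den)
}

# Best two-atom least-squares residual norm by exhaustive enumeration.
oracle_best_pair_residual <- function(v, D) {
  k <- ncol(D)
  best <- sqrt(sum(v^2))
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      Ds <- D[, c(i, j)]
      beta <- qr.solve(qr(Ds), v)
      r <- sqrt(sum((v - Ds %*% beta)^2))
      if (r < best) best <- r
    }
  }
  best
}

# Small deterministic random image.
rand_img <- function(h, w = h, seed = 1) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}
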