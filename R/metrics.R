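# Fusion-quality metrics: mutual information MI(AB,F), standard deviation,
# Xydeas-Petrovic QAB/F edge preservation, spatial frequency and mean
# intensity. All operate on [0,1] images; SD, SF and Mean are reported on
# the conventional 0-255 intensity scale.

#' Mutual information between the sources and the fused image
#'
#' `MI(AB,F) = I(A;F) + I(B;F)`, each term estimated from a joint histogram
#' with `bins` equal-width bins on `[0, 1]`, log base 2 with the `0 log 0 = 0`
#' convention.
#'
#' @param a,b Source images; `f` fused image. Equal shapes required.
#' @param bins Histogram bins per axis. Default 256.
#' @return Mutual information in bits (>= 0).
#' @export
mutual_information <- function(a, b, f, bins = 256L) {
  if (!identical(dim(a), dim(f)) || !identical(dim(b), dim(f)))
    stop_validation("mutual_information: image shapes differ")
  if (bins < 2L) stop_validation("mutual_information: bins must be >= 2")
  mi_pair(a, f, bins) + mi_pair(b, f, bins)
}

mi_pair <- function(x, y, bins) {
  bx <- bin_index(x, bins)
  by <- bin_index(y, bins)
  joint <- table(factor(bx, levels = seq_len(bins)),
                 factor(by, levels = seq_len(bins)))
  p <- joint / sum(joint)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  outer_p <- outer(px, py)
  sum(p[nz] * log2(p[nz] / outer_p[nz]))
}

bin_index <- function(x, bins) {
  pmin(floor(as.vector(x) * bins) + 1L, bins)
}

#' Standard deviation of a fused image
#'
#' Population standard deviation of the intensities on the 0-255 scale.
#'
#' @param f Image matrix on `[0, 1]`.
#' @return Non-negative scalar.
#' @export
std_dev <- function(f) {
  v <- as.vector(f) * 255
  sqrt(mean((v - mean(v))^2))
}

#' Mean intensity of a fused image on the 0-255 scale
#' @param f Image matrix on `[0, 1]`.
#' @return Scalar in `[0, 255]`.
#' @export
mean_intensity <- function(f) mean(f) * 255

#' Spatial frequency
#'
#' `SF = sqrt(RF^2 + CF^2)` where RF is the RMS of horizontal first
#' differences (along columns) and CF the RMS of vertical first differences,
#' both on the 0-255 scale. Differences are taken between adjacent pixels
#' only (no wrap), so the normalizer is the count of differences, M*(N-1)
#' and (M-1)*N respectively.
#'
#' @param f Image matrix on `[0, 1]`, at least 2x2.
#' @return Non-negative scalar.
#' @export
spatial_frequency <- function(f) {
  if (nrow(f) < 2L || ncol(f) < 2L)
    stop_validation("spatial_frequency: image must be at least 2x2")
  g <- f * 255
  rf2 <- mean((g[, -1L, drop = FALSE] - g[, -ncol(g), drop = FALSE])^2)
  cf2 <- mean((g[-1L, , drop = FALSE] - g[-nrow(g), , drop = FALSE])^2)
  sqrt(rf2 + cf2)
}

# Sobel edge strength g and orientation alpha (atan of gy/gx, in
# [-pi/2, pi/2]); replicate boundary.
sobel_edges <- function(x) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  gx <- filter_2d(x, kx)
  gy <- filter_2d(x, ky)
  g <- sqrt(gx^2 + gy^2)
  alpha <- atan(ifelse(gx == 0, ifelse(gy == 0, 0, sign(gy) * Inf), gy / gx))
  list(g = g, alpha = alpha)
}

# Sigmoid constants of the edge-preservation model (strength / orientation).
QABF_GAMMA_G <- 0.9994; QABF_KAPPA_G <- -15; QABF_SIGMA_G <- 0.5
QABF_GAMMA_A <- 0.9879; QABF_KAPPA_A <- -22; QABF_SIGMA_A <- 0.8

qabf_sigmoid <- function(x, gamma, kappa, sigma) {
  gamma / (1 + exp(kappa * (x - sigma)))
}

# Per-source edge-preservation factor Q^{XF}. The sigmoids are normalized
# by their value at perfect preservation (relative strength and orientation
# agreement both 1), so transferring an image onto itself scores exactly 1.
qabf_factor <- function(ex, ef) {
  gx <- ex$g; gf <- ef$g
  G <- ifelse(gx > gf, ifelse(gx > 0, gf / gx, 0),
              ifelse(gf > 0, gx / gf, 1))
  A <- 1 - abs(ex$alpha - ef$alpha) / (pi / 2)
  qg <- qabf_sigmoid(G, QABF_GAMMA_G, QABF_KAPPA_G, QABF_SIGMA_G) /
        qabf_sigmoid(1, QABF_GAMMA_G, QABF_KAPPA_G, QABF_SIGMA_G)
  qa <- qabf_sigmoid(A, QABF_GAMMA_A, QABF_KAPPA_A, QABF_SIGMA_A) /
        qabf_sigmoid(1, QABF_GAMMA_A, QABF_KAPPA_A, QABF_SIGMA_A)
  pmin(qg, 1) * pmin(qa, 1)
}

#' QAB/F edge-preservation metric
#'
#' Edge-information transfer from both sources into the fused image: Sobel
#' edge strength and orientation are compared pixelwise between each source
#' and the fused image, mapped through the standard sigmoid preservation
#' model, and averaged with the source edge strengths as weights. The
#' sigmoids are peak-normalized so that fusing an image with itself scores
#' exactly 1. Returns 0 when neither source has any edge content.
#'
#' @param a,b Source images; `f` fused image. Equal shapes required.
#' @return Scalar in `[0, 1]`.
#' @export
q_abf <- function(a, b, f) {
  if (!identical(dim(a), dim(f)) || !identical(dim(b), dim(f)))
    stop_validation("q_abf: image shapes differ")
  ea <- sobel_edges(a); eb <- sobel_edges(b); ef <- sobel_edges(f)
  qaf <- qabf_factor(ea, ef)
  qbf <- qabf_factor(eb, ef)
  wa <- ea$g; wb <- eb$g
  denom <- sum(wa) + sum(wb)
  if (denom == 0) return(0)
  sum(qaf * wa + qbf * wb) / denom
}

#' All fusion metrics at once
#'
#' @param a,b Source images; `f` fused image.
#' @param bins Histogram bins for mutual information. Default 256.
#' @return List with `mi`, `sd`, `q_abf`, `sf`, `mean`.
#' @export
fusion_metrics <- function(a, b, f, bins = 256L) {
  list(mi = mutual_information(a, b, f, bins),
       sd = std_dev(f),
       q_abf = q_abf(a, b, f),
       sf = spatial_frequency(f),
       mean = mean_intensity(f))
}
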