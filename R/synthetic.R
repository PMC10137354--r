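# Synthetic co-registered multimodal phantom pairs.
#
# Image A emulates a high-contrast anatomical modality (CT-like): a bright
# skull-like annulus around a flat low-intensity interior, plus a sharp
# square insert. Image B emulates a soft-tissue modality (MRI-like): a dark
# annulus, a band-limited textured interior, and a disc insert that A does
# not contain. The pair is complementary by construction — each image holds
# structure invisible in the other — so a fusion result can be scored
# against known ground truth masks.

#' Phantom specification
#'
#' @param size Square side in pixels (>= 64). Default 128; use 512 to mirror
#'   typical clinical resolution.
#' @param ring_radius_frac Outer annulus radius as a fraction of `size/2`.
#'   Default 0.85.
#' @param texture_grain Smoothing scale (pixels) of B's interior texture.
#'   Default 3.
#' @param noise_sigma Additive Gaussian noise SD on the `[0, 1]` scale
#'   (< 0.2). Default 0.01.
#' @param seed Integer seed; the pair is a pure function of the spec.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 128L, ring_radius_frac = 0.85,
                         texture_grain = 3, noise_sigma = 0.01, seed = 1L) {
  size <- as.integer(size)
  if (size < 64L) stop_validation("phantom size must be >= 64, got %d", size)
  if (ring_radius_frac <= 0 || ring_radius_frac >= 1)
    stop_validation("ring_radius_frac must be in (0, 1)")
  if (noise_sigma < 0 || noise_sigma >= 0.2)
    stop_validation("noise_sigma must be in [0, 0.2)")
  if (texture_grain <= 0) stop_validation("texture_grain must be > 0")
  structure(list(size = size, ring_radius_frac = ring_radius_frac,
                 texture_grain = texture_grain, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Geometry shared by images and masks: everything derives from the spec
# only, never from the noise draw.
phantom_geometry <- function(spec) {
  n <- spec$size
  ctr <- (n + 1) / 2
  g <- expand.grid(i = seq_len(n), j = seq_len(n))
  r <- sqrt((g$i - ctr)^2 + (g$j - ctr)^2)
  rmat <- matrix(r, n, n)
  r_out <- spec$ring_radius_frac * n / 2
  r_in <- r_out - max(3, round(0.06 * n))
  annulus <- rmat >= r_in & rmat <= r_out
  # square insert (A only), upper-left quadrant; offset + half-side chosen
  # so the whole square sits strictly inside the annulus for any size >= 64
  sq_half <- max(4, round(0.08 * n))
  sq_ci <- round(ctr - 0.15 * n); sq_cj <- round(ctr - 0.15 * n)
  gi <- matrix(g$i, n, n); gj <- matrix(g$j, n, n)
  insert_a <- abs(gi - sq_ci) <= sq_half & abs(gj - sq_cj) <= sq_half
  # disc insert (B only), lower-right quadrant
  d_r <- max(4, round(0.10 * n))
  d_ci <- ctr + 0.20 * n; d_cj <- ctr + 0.20 * n
  insert_b <- (gi - d_ci)^2 + (gj - d_cj)^2 <= d_r^2
  interior <- rmat < r_in & !insert_a & !insert_b
  # inserts never overlap the annulus by construction; keep masks disjoint
  insert_a <- insert_a & rmat < r_in
  insert_b <- insert_b & rmat < r_in & !insert_a
  background <- !(annulus | insert_a | insert_b | interior)
  list(annulus = annulus, insert_a = insert_a, insert_b = insert_b,
       interior = interior, background = background,
       square_half = sq_half, disc_radius = d_r)
}

#' Generate a co-registered phantom pair
#'
#' @param spec A [phantom_spec()].
#' @return A [make_pair()] object with modalities "CT-like" / "MRI-like".
#' @export
generate_pair <- function(spec = phantom_spec()) {
  geo <- phantom_geometry(spec)
  n <- spec$size
  a <- matrix(0.05, n, n)          # background
  a[geo$interior] <- 0.20          # flat soft interior (CT: low contrast)
  a[geo$insert_b] <- 0.20          # B's insert is invisible in A
  a[geo$annulus] <- 0.90           # bright bone-like ring
  a[geo$insert_a] <- 0.80          # sharp geometric insert

  with_seed(spec$seed, {
    # band-limited texture for B's interior: smoothed white noise
    tex <- matrix(stats::rnorm(n * n), n, n)
    klen <- 2L * ceiling(2 * spec$texture_grain) + 1L
    t0 <- seq(-(klen %/% 2), klen %/% 2)
    kern <- exp(-t0^2 / (2 * spec$texture_grain^2))
    kern <- kern / sum(kern)
    tex <- filter_1d(filter_1d(tex, kern, "row"), kern, "col")
    tex <- tex / max(abs(tex))

    b <- matrix(0.05, n, n)
    inter_all <- geo$interior | geo$insert_a | geo$insert_b
    b[inter_all] <- 0.45 + 0.18 * tex[inter_all]
    b[geo$annulus] <- 0.15          # dark ring (bone is dark on MRI)
    b[geo$insert_b] <- 0.85         # insert only B carries

    if (spec$noise_sigma > 0) {
      a <- a + matrix(stats::rnorm(n * n, sd = spec$noise_sigma), n, n)
      b <- b + matrix(stats::rnorm(n * n, sd = spec$noise_sigma), n, n)
    }
  })
  a <- pmin(pmax(a, 0), 1)
  b <- pmin(pmax(b, 0), 1)
  make_pair(a, b, modality_a = "CT-like", modality_b = "MRI-like")
}

#' Ground-truth region masks of the phantom
#'
#' Pixel-accurate logical masks of the generator's structures, independent
#' of the noise level: `annulus`, `insert_a`, `insert_b`, `interior`,
#' `background`. The five masks are disjoint and cover the frame.
#'
#' @param spec A [phantom_spec()].
#' @return Named list of logical matrices.
#' @export
ground_truth_masks <- function(spec = phantom_spec()) {
  geo <- phantom_geometry(spec)
  geo[c("annulus", "insert_a", "insert_b", "interior", "background")]
}
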