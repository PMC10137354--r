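# Non-subsampled shearlet transform (NSST).
#
# Decomposition = non-subsampled Laplacian pyramid (shift-invariant, no
# decimation) followed by directional splitting of each detail plane with
# frequency-domain wedge windows. Everything is realized as FFT-domain
# multiplication with periodic boundary handling, so shift-invariance is
# exact and reconstruction is a telescoping sum:
#
#   x = low + sum_s sum_k band[s][k]
#
# because (i) detail_s = approx_{s-1} - approx_s and (ii) the d angular
# windows form a partition of unity on the frequency plane.

#' NSST configuration
#'
#' @param levels Number of pyramid scales c (>= 1). Default 1, the setting
#'   used for the fusion pipeline.
#' @param directions Directional bands d per scale; one of 2, 4, 8, 16.
#'   Default 8.
#' @param pyramid_filter Lowpass used by the non-subsampled pyramid:
#'   `"maxflat"` (binomial 5-tap, default) or `"9-7"` (CDF 9/7 analysis).
#' @param shear_window Angular window profile: `"meyer"` (polynomial Meyer
#'   transition, default) or `"raised-cosine"`.
#' @return An object of class `nsst_config`.
#' @export
nsst_config <- function(levels = 1L, directions = 8L,
                        pyramid_filter = c("maxflat", "9-7"),
                        shear_window = c("meyer", "raised-cosine")) {
  levels <- as.integer(levels)
  directions <- as.integer(directions)
  pyramid_filter <- match.arg(pyramid_filter)
  shear_window <- match.arg(shear_window)
  if (levels < 1L)
    stop_validation("levels must be >= 1, got %d", levels)
  if (!directions %in% c(2L, 4L, 8L, 16L))
    stop_validation("directions must be one of 2, 4, 8, 16, got %d", directions)
  structure(list(levels = levels, directions = directions,
                 pyramid_filter = pyramid_filter,
                 shear_window = shear_window),
            class = "nsst_config")
}

# 1-D frequency response of the pyramid lowpass on grid omega (radians).
pyramid_lowpass_response <- function(omega, filter = c("maxflat", "9-7")) {
  filter <- match.arg(filter)
  if (filter == "maxflat") {
    # binomial [1 4 6 4 1]/16: H(w) = cos^4(w/2); maximally flat at 0 and pi
    cos(omega / 2)^4
  } else {
    # CDF 9/7 analysis lowpass (JPEG2000), zero-phase cosine series
    h <- c(0.026748757411, -0.016864118443, -0.078223266529,
           0.266864118443, 0.602949018236, 0.266864118443,
           -0.078223266529, -0.016864118443, 0.026748757411)
    # normalize DC gain to exactly 1 so the pyramid preserves constants
    h <- h / sum(h)
    resp <- rep(h[5], length(omega))
    for (t in 1:4) resp <- resp + 2 * h[5 + t] * cos(t * omega)
    resp
  }
}

# 2-D separable lowpass transfer function at pyramid scale s (0-based),
# via the a-trous dilation H(2^s w). Returns an H x W matrix aligned with
# R's fft() frequency ordering.
lowpass_transfer <- function(h, w, scale, filter) {
  wr <- 2 * pi * (seq_len(h) - 1L) / h
  wr <- ifelse(wr > pi, wr - 2 * pi, wr)
  wc <- 2 * pi * (seq_len(w) - 1L) / w
  wc <- ifelse(wc > pi, wc - 2 * pi, wc)
  hr <- pyramid_lowpass_response(2^scale * wr, filter)
  hc <- pyramid_lowpass_response(2^scale * wc, filter)
  outer(hr, hc)
}

# Meyer auxiliary polynomial: smooth 0->1 on [0,1].
meyer_nu <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t^4 * (35 - 84 * t + 70 * t^2 - 20 * t^3)
}

# Angular wedge windows. Frequencies are binned by angle theta mod pi
# (antipodal frequencies share a window, keeping bands real). Window k is
# centered at theta_k = k*pi/d and overlaps its neighbours by 50%; the
# squared-cosine (or Meyer) crossfade makes the windows sum to exactly 1
# at every frequency, which is what guarantees perfect reconstruction.
shear_windows <- function(h, w, directions, profile = c("meyer", "raised-cosine")) {
  profile <- match.arg(profile)
  fr <- (seq_len(h) - 1L) / h
  fr <- ifelse(fr >= 0.5, fr - 1, fr)
  fc <- (seq_len(w) - 1L) / w
  fc <- ifelse(fc >= 0.5, fc - 1, fc)
  # theta in [0, pi); rows index the vertical frequency axis
  theta <- atan2(outer(fr, rep(1, w)), outer(rep(1, h), fc)) %% pi
  u <- theta * directions / pi    # window-centre units, period `directions`
  wins <- vector("list", directions)
  for (k in seq_len(directions) - 1L) {
    s <- abs(u - k)
    s <- pmin(s, directions - s)  # circular distance to centre k
    tr <- if (profile == "meyer") meyer_nu(s) else s
    v <- ifelse(s < 1, cos(pi * tr / 2)^2, 0)
    wins[[k + 1L]] <- v
  }
  wins
}

#' Forward non-subsampled shearlet transform
#'
#' Decomposes an image into one low-frequency approximation plus
#' `levels` groups of `directions` directional detail bands, all at the
#' input resolution. Boundary handling is periodic.
#'
#' @param img Numeric matrix (any real-valued band; the fusion pipeline
#'   passes `[0, 1]` images).
#' @param cfg An [nsst_config()].
#' @return An object of class `nsst_pyramid`: list with `low` (matrix),
#'   `high` (list of `levels` lists of `directions` matrices, scale 1 =
#'   finest), and `config`.
#' @export
nsst_forward <- function(img, cfg = nsst_config()) {
  if (!is.matrix(img) || !is.numeric(img))
    stop_validation("nsst_forward: input must be a numeric matrix")
  h <- nrow(img); w <- ncol(img)
  if (h < 2^cfg$levels || w < 16L || h < 16L)
    stop_validation(
      "nsst_forward: image %dx%d too small for %d level(s) (need >= %dx16)",
      h, w, cfg$levels, max(16L, 2^cfg$levels))
  X <- stats::fft(img)
  wins <- shear_windows(h, w, cfg$directions, cfg$shear_window)
  high <- vector("list", cfg$levels)
  approx_hat <- X
  for (s in seq_len(cfg$levels)) {
    L <- lowpass_transfer(h, w, s - 1L, cfg$pyramid_filter)
    next_hat <- approx_hat * L
    detail_hat <- approx_hat - next_hat
    bands <- lapply(wins, function(wk) Re(stats::fft(detail_hat * wk,
                                                     inverse = TRUE)) / (h * w))
    high[[s]] <- bands
    approx_hat <- next_hat
  }
  low <- Re(stats::fft(approx_hat, inverse = TRUE)) / (h * w)
  structure(list(low = low, high = high, config = cfg),
            class = "nsst_pyramid")
}

validate_pyramid <- function(pyr) {
  if (!inherits(pyr, "nsst_pyramid"))
    stop_validation("expected an nsst_pyramid")
  dm <- dim(pyr$low)
  cfg <- pyr$config
  if (length(pyr$high) != cfg$levels)
    stop_validation("pyramid has %d scale group(s), config says %d",
                    length(pyr$high), cfg$levels)
  for (s in seq_along(pyr$high)) {
    if (length(pyr$high[[s]]) != cfg$directions)
      stop_validation("scale %d has %d band(s), config says %d",
                      s, length(pyr$high[[s]]), cfg$directions)
    for (k in seq_along(pyr$high[[s]])) {
      if (!identical(dim(pyr$high[[s]][[k]]), dm))
        stop_validation("band (scale %d, dir %d) shape differs from low band",
                        s, k)
    }
  }
  invisible(pyr)
}

#' Inverse non-subsampled shearlet transform
#'
#' Reconstructs the image as the sum of the low band and every directional
#' band. With bands produced by [nsst_forward()] this is exact to floating
#' point (the angular windows are a partition of unity and the pyramid is
#' telescoping). No clipping is applied here; the fusion pipeline clips to
#' `[0, 1]` at its own boundary.
#'
#' @param pyr An `nsst_pyramid`.
#' @return Numeric matrix of the input shape.
#' @export
nsst_inverse <- function(pyr) {
  validate_pyramid(pyr)
  out <- pyr$low
  for (grp in pyr$high) for (band in grp) out <- out + band
  out
}

#' @export
print.nsst_pyramid <- function(x, ...) {
  cat(sprintf("nsst_pyramid: %d x %d, %d level(s) x %d direction(s) [%s/%s]\n",
              nrow(x$low), ncol(x$low), x$config$levels, x$config$directions,
              x$config$pyramid_filter, x$config$shear_window))
  invisible(x)
}

#' Dump pyramid bands to TIFF files for inspection
#'
#' Writes `lowband.tif` plus `s{scale}_d{dir}.tif` for every directional
#' band into `dir`. Band values are written as 32-bit float TIFF so signed
#' detail coefficients survive the round trip.
#'
#' @param pyr An `nsst_pyramid`.
#' @param dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
nsst_dump_bands <- function(pyr, dir) {
  validate_pyramid(pyr)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "lowband.tif")
  tiff::writeTIFF(pyr$low, p, bits.per.sample = 32L, reduce = FALSE)
  paths <- c(paths, p)
  for (s in seq_along(pyr$high)) {
    for (k in seq_along(pyr$high[[s]])) {
      p <- file.path(dir, sprintf("s%d_d%d.tif", s, k - 1L))
      tiff::writeTIFF(pyr$high[[s]][[k]], p, bits.per.sample = 32L,
                      reduce = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
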