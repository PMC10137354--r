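# Directive-contrast fusion of the directional high-frequency bands.
#
# Each source image gets one directive-contrast map: the pixel-resolution
# MSML activity of its low band divided by the low-band coefficient
# magnitude where that magnitude is meaningfully nonzero, the raw activity
# otherwise. Per pixel, the source with the larger contrast contributes its
# coefficient in every directional band (ties go to B), so fused
# coefficients are always selected, never blended.

#' Directive contrast of a source image
#'
#' `DL(i,j) = MSML(i,j) / |L(i,j)|` where `|L(i,j)| > eps`, else
#' `DL(i,j) = MSML(i,j)`. The epsilon guard keeps the published
#' "denominator > 0" test stable under floating-point noise.
#'
#' @param msml_map Pixel-resolution MSML activity of the low band
#'   (see [msml_map()]).
#' @param low_band The source's low-frequency band.
#' @param eps Magnitude below which the denominator is treated as zero.
#'   Default 1e-8.
#' @return Non-negative, finite matrix of the band's shape.
#' @export
directive_contrast <- function(msml_map, low_band, eps = 1e-8) {
  if (!identical(dim(msml_map), dim(low_band)))
    stop_validation("directive_contrast: shapes differ (%dx%d vs %dx%d)",
                    nrow(msml_map), ncol(msml_map),
                    nrow(low_band), ncol(low_band))
  if (eps <= 0) stop_validation("directive_contrast: eps must be > 0")
  denom_ok <- abs(low_band) > eps
  out <- msml_map
  out[denom_ok] <- msml_map[denom_ok] / abs(low_band[denom_ok])
  out
}

#' Fuse directional high-frequency bands
#'
#' Per pixel and per band: take A's coefficient where `DLA > DLB`, B's
#' otherwise (ties included). One decision map is shared across all bands
#' of all scales.
#'
#' @param bands_a,bands_b Band lists as in `nsst_pyramid$high` (list of
#'   scales, each a list of direction matrices), or a flat list of matrices.
#' @param dl_a,dl_b Directive-contrast maps for A and B.
#' @return List with `bands` (same nesting as the inputs) and `from_a`
#'   (logical decision matrix).
#' @export
fuse_high_bands <- function(bands_a, bands_b, dl_a, dl_b) {
  nested <- is.list(bands_a[[1L]])
  flat_a <- if (nested) unlist(bands_a, recursive = FALSE) else bands_a
  flat_b <- if (nested) unlist(bands_b, recursive = FALSE) else bands_b
  if (length(flat_a) != length(flat_b))
    stop_validation("fuse_high_bands: band counts differ (%d vs %d)",
                    length(flat_a), length(flat_b))
  from_a <- dl_a > dl_b
  fused_flat <- vector("list", length(flat_a))
  for (i in seq_along(flat_a)) {
    if (!identical(dim(flat_a[[i]]), dim(flat_b[[i]])))
      stop_validation("fuse_high_bands: band %d shapes differ", i)
    f <- flat_b[[i]]
    f[from_a] <- flat_a[[i]][from_a]
    fused_flat[[i]] <- f
  }
  bands <- if (nested) {
    sizes <- vapply(bands_a, length, 1L)
    split(fused_flat, rep(seq_along(sizes), sizes))
  } else {
    fused_flat
  }
  if (nested) bands <- unname(lapply(bands, unname))
  list(bands = bands, from_a = from_a)
}
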