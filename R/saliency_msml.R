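# Activity measures on the low-frequency band: gradients, maximum symmetric
# surround (MSS) saliency, modified Laplacian (ML) and the patchwise modified
# sum-modified-Laplacian (MSML).

#' Horizontal and vertical gradients
#'
#' Centered first differences `[-1, 0, 1]/2`: `grad_h` responds to variation
#' along columns (horizontal direction), `grad_v` along rows. Replicate
#' (symmetric) boundary.
#'
#' @param band Numeric matrix, at least 3x3.
#' @return List with `grad_h`, `grad_v` (matrices of `band`'s shape).
#' @export
gradients <- function(band) {
  if (nrow(band) < 3L || ncol(band) < 3L)
    stop_validation("gradients: band must be at least 3x3")
  k <- c(-1, 0, 1) / 2
  list(grad_h = filter_1d(band, k, along = "col"),
       grad_v = filter_1d(band, k, along = "row"))
}

#' Maximum symmetric surround saliency
#'
#' For each pixel, take the largest window centred on it that is symmetric
#' and still fits in the image (half-heights `m = min(i-1, H-i)`, half-widths
#' `n = min(j-1, W-j)` in 1-based indexing), and compare the smoothed pixel
#' value against the window mean. Saliency is the squared difference, so
#' pixels that stand out from their maximal surround score high while the
#' window shrinks gracefully near borders. The smoothed value uses a 3x3
#' binomial filter; for a single grayscale channel the multi-channel norm of
#' the original formulation reduces to this scalar difference.
#'
#' @param band Numeric matrix, at least 3x3.
#' @return List with `values` (non-negative matrix) and `window_desc`.
#' @export
mss_saliency <- function(band) {
  h <- nrow(band); w <- ncol(band)
  if (h < 3L || w < 3L)
    stop_validation("mss_saliency: band must be at least 3x3")
  smooth <- filter_1d(filter_1d(band, c(1, 2, 1) / 4, "row"),
                      c(1, 2, 1) / 4, "col")
  S <- integral_image(band)
  i <- rep(seq_len(h), times = w)
  j <- rep(seq_len(w), each = h)
  m <- pmin(i - 1L, h - i)
  n <- pmin(j - 1L, w - j)
  tot <- window_sum_from_integral(S, i - m, i + m, j - n, j + n)
  mu <- tot / ((2 * m + 1) * (2 * n + 1))
  vals <- matrix((as.vector(smooth) - mu)^2, h, w)
  list(values = vals,
       window_desc = "largest centred symmetric window; mean normalized by window area")
}

#' Modified Laplacian
#'
#' Directional second-difference activity: the band is convolved with
#' `[-1, 2, -1]` along columns and along rows and the absolute responses are
#' summed (`ml_mode = "convolution"`, the sum-modified-Laplacian reading).
#' `ml_mode = "pointwise"` instead forms `|P * grad_h| + |P * grad_v|` as a
#' literal pointwise product with the first-derivative maps.
#'
#' @param band Numeric matrix.
#' @param grads Optional precomputed [gradients()] output (required for
#'   `ml_mode = "pointwise"`, computed on demand otherwise).
#' @param ml_mode `"convolution"` (default) or `"pointwise"`.
#' @return List with `values`, a non-negative matrix of `band`'s shape.
#' @export
modified_laplacian <- function(band, grads = NULL,
                               ml_mode = c("convolution", "pointwise")) {
  ml_mode <- match.arg(ml_mode)
  if (ml_mode == "convolution") {
    k <- c(-1, 2, -1)
    vals <- abs(filter_1d(band, k, "col")) + abs(filter_1d(band, k, "row"))
  } else {
    if (is.null(grads)) grads <- gradients(band)
    if (!identical(dim(grads$grad_h), dim(band)))
      stop_validation("modified_laplacian: gradient shape differs from band")
    vals <- abs(band * grads$grad_h) + abs(band * grads$grad_v)
  }
  list(values = vals)
}

#' Patchwise MSML activity
#'
#' Sums the modified-Laplacian map over every n x n patch of a tiling with
#' the given stride (patches enumerated row-major by top-left corner). This
#' is the per-patch activity that drives clustering and the low-band fusion
#' rule.
#'
#' @param ml A [modified_laplacian()] result (or any list with `values`).
#' @param patch_size Patch side n.
#' @param stride Step between patch origins; the last patch along each axis
#'   is pinned to the border so the tiling always covers the band.
#' @param source Label recorded on each row (`"A"` or `"B"`).
#' @return data.frame with columns `patch_index`, `source`, `row`, `col`
#'   (1-based top-left) and `msml`.
#' @export
msml_per_patch <- function(ml, patch_size, stride, source = "A") {
  vals <- ml$values
  h <- nrow(vals); w <- ncol(vals)
  if (patch_size > h || patch_size > w)
    stop_validation("patch_size %d exceeds band dimensions %dx%d",
                    patch_size, h, w)
  origins_r <- patch_origins(h, patch_size, stride)
  origins_c <- patch_origins(w, patch_size, stride)
  S <- integral_image(vals)
  r <- rep(origins_r, times = length(origins_c))
  cc <- rep(origins_c, each = length(origins_r))
  # row-major enumeration: all patches of row-origin 1 first
  ord <- order(r, cc)
  r <- r[ord]; cc <- cc[ord]
  s <- window_sum_from_integral(S, r, r + patch_size - 1L,
                                cc, cc + patch_size - 1L)
  data.frame(patch_index = seq_along(r), source = source,
             row = r, col = cc, msml = s, stringsAsFactors = FALSE)
}

# Patch origins covering [1, len] with the given stride; the final origin is
# clamped so the last patch ends exactly at the border.
patch_origins <- function(len, patch_size, stride) {
  if (patch_size > len)
    stop_validation("patch_size %d exceeds dimension %d", patch_size, len)
  o <- seq.int(1L, len - patch_size + 1L, by = stride)
  last <- len - patch_size + 1L
  if (o[length(o)] != last) o <- c(o, last)
  as.integer(o)
}

#' Pixel-resolution MSML map
#'
#' Evaluates the patch activity on a sliding n x n window centred at every
#' pixel (window rows `i - floor((n-1)/2) .. i + ceil((n-1)/2)`), with
#' replicate padding at the borders. Used by the directive-contrast rule,
#' which needs MSML at coefficient resolution.
#'
#' @param ml A [modified_laplacian()] result.
#' @param window Window side n (defaults to the patch size 8).
#' @return Non-negative matrix of the band's shape.
#' @export
msml_map <- function(ml, window = 8L) {
  vals <- ml$values
  h <- nrow(vals); w <- ncol(vals)
  lo <- (window - 1L) %/% 2L
  hi <- window - 1L - lo
  padded <- pad_replicate(vals, top = lo, bottom = hi, left = lo, right = hi)
  S <- integral_image(padded)
  i <- rep(seq_len(h), times = w)
  j <- rep(seq_len(w), each = h)
  s <- window_sum_from_integral(S, i, i + window - 1L, j, j + window - 1L)
  matrix(s, h, w)
}
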