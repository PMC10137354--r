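# Image input/output and pair validation.
#
# Images are plain numeric matrices with intensities on [0, 1]; [1,1] is the
# top-left pixel. All internal computation is scale-free on [0, 1]; files are
# quantized to 8 or 16 bits only at the I/O boundary.

MIN_IMAGE_DIM <- 16L

#' Validate a grayscale image matrix
#'
#' Checks the in-memory image contract used throughout the package: a numeric
#' matrix, all values finite and in `[0, 1]`, at least 16 pixels along each
#' axis (the minimum for one shearlet level plus 8x8 patches).
#'
#' @param img Numeric matrix.
#' @param what Label used in error messages.
#' @return `img`, invisibly, if valid; otherwise an error.
#' @export
validate_gray_image <- function(img, what = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop_validation("%s must be a numeric matrix", what)
  if (nrow(img) < MIN_IMAGE_DIM || ncol(img) < MIN_IMAGE_DIM)
    stop_validation("%s must be at least %dx%d pixels, got %dx%d",
                    what, MIN_IMAGE_DIM, MIN_IMAGE_DIM, nrow(img), ncol(img))
  if (any(!is.finite(img)))
    stop_validation("%s contains non-finite values", what)
  if (min(img) < 0 || max(img) > 1)
    stop_validation("%s has values outside [0, 1] (range %.4g..%.4g)",
                    what, min(img), max(img))
  invisible(img)
}

# ITU-R BT.601 luminance weights for RGB inputs.
rgb_to_gray <- function(arr) {
  0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
}

#' Read a grayscale image from PNG or TIFF
#'
#' Reads an 8- or 16-bit single-channel or RGB PNG/TIFF file and returns a
#' numeric matrix of intensities on `[0, 1]`. RGB inputs are converted to
#' luminance with ITU-R BT.601 weights; an alpha channel, if present, is
#' dropped. Values are rescaled by the dtype maximum (255 or 65535), so a
#' saturated 8-bit pixel maps exactly to 1.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param bit_depth_policy `"auto"` trusts the file's declared depth;
#'   `"force8"`/`"force16"` re-quantize the decoded values to that depth
#'   before normalization (useful when a writer padded 8-bit data into a
#'   16-bit container).
#' @return Numeric matrix on `[0, 1]`.
#' @export
read_image <- function(path, bit_depth_policy = c("auto", "force8", "force16")) {
  bit_depth_policy <- match.arg(bit_depth_policy)
  if (!file.exists(path))
    stop_validation("cannot read image: no such file '%s'", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      frames <- tiff::readTIFF(path, all = TRUE)
      if (length(frames) > 1L)
        stop_validation("multi-frame TIFF not supported: '%s' has %d frames",
                        path, length(frames))
      frames[[1L]]
    },
    stop_validation("unsupported image format '.%s' for '%s' (PNG/TIFF only)",
                    ext, path)
  )
  # readPNG/readTIFF already return doubles on [0,1], scaled by dtype max.
  img <- if (length(dim(arr)) == 3L) {
    if (dim(arr)[3L] >= 3L) rgb_to_gray(arr) else arr[, , 1L]
  } else {
    arr
  }
  if (bit_depth_policy == "force8") img <- round(img * 255) / 255
  if (bit_depth_policy == "force16") img <- round(img * 65535) / 65535
  img <- pmin(pmax(img, 0), 1)
  validate_gray_image(img, sprintf("image '%s'", path))
  img
}

#' Pair two co-registered images
#'
#' Bundles two grayscale images for fusion after checking that their shapes
#' match exactly. No resampling or registration is attempted: the fusion
#' model assumes co-registered inputs of identical resolution, and silently
#' resizing a medical image would invalidate that assumption.
#'
#' @param a,b Numeric matrices on `[0, 1]`.
#' @param modality_a,modality_b Free-text modality labels (e.g. "CT", "MRI").
#' @return An object of class `source_pair` with elements `a`, `b`,
#'   `modality_a`, `modality_b`.
#' @export
make_pair <- function(a, b, modality_a = "A", modality_b = "B") {
  validate_gray_image(a, "image A")
  validate_gray_image(b, "image B")
  if (!identical(dim(a), dim(b)))
    stop_validation("image shapes differ: A is %dx%d, B is %dx%d",
                    nrow(a), ncol(a), nrow(b), ncol(b))
  structure(list(a = a, b = b,
                 modality_a = modality_a, modality_b = modality_b),
            class = "source_pair")
}

#' @export
print.source_pair <- function(x, ...) {
  cat(sprintf("source_pair: %s / %s, %d x %d\n",
              x$modality_a, x$modality_b, nrow(x$a), ncol(x$a)))
  invisible(x)
}

#' Write a grayscale image to PNG or TIFF
#'
#' Quantizes the `[0, 1]` image to the requested bit depth and writes it.
#' A round-trip through [read_image()] recovers every pixel within one
#' quantization step (1/255 or 1/65535). PNG output is 8-bit; request a
#' TIFF path for 16-bit.
#'
#' @param img Numeric matrix on `[0, 1]`.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @param bit_depth 8 (default) or 16.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bit_depth = 8L) {
  validate_gray_image(img)
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L))
    stop_validation("bit_depth must be 8 or 16, got %s", bit_depth)
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop_validation("cannot write image: no such directory '%s'", dir)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bit_depth != 8L)
      stop_validation("PNG output is 8-bit; use a .tif path for 16-bit")
    # quantize explicitly so the file is a pure function of the matrix
    png::writePNG(round(img * 255) / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(round(img * (2^bit_depth - 1)) / (2^bit_depth - 1),
                    path, bits.per.sample = bit_depth)
  } else {
    stop_validation("unsupported output format '.%s' (PNG/TIFF only)", ext)
  }
  invisible(path)
}
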