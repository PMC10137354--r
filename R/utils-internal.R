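# Internal array helpers shared across modules. All image matrices are
# numeric, indexed [row, col], intensities on [0, 1].

# Pad a matrix by replicating edge rows/cols (symmetric/replicate boundary).
pad_replicate <- function(x, top, bottom = top, left = top, right = left) {
  h <- nrow(x); w <- ncol(x)
  ri <- c(rep(1L, top), seq_len(h), rep(h, bottom))
  ci <- c(rep(1L, left), seq_len(w), rep(w, right))
  x[ri, ci, drop = FALSE]
}

# Correlate with a 1-D kernel along rows (i direction, "vertical") or
# columns (j direction, "horizontal"), replicate boundary. Kernel must be
# odd-length and centered.
filter_1d <- function(x, kernel, along = c("col", "row")) {
  along <- match.arg(along)
  k <- length(kernel)
  stopifnot(k %% 2L == 1L)
  r <- (k - 1L) %/% 2L
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  if (along == "col") {
    xp <- pad_replicate(x, top = 0L, bottom = 0L, left = r, right = r)
    for (t in seq_len(k)) {
      out <- out + kernel[t] * xp[, t:(t + w - 1L), drop = FALSE]
    }
  } else {
    xp <- pad_replicate(x, top = r, bottom = r, left = 0L, right = 0L)
    for (t in seq_len(k)) {
      out <- out + kernel[t] * xp[t:(t + h - 1L), , drop = FALSE]
    }
  }
  out
}

# Correlate with a small 2-D kernel (odd dims), replicate boundary.
filter_2d <- function(x, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  stopifnot(kh %% 2L == 1L, kw %% 2L == 1L)
  rr <- (kh - 1L) %/% 2L; rc <- (kw - 1L) %/% 2L
  h <- nrow(x); w <- ncol(x)
  xp <- pad_replicate(x, top = rr, bottom = rr, left = rc, right = rc)
  out <- matrix(0, h, w)
  for (a in seq_len(kh)) {
    for (b in seq_len(kw)) {
      if (kernel[a, b] != 0) {
        out <- out + kernel[a, b] *
          xp[a:(a + h - 1L), b:(b + w - 1L), drop = FALSE]
      }
    }
  }
  out
}

# Summed-area table with a leading row/col of zeros, so that
# sum over rows r1..r2, cols c1..c2 is S[r2+1,c2+1]-S[r1,c2+1]-S[r2+1,c1]+S[r1,c1].
integral_image <- function(x) {
  s <- apply(x, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  rbind(0, cbind(0, s))
}

window_sum_from_integral <- function(S, r1, r2, c1, c2) {
  S[cbind(r2 + 1L, c2 + 1L)] - S[cbind(r1, c2 + 1L)] -
    S[cbind(r2 + 1L, c1)] + S[cbind(r1, c1)]
}

# RMS difference between two matrices.
rms <- function(a, b = 0) sqrt(mean((a - b)^2))

# Peak signal-to-noise ratio for intensities on [0, 1].
#' Peak signal-to-noise ratio
#'
#' PSNR in decibels between two images on the `[0, 1]` intensity scale
#' (peak value 1). Identical images give `Inf`.
#'
#' @param x,ref Numeric matrices of equal shape.
#' @return PSNR in dB.
#' @export
psnr <- function(x, ref) {
  stopifnot(identical(dim(x), dim(ref)))
  mse <- mean((x - ref)^2)
  if (mse == 0) return(Inf)
  -10 * log10(mse)
}

# Evaluate randomized code with a seed without disturbing the caller's RNG
# stream; restores .Random.seed (or its absence) on exit.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
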