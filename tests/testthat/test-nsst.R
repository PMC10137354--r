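# Non-subsampled shearlet transform: structure, perfect reconstruction,
# shift-invariance, linearity, partition of unity.

test_that("constant images decompose into a constant low band and silent high bands", {
  p <- nsst_forward(matrix(0.5, 32, 32), nsst_config(levels = 1, directions = 8))
  expect_lt(max(abs(p$low - 0.5)), 1e-9)
  for (band in p$high[[1]]) expect_lt(max(abs(band)), 1e-9)
})

test_that("pyramid structure matches the configuration and input shape", {
  x <- rand_img(32, 48, seed = 3)
  for (cfg in list(nsst_config(1, 8), nsst_config(2, 4),
                   nsst_config(1, 16, pyramid_filter = "9-7",
                               shear_window = "raised-cosine"))) {
    p <- nsst_forward(x, cfg)
    expect_identical(dim(p$low), dim(x))
    expect_length(p$high, cfg$levels)
    for (grp in p$high) {
      expect_length(grp, cfg$directions)
      for (band in grp) expect_identical(dim(band), dim(x))
    }
  }
})

test_that("directional bands at each scale sum back to the detail plane", {
  x <- rand_img(40, 40, seed = 11)
  cfg <- nsst_config(levels = 1, directions = 8)
  p <- nsst_forward(x, cfg)
  detail <- x - p$low
  expect_lt(rms(Reduce(`+`, p$high[[1]]), detail), 1e-8)
})

test_that("bands match a direct frequency-domain filter-bank evaluation on an impulse", {
  # independent oracle: build each band's overall transfer function from
  # first principles (separable cos^4 lowpass, squared-cosine angular
  # crossfade with Meyer transition) and apply it to the impulse spectrum
  h <- 32L; w <- 32L
  x <- matrix(0, h, w); x[17, 17] <- 1
  cfg <- nsst_config(levels = 1, directions = 8)
  p <- nsst_forward(x, cfg)
  wr <- 2 * pi * (0:(h - 1)) / h; wr <- ifelse(wr > pi, wr - 2 * pi, wr)
  wc <- 2 * pi * (0:(w - 1)) / w; wc <- ifelse(wc > pi, wc - 2 * pi, wc)
  L <- outer(cos(wr / 2)^4, cos(wc / 2)^4)
  fr <- wr / (2 * pi); fc <- wc / (2 * pi)
  theta <- atan2(outer(fr, rep(1, w)), outer(rep(1, h), fc)) %% pi
  nu <- function(t) { t <- pmin(pmax(t, 0), 1); t^4 * (35 - 84 * t + 70 * t^2 - 20 * t^3) }
  X <- stats::fft(x)
  total_energy_bands <- 0
  for (k in 0:7) {
    s <- abs(theta * 8 / pi - k)
    s <- pmin(s, 8 - s)
    wk <- ifelse(s < 1, cos(pi * nu(s) / 2)^2, 0)
    ref <- Re(stats::fft(X * (1 - L) * wk, inverse = TRUE)) / (h * w)
    expect_lt(rms(p$high[[1]][[k + 1]], ref), 1e-10)
    total_energy_bands <- total_energy_bands + sum(ref^2)
  }
  got_energy <- sum(sapply(p$high[[1]], function(b) sum(b^2)))
  expect_equal(got_energy, total_energy_bands, tolerance = 1e-10)
})

test_that("forward-inverse round trip is exact for random and structured inputs", {
  imgs <- list(rand_img(64, 64, seed = 1),
               rand_img(96, 64, seed = 2),
               generate_pair(phantom_spec(size = 64, seed = 5))$a)
  for (x in imgs) {
    for (cfg in list(nsst_config(1, 8), nsst_config(2, 8),
                     nsst_config(1, 4, pyramid_filter = "9-7"))) {
      expect_lt(rms(nsst_inverse(nsst_forward(x, cfg)), x), 1e-6)
    }
  }
})

test_that("transform is linear and exactly shift-invariant under periodic shifts", {
  x <- rand_img(48, 48, seed = 21)
  y <- rand_img(48, 48, seed = 22)
  cfg <- nsst_config(1, 8)
  pxy <- nsst_forward(x + y, cfg)
  pa <- nsst_forward(x, cfg); pb <- nsst_forward(y, cfg)
  expect_lt(rms(pxy$low, pa$low + pb$low), 1e-12)
  expect_lt(rms(pxy$high[[1]][[2]], pa$high[[1]][[2]] + pb$high[[1]][[2]]), 1e-12)
  # inverse linearity: inverse(pyrA + pyrB) = inverse(pyrA) + inverse(pyrB)
  padd <- pa
  padd$low <- pa$low + pb$low
  padd$high[[1]] <- Map(`+`, pa$high[[1]], pb$high[[1]])
  expect_lt(rms(nsst_inverse(padd),
                nsst_inverse(pa) + nsst_inverse(pb)), 1e-8)
  # circular shift commutes with the transform
  sh <- function(m) m[c(8:48, 1:7), c(30:48, 1:29)]
  ps <- nsst_forward(sh(x), cfg)
  expect_lt(max(abs(ps$low - sh(pa$low))), 1e-12)
  expect_lt(max(abs(ps$high[[1]][[5]] - sh(pa$high[[1]][[5]]))), 1e-12)
})

test_that("all-zero pyramid inverts to the zero image and bad shapes are rejected", {
  p <- nsst_forward(rand_img(32, 32), nsst_config(1, 4))
  p$low[] <- 0
  for (k in seq_along(p$high[[1]])) p$high[[1]][[k]][] <- 0
  expect_equal(nsst_inverse(p), matrix(0, 32, 32))
  p$high[[1]][[2]] <- matrix(0, 16, 16)
  expect_error(nsst_inverse(p), "shape")
  expect_error(nsst_forward(matrix(0.5, 8, 32), nsst_config(1, 8)), "too small")
  expect_error(nsst_config(directions = 3), "directions")
  expect_error(nsst_config(levels = 0), "levels")
})
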