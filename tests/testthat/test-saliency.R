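# Gradients, MSS saliency, modified Laplacian, patchwise MSML.

test_that("gradients: constants, ramps and transpose symmetry", {
  expect_equal(gradients(matrix(0.3, 10, 10))$grad_h, matrix(0, 10, 10))
  expect_equal(gradients(matrix(0.3, 10, 10))$grad_v, matrix(0, 10, 10))
  ramp <- outer(rep(1, 10), 1:12)   # x(i,j) = j
  g <- gradients(ramp)
  expect_equal(g$grad_h[3:8, 2:11], matrix(1, 6, 10))
  expect_equal(g$grad_v, matrix(0, 10, 12))
  x <- rand_img(12, 9, seed = 2)
  expect_equal(gradients(t(x))$grad_h, t(gradients(x)$grad_v))
})

test_that("MSS saliency is zero on constants and peaks at a lone bright pixel", {
  s <- mss_saliency(matrix(0.7, 16, 16))
  expect_equal(s$values, matrix(0, 16, 16))
  z <- matrix(0, 33, 33); z[17, 17] <- 1
  s <- mss_saliency(z)
  centre <- 16L * 33L + 17L  # column-major index of (17, 17)
  expect_gt(s$values[17, 17], 0)
  expect_identical(which.max(s$values), centre)
  expect_gt(s$values[17, 17], max(s$values[-centre]))
})

test_that("MSS saliency matches the brute-force windowed-mean oracle", {
  for (seed in 1:3) {
    x <- rand_img(16, 16, seed = seed)
    expect_equal(mss_saliency(x)$values, oracle_mss(x), tolerance = 1e-12)
  }
  x <- rand_img(13, 19, seed = 9)  # non-square
  expect_equal(mss_saliency(x)$values, oracle_mss(x), tolerance = 1e-12)
})

test_that("modified Laplacian: constants, quadratic ramp, rotation symmetry, affine kill", {
  expect_equal(modified_laplacian(matrix(0.4, 12, 12))$values,
               matrix(0, 12, 12))
  q <- outer(rep(1, 12), (1:14)^2)   # x(i,j) = j^2
  ml <- modified_laplacian(q)$values
  expect_equal(ml[3:10, 2:13], matrix(2, 8, 12))
  z <- matrix(0, 15, 15); z[8, 8] <- 1
  ml <- modified_laplacian(z)$values
  rot <- ml[15:1, ][, 15:1]
  expect_equal(ml, t(ml))            # kernel pair is transpose-symmetric
  expect_equal(ml, rot)              # and symmetric under 180-degree rotation
  aff <- outer(1:20, 1:20, function(i, j) 0.1 + 0.3 * i + 0.7 * j)
  expect_equal(modified_laplacian(aff)$values[2:19, 2:19],
               matrix(0, 18, 18), tolerance = 1e-12)
})

test_that("pointwise ML mode multiplies the band with its gradients", {
  x <- rand_img(10, 10, seed = 4)
  g <- gradients(x)
  got <- modified_laplacian(x, grads = g, ml_mode = "pointwise")$values
  expect_equal(got, abs(x * g$grad_h) + abs(x * g$grad_v))
})

test_that("patchwise MSML sums match counting and the loop oracle", {
  ones <- list(values = matrix(1, 16, 16))
  acts <- msml_per_patch(ones, patch_size = 8, stride = 8)
  expect_equal(nrow(acts), 4L)
  expect_equal(acts$msml, rep(64, 4))
  zeros <- list(values = matrix(0, 16, 16))
  expect_equal(msml_per_patch(zeros, 8, 4)$msml, rep(0, 9))
  ml <- list(values = rand_img(16, 16, seed = 6))
  acts <- msml_per_patch(ml, 8, 4)
  expect_equal(nrow(acts), 9L)
  for (k in seq_len(nrow(acts))) {
    expect_equal(acts$msml[k],
                 oracle_patch_sum(ml$values, acts$row[k], acts$col[k], 8),
                 tolerance = 1e-12)
  }
  expect_error(msml_per_patch(ml, 32, 4), "exceeds")
})

test_that("MSML is monotone in the ML map and never negative", {
  ml <- list(values = rand_img(16, 16, seed = 8))
  base <- msml_per_patch(ml, 8, 4)
  expect_true(all(base$msml >= 0))
  bumped <- ml
  bumped$values[5, 5] <- bumped$values[5, 5] + 1
  expect_true(all(msml_per_patch(bumped, 8, 4)$msml >= base$msml))
})

test_that("pixel-resolution MSML map equals padded window sums", {
  ml <- list(values = rand_img(12, 12, seed = 10))
  m <- msml_map(ml, window = 4)
  # brute force with replicate padding, window rows i-1..i+2 for n=4
  ref <- matrix(0, 12, 12)
  for (i in 1:12) {
    for (j in 1:12) {
      s <- 0
      for (a in (i - 1):(i + 2)) for (b in (j - 1):(j + 2))
        s <- s + px(ml$values, a, b)
      ref[i, j] <- s
    }
  }
  expect_equal(m, ref, tolerance = 1e-12)
  expect_true(all(m >= 0))
})
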