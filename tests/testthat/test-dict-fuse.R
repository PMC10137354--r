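# Dictionary training, sparse coding, code fusion, low-band reconstruction.

make_fake_dict <- function(D) {
  structure(list(merged = D, sub = list(edge = D),
                 atom_cluster = rep("edge", ncol(D)), patch_size = NA),
            class = "clustered_dictionary")
}

fake_patches <- function(vectors, patch_size = 4L) {
  list(vectors = vectors, means = rep(0, ncol(vectors)),
       patch_size = patch_size)
}

test_that("a rank-one cluster trains to its own direction and codes losslessly", {
  set.seed(1)
  v <- rnorm(16); v <- v - mean(v)
  X <- matrix(rep(v, 10), 16, 10)
  patches <- fake_patches(X)
  partition <- list(edge = 1:10, texture = integer(0), smooth = integer(0),
                    total = 10L)
  dict <- train_subdictionaries(patches, partition, atoms_per_cluster = 4,
                                iterations = 5, seed = 42)
  sims <- abs(crossprod(dict$merged, v / sqrt(sum(v^2))))
  expect_gt(max(sims), 1 - 1e-6)
  code <- sparse_code(v, dict, sparsity_t = 1)
  expect_lte(code$residual_norm, 1e-6)
  expect_lte(sum(code$coeffs != 0), 1L)
})

test_that("empty clusters are omitted and an all-empty partition errors", {
  set.seed(2)
  X <- matrix(rnorm(16 * 12), 16, 12)
  X <- sweep(X, 2, colMeans(X))
  patches <- fake_patches(X)
  partition <- list(edge = integer(0), texture = 1:6, smooth = 7:12,
                    total = 12L)
  dict <- train_subdictionaries(patches, partition, atoms_per_cluster = 3,
                                iterations = 3, seed = 1)
  expect_named(dict$sub, c("texture", "smooth"))
  expect_equal(ncol(dict$merged), 6L)
  expect_false("edge" %in% dict$atom_cluster)
  empty <- list(edge = integer(0), texture = integer(0), smooth = integer(0),
                total = 0L)
  expect_error(train_subdictionaries(patches, empty), "empty")
})

test_that("training is deterministic given the seed and atoms stay unit-norm", {
  set.seed(3)
  X <- matrix(rnorm(16 * 30), 16, 30)
  X <- sweep(X, 2, colMeans(X))
  patches <- fake_patches(X)
  partition <- list(edge = 1:10, texture = 11:20, smooth = 21:30, total = 30L)
  d1 <- train_subdictionaries(patches, partition, atoms_per_cluster = 5,
                              iterations = 4, seed = 7)
  d2 <- train_subdictionaries(patches, partition, atoms_per_cluster = 5,
                              iterations = 4, seed = 7)
  expect_identical(d1$merged, d2$merged)
  norms <- sqrt(colSums(d1$merged^2))
  expect_equal(norms, rep(1, ncol(d1$merged)), tolerance = 1e-9)
})

test_that("sparse coding recovers exact atom multiples and the zero vector", {
  set.seed(4)
  D <- qr.Q(qr(matrix(rnorm(16 * 6), 16, 6)))
  dict <- make_fake_dict(D)
  z <- sparse_code(rep(0, 16), dict, sparsity_t = 3)
  expect_equal(z$coeffs, rep(0, 6))
  expect_equal(z$residual_norm, 0)
  c2 <- sparse_code(0.7 * D[, 3], dict, sparsity_t = 2)
  expect_equal(c2$coeffs[3], 0.7, tolerance = 1e-9)
  expect_lte(c2$residual_norm, 1e-9)
  expect_equal(sum(c2$coeffs != 0), 1L)
  expect_error(sparse_code(rep(0, 16), make_fake_dict(matrix(0, 16, 0))),
               "no atoms")
})

test_that("pursuit residual matches exhaustive two-atom search on tiny dictionaries", {
  for (seed in 1:20) {
    set.seed(seed)
    D <- matrix(rnorm(16 * 6), 16, 6)
    D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
    v <- rnorm(16)
    got <- sparse_code(v, make_fake_dict(D), sparsity_t = 2)
    expect_lte(got$residual_norm, oracle_best_pair_residual(v, D) + 1e-9)
  }
})

test_that("coding residual never increases with the sparsity budget", {
  set.seed(5)
  D <- matrix(rnorm(16 * 10), 16, 10)
  D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
  dict <- make_fake_dict(D)
  v <- rnorm(16)
  res <- sapply(1:6, function(t) sparse_code(v, dict, t)$residual_norm)
  expect_true(all(diff(res) <= 1e-12))
})

test_that("code fusion follows the MSML rule with ties to A", {
  K <- 5; N <- 4
  ca <- matrix(1, K, N); cb <- matrix(2, K, N)
  out <- fuse_codes(ca, cb, means_a = rep(10, N), means_b = rep(20, N),
                    msml_a = c(5, 3, 4, 1), msml_b = c(3, 5, 4, 1))
  expect_equal(out$from_a, c(TRUE, FALSE, TRUE, TRUE))  # ties at 4 and 1 -> A
  expect_equal(out$coeffs[1, ], c(1, 2, 1, 1))
  expect_equal(out$means, c(10, 20, 10, 10))            # mean travels with code
  same <- fuse_codes(ca, ca, rep(1, N), rep(1, N), 1:4, 1:4)
  expect_equal(same$coeffs, ca)
  expect_error(fuse_codes(ca, cb[, 1:3], rep(1, N), rep(1, N), 1:4, 1:4),
               "aligned")
})

test_that("reconstruction rebuilds D a + m with overlap averaging", {
  set.seed(6)
  n <- 4L
  D <- matrix(rnorm(16 * 8), 16, 8)
  D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
  dict <- make_fake_dict(D)
  # all-zero codes, constant mean -> constant band
  origins <- expand.grid(r = c(1L, 5L), c = c(1L, 5L))
  fused0 <- list(coeffs = matrix(0, 8, 4), means = rep(0.4, 4))
  out <- reconstruct_low_band(fused0, dict, c(8L, 8L),
                              origins$r, origins$c, n)
  expect_equal(out$band, matrix(0.4, 8, 8))
  expect_true(all(out$weight_map == 1))
  # non-overlapping tiling reproduces each block exactly
  coeffs <- matrix(rnorm(8 * 4), 8, 4)
  means <- rnorm(4)
  out <- reconstruct_low_band(list(coeffs = coeffs, means = means),
                              dict, c(8L, 8L), origins$r, origins$c, n)
  blk <- matrix(D %*% coeffs[, 1] + means[1], 4, 4)
  expect_equal(out$band[1:4, 1:4], blk, tolerance = 1e-12)
  # overlapping stride n/2 matches the accumulate-and-divide loop oracle
  og <- expand.grid(r = c(1L, 3L, 5L), c = c(1L, 3L, 5L))
  og <- og[order(og$r, og$c), ]
  coeffs <- matrix(rnorm(8 * 9), 8, 9)
  means <- rnorm(9)
  out <- reconstruct_low_band(list(coeffs = coeffs, means = means),
                              dict, c(8L, 8L), og$r, og$c, n)
  blocks <- lapply(seq_len(9), function(k)
    matrix(D %*% coeffs[, k] + means[k], 4, 4))
  expect_equal(out$band,
               oracle_overlap_average(blocks, og$r, og$c, 4L, c(8L, 8L)),
               tolerance = 1e-12)
  # coverage gaps are an error
  expect_error(reconstruct_low_band(fused0, dict, c(12L, 12L),
                                    origins$r, origins$c, n),
               "uncovered")
})

test_that("dictionaries survive a save/load round trip", {
  set.seed(7)
  X <- matrix(rnorm(16 * 20), 16, 20)
  X <- sweep(X, 2, colMeans(X))
  patches <- fake_patches(X)
  partition <- list(edge = 1:10, texture = 11:20, smooth = integer(0),
                    total = 20L)
  dict <- train_subdictionaries(patches, partition, atoms_per_cluster = 4,
                                iterations = 3, seed = 9)
  path <- withr::local_tempfile(fileext = ".dict")
  save_dictionary(dict, path)
  back <- load_dictionary(path)
  expect_equal(back$merged, dict$merged, tolerance = 1e-15)
  expect_equal(sort(names(back$sub)), sort(names(dict$sub)))
})
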