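# Clustered dictionary learning, sparse coding and low-band fusion.
#
# Each nonempty cluster (edge/texture/smooth) is trained independently with
# mini-batch online dictionary learning (ODL); the sub-dictionaries are
# concatenated into one merged dictionary D against which every patch is
# sparse-coded. Codes of co-located patches are fused by the MSML rule (the
# more active source wins; ties go to A), and the fused low band is rebuilt
# patch-by-patch as D %*% a + m with overlap averaging.

#' Train per-cluster sub-dictionaries with online dictionary learning
#'
#' Runs mini-batch ODL (alternating greedy sparse coding and block-coordinate
#' atom updates on accumulator matrices) independently on each nonempty
#' cluster. Atoms are initialized from a seeded sample of the cluster's own
#' patches (zero-norm picks are replaced by seeded Gaussian vectors) and kept
#' at unit L2 norm throughout. Empty clusters are omitted from the merged
#' dictionary. Fully deterministic given `seed`.
#'
#' @param patches An [extract_joint_patches()] result.
#' @param partition An [assign_clusters()] result over the same joint set.
#' @param atoms_per_cluster Atoms k per sub-dictionary (capped at the cluster
#'   size). Default 64.
#' @param iterations Passes of mini-batch ODL over each cluster. Default 15.
#' @param sparsity_t Sparsity budget used during training. Default 4.
#' @param seed Integer seed controlling initialization and batch order.
#' @return Object of class `clustered_dictionary`: list with `merged`
#'   (n^2 x K atom matrix, unit-norm columns), `sub` (named list of the
#'   per-cluster atom matrices present), `atom_cluster` (cluster label per
#'   merged column), `patch_size`.
#' @export
train_subdictionaries <- function(patches, partition, atoms_per_cluster = 64L,
                                  iterations = 15L, sparsity_t = 4L,
                                  seed = 1L) {
  idx_by_cluster <- list(edge = partition$edge,
                         texture = partition$texture,
                         smooth = partition$smooth)
  nonempty <- names(idx_by_cluster)[vapply(idx_by_cluster, length, 1L) > 0L]
  if (length(nonempty) == 0L)
    stop_validation("train_subdictionaries: all clusters are empty")
  sub <- list()
  with_seed(seed, {
    for (cl in nonempty) {
      X <- patches$vectors[, idx_by_cluster[[cl]], drop = FALSE]
      k <- min(atoms_per_cluster, ncol(X))
      sub[[cl]] <- odl_train(X, k, iterations, sparsity_t)
    }
  })
  merged <- do.call(cbind, sub)
  atom_cluster <- rep(names(sub), vapply(sub, ncol, 1L))
  structure(list(merged = merged, sub = sub, atom_cluster = atom_cluster,
                 patch_size = patches$patch_size),
            class = "clustered_dictionary")
}

# Mini-batch online dictionary learning (Mairal-style). X: p x n training
# matrix (columns are mean-removed patches). Returns p x k unit-norm atoms.
odl_train <- function(X, k, iterations, sparsity_t, batch_size = 32L) {
  p <- nrow(X); n <- ncol(X)
  D <- init_atoms(X, k)
  A <- diag(1e-8, k)          # sum of alpha alpha^T (ridge keeps updates defined)
  B <- matrix(0, p, k)        # sum of x alpha^T
  for (it in seq_len(iterations)) {
    ord <- sample.int(n)
    starts <- seq.int(1L, n, by = batch_size)
    for (s in starts) {
      cols <- ord[s:min(s + batch_size - 1L, n)]
      Xb <- X[, cols, drop = FALSE]
      Ab <- omp_code_matrix(Xb, D, sparsity_t)
      A <- A + Ab %*% t(Ab)
      B <- B + Xb %*% t(Ab)
      # block-coordinate atom update (one sweep)
      for (j in seq_len(k)) {
        ajj <- A[j, j]
        if (ajj <= 1e-10) next
        u <- D[, j] + (B[, j] - D %*% A[, j]) / ajj
        nu <- sqrt(sum(u^2))
        if (nu > 1e-12) D[, j] <- u / nu
      }
    }
  }
  D
}

# Seeded initialization: sample columns of X, unit-normalize, replace
# degenerate (near-zero) picks with random unit Gaussians.
init_atoms <- function(X, k) {
  picks <- sample.int(ncol(X), k, replace = ncol(X) < k)
  D <- X[, picks, drop = FALSE]
  for (j in seq_len(k)) {
    nj <- sqrt(sum(D[, j]^2))
    if (nj > 1e-10) {
      D[, j] <- D[, j] / nj
    } else {
      g <- stats::rnorm(nrow(X))
      D[, j] <- g / sqrt(sum(g^2))
    }
  }
  D
}

# Orthogonal matching pursuit for one vector. Returns dense coefficient
# vector (length ncol(D)) with at most t nonzeros, plus the residual norm.
omp_one <- function(v, D, t, tol = 1e-12, refine = FALSE) {
  k <- ncol(D)
  coeffs <- numeric(k)
  r <- v
  sel <- integer(0)
  for (step in seq_len(min(t, k))) {
    if (sqrt(sum(r^2)) <= tol) break
    corr <- abs(crossprod(D, r))
    corr[sel] <- -Inf
    j <- which.max(corr)
    sel <- c(sel, j)
    fit <- least_squares_fit(v, D, sel)
    r <- fit$residual
  }
  if (refine && length(sel) > 0L && sqrt(sum(r^2)) > tol) {
    sel <- omp_swap_refine(v, D, sel)
    sel <- exact_subset_if_small(v, D, sel, min(t, k))
    fit <- least_squares_fit(v, D, sel)
    r <- fit$residual
  }
  if (length(sel) > 0L) coeffs[sel] <- least_squares_fit(v, D, sel)$beta
  list(coeffs = coeffs, residual_norm = sqrt(sum(r^2)), support = sel)
}

least_squares_fit <- function(v, D, sel) {
  Ds <- D[, sel, drop = FALSE]
  beta <- tryCatch(qr.solve(Ds, v), error = function(e) {
    # rank-deficient support: minimum-norm solution via pseudoinverse
    sv <- svd(Ds)
    pos <- sv$d > 1e-10 * sv$d[1]
    sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% v) / sv$d[pos])
  })
  beta <- as.numeric(beta)
  list(beta = beta, residual = v - as.numeric(Ds %*% beta))
}

# Local swap refinement: greedily replace one selected atom by one
# unselected atom while the residual improves. Protects the greedy pursuit
# from near-miss selections on coherent dictionaries.
omp_swap_refine <- function(v, D, sel, max_rounds = 10L) {
  k <- ncol(D)
  best <- sum(least_squares_fit(v, D, sel)$residual^2)
  for (round in seq_len(max_rounds)) {
    improved <- FALSE
    for (pos in seq_along(sel)) {
      for (cand in setdiff(seq_len(k), sel)) {
        trial <- sel
        trial[pos] <- cand
        res <- sum(least_squares_fit(v, D, trial)$residual^2)
        if (res < best - 1e-14) {
          sel <- trial; best <- res; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  sel
}

# Exact best-subset selection, feasible only for tiny dictionaries (sparse
# coding is NP-hard in general, but for at most `budget` candidate supports
# exhaustive least squares is cheap and certifiably optimal). Returns the
# incumbent support unless a strictly better one exists.
exact_subset_if_small <- function(v, D, sel, t, budget = 512) {
  k <- ncol(D)
  if (t < 1L || choose(k, t) > budget) return(sel)
  best <- sum(least_squares_fit(v, D, sel)$residual^2)
  supports <- utils::combn(k, t)
  for (col in seq_len(ncol(supports))) {
    trial <- supports[, col]
    res <- sum(least_squares_fit(v, D, trial)$residual^2)
    if (res < best - 1e-14) {
      sel <- trial; best <- res
    }
  }
  sel
}

# Batch OMP used inside training (no refinement; speed matters there).
omp_code_matrix <- function(X, D, t) {
  out <- matrix(0, ncol(D), ncol(X))
  for (i in seq_len(ncol(X))) out[, i] <- omp_one(X[, i], D, t)$coeffs
  out
}

#' Sparse-code one patch vector against the merged dictionary
#'
#' Greedy orthogonal pursuit with at most `sparsity_t` nonzero coefficients,
#' followed by a polishing pass: atom swaps while the residual improves,
#' plus exact best-subset enumeration whenever the dictionary is small
#' enough for that to be tractable (at most ~500 candidate supports), where
#' the returned code is certifiably optimal.
#'
#' @param vector Mean-removed patch vector (length n^2).
#' @param dict A [train_subdictionaries()] result (or any list with a
#'   `merged` atom matrix).
#' @param sparsity_t Sparsity budget T. Default 4.
#' @param refine Run the swap-refinement pass (default TRUE; the full-image
#'   pipeline disables it for speed, where plain orthogonal pursuit is
#'   already accurate on learned dictionaries).
#' @return List with `coeffs` (dense length-K vector), `support`,
#'   `residual_norm`.
#' @export
sparse_code <- function(vector, dict, sparsity_t = 4L, refine = TRUE) {
  D <- dict$merged
  if (is.null(D) || ncol(D) == 0L)
    stop_validation("sparse_code: dictionary has no atoms")
  if (length(vector) != nrow(D))
    stop_validation("sparse_code: vector length %d does not match atom size %d",
                    length(vector), nrow(D))
  omp_one(vector, D, sparsity_t, refine = refine)
}

# Code every column of a patch matrix; returns coefficient matrix K x N.
sparse_code_all <- function(vectors, dict, sparsity_t = 4L, refine = FALSE) {
  D <- dict$merged
  out <- matrix(0, ncol(D), ncol(vectors))
  for (i in seq_len(ncol(vectors)))
    out[, i] <- omp_one(vectors[, i], D, sparsity_t, refine = refine)$coeffs
  out
}

#' Fuse sparse codes of co-located patches by the MSML rule
#'
#' For each spatial patch position i, the fused code/mean is A's if
#' `MSML(i; A) >= MSML(i; B)` and B's otherwise; the coefficient vector and
#' the patch mean always travel together.
#'
#' @param codes_a,codes_b K x N coefficient matrices for the co-located
#'   patches of A and B.
#' @param means_a,means_b Length-N patch means.
#' @param msml_a,msml_b Length-N patch activities (same spatial order).
#' @return List with `coeffs` (K x N), `means`, and `from_a` (logical).
#' @export
fuse_codes <- function(codes_a, codes_b, means_a, means_b, msml_a, msml_b) {
  n <- ncol(codes_a)
  if (ncol(codes_b) != n || length(means_a) != n || length(means_b) != n ||
      length(msml_a) != n || length(msml_b) != n)
    stop_validation("fuse_codes: inputs not aligned (A has %d patches)", n)
  from_a <- msml_a >= msml_b
  coeffs <- codes_b
  coeffs[, from_a] <- codes_a[, from_a, drop = FALSE]
  means <- ifelse(from_a, means_a, means_b)
  list(coeffs = coeffs, means = means, from_a = from_a)
}

#' Reconstruct the fused low band from fused codes
#'
#' Rebuilds each patch as `D %*% a + m`, places it at its origin and
#' averages overlapping contributions by per-pixel coverage count.
#'
#' @param fused A [fuse_codes()] result.
#' @param dict The dictionary the codes refer to.
#' @param shape `c(H, W)` of the band.
#' @param row,col Patch origins (1-based), same order as the codes.
#' @param patch_size Patch side n.
#' @return List with `band` (H x W matrix) and `weight_map` (coverage
#'   counts, all >= 1).
#' @export
reconstruct_low_band <- function(fused, dict, shape, row, col, patch_size) {
  H <- shape[1L]; W <- shape[2L]
  acc <- matrix(0, H, W)
  wt <- matrix(0, H, W)
  recon <- dict$merged %*% fused$coeffs   # n^2 x N
  for (i in seq_len(ncol(recon))) {
    rr <- row[i]:(row[i] + patch_size - 1L)
    cc <- col[i]:(col[i] + patch_size - 1L)
    block <- matrix(recon[, i] + fused$means[i], patch_size, patch_size)
    acc[rr, cc] <- acc[rr, cc] + block
    wt[rr, cc] <- wt[rr, cc] + 1
  }
  if (any(wt == 0))
    stop_validation("reconstruct_low_band: tiling leaves %d uncovered pixel(s)",
                    sum(wt == 0))
  list(band = acc / wt, weight_map = wt)
}

#' Save / load a clustered dictionary
#'
#' Plain-text representation: a JSON header (atom size, cluster labels) and
#' the atom matrix in column-major scientific notation, so dictionaries can
#' move between a training run and a later fusion run.
#'
#' @param dict A `clustered_dictionary`.
#' @param path Output file.
#' @return `path` (write) / the dictionary (load), invisibly for write.
#' @export
save_dictionary <- function(dict, path) {
  header <- list(patch_size = dict$patch_size,
                 n_rows = nrow(dict$merged),
                 atom_cluster = dict$atom_cluster)
  lines <- c(jsonlite::toJSON(header, auto_unbox = TRUE),
             paste(format(dict$merged, digits = 17, scientific = TRUE,
                          trim = TRUE), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname save_dictionary
#' @export
load_dictionary <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1L])
  vals <- as.numeric(strsplit(lines[2L], " ", fixed = TRUE)[[1L]])
  merged <- matrix(vals, nrow = header$n_rows)
  atom_cluster <- header$atom_cluster
  sub <- lapply(split(seq_len(ncol(merged)), atom_cluster),
                function(ix) merged[, ix, drop = FALSE])
  structure(list(merged = merged, sub = sub, atom_cluster = atom_cluster,
                 patch_size = header$patch_size),
            class = "clustered_dictionary")
}

#' @export
print.clustered_dictionary <- function(x, ...) {
  cat(sprintf("clustered_dictionary: %d atoms (%s), atom size %d\n",
              ncol(x$merged),
              paste(sprintf("%s=%d", names(x$sub),
                            vapply(x$sub, ncol, 1L)), collapse = ", "),
              nrow(x$merged)))
  invisible(x)
}
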