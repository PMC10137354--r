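# Joint patch set construction and edge/texture/smooth clustering.
#
# Patches from both low bands are pooled into one joint set; two thresholds
# derived from the maximum MSML activity over that set split it into an edge
# cluster Ce (MSML >= TH1), a texture cluster Ct (TH1 > MSML >= TH2) and a
# smooth cluster Cs (MSML < TH2).

TH1_FRACTION <- 0.13
TH2_FRACTION <- 0.07

#' Extract the joint patch set from two low bands
#'
#' Slides an n x n window over each band (stride `stride`, row-major, border
#' patches pinned as in [msml_per_patch()]), flattens each patch
#' column-major, removes its mean, and stacks A's patches before B's.
#' Means are kept separately: dictionary learning and sparse coding operate
#' on zero-mean structure, and the mean is restored at reconstruction.
#'
#' @param low_a,low_b Numeric matrices of identical shape.
#' @param patch_size Patch side n (default 8).
#' @param stride Origin step (default 4, 50% overlap).
#' @return List with `vectors` (n^2 x N matrix of mean-removed patches),
#'   `means` (length-N), `row`, `col`, `source` (length-N), `patch_size`,
#'   `stride`, `shape`, and `n_per_image`.
#' @export
extract_joint_patches <- function(low_a, low_b, patch_size = 8L, stride = 4L) {
  if (!identical(dim(low_a), dim(low_b)))
    stop_validation("low bands differ in shape: %dx%d vs %dx%d",
                    nrow(low_a), ncol(low_a), nrow(low_b), ncol(low_b))
  pa <- extract_patches_one(low_a, patch_size, stride)
  pb <- extract_patches_one(low_b, patch_size, stride)
  vectors <- cbind(pa$vectors, pb$vectors)
  means <- c(pa$means, pb$means)
  vectors <- sweep(vectors, 2L, means)
  list(vectors = vectors, means = means,
       row = c(pa$row, pb$row), col = c(pa$col, pb$col),
       source = rep(c("A", "B"), times = c(ncol(pa$vectors), ncol(pb$vectors))),
       patch_size = as.integer(patch_size), stride = as.integer(stride),
       shape = dim(low_a), n_per_image = ncol(pa$vectors))
}

# Patches of a single band, not yet mean-removed.
extract_patches_one <- function(band, patch_size, stride) {
  h <- nrow(band); w <- ncol(band)
  or <- patch_origins(h, patch_size, stride)
  oc <- patch_origins(w, patch_size, stride)
  n2 <- patch_size * patch_size
  total <- length(or) * length(oc)
  vecs <- matrix(0, n2, total)
  rows <- integer(total); cols <- integer(total)
  idx <- 1L
  for (r in or) {
    for (cc in oc) {
      vecs[, idx] <- as.vector(band[r:(r + patch_size - 1L),
                                    cc:(cc + patch_size - 1L)])
      rows[idx] <- r; cols[idx] <- cc
      idx <- idx + 1L
    }
  }
  list(vectors = vecs, means = colMeans(vecs), row = rows, col = cols)
}

#' Cluster thresholds from MSML activities
#'
#' `TH1 = 0.13 * max(MSML)` and `TH2 = 0.07 * max(MSML)`, the maximum taken
#' over the joint patch set (both source images).
#'
#' @param activities data.frame with an `msml` column (rbind the per-image
#'   [msml_per_patch()] outputs).
#' @return List with `th1`, `th2`, `max_msml`.
#' @export
compute_thresholds <- function(activities) {
  if (NROW(activities) == 0L)
    stop_validation("compute_thresholds: empty activity set")
  mx <- max(activities$msml)
  list(th1 = TH1_FRACTION * mx, th2 = TH2_FRACTION * mx, max_msml = mx)
}

#' Assign patches to edge/texture/smooth clusters
#'
#' Edge if `MSML >= TH1`, texture if `TH1 > MSML >= TH2`, smooth otherwise.
#' Both boundaries are inclusive upwards, so a patch exactly at TH1 is an
#' edge patch and one exactly at TH2 is a texture patch. Every patch lands
#' in exactly one cluster.
#'
#' @param activities data.frame with an `msml` column; row order defines the
#'   joint patch indices.
#' @param th A [compute_thresholds()] result.
#' @return List with integer index vectors `edge`, `texture`, `smooth`,
#'   `labels` (factor over all patches) and `total`.
#' @export
assign_clusters <- function(activities, th) {
  v <- activities$msml
  lab <- ifelse(v >= th$th1, "edge", ifelse(v >= th$th2, "texture", "smooth"))
  labels <- factor(lab, levels = c("edge", "texture", "smooth"))
  list(edge = which(labels == "edge"),
       texture = which(labels == "texture"),
       smooth = which(labels == "smooth"),
       labels = labels,
       total = length(v))
}

#' One-line summary of a cluster partition
#' @param partition An [assign_clusters()] result.
#' @param th A [compute_thresholds()] result.
#' @return Named list suitable for JSON export.
#' @export
partition_summary <- function(partition, th) {
  list(n_edge = length(partition$edge),
       n_texture = length(partition$texture),
       n_smooth = length(partition$smooth),
       total = partition$total,
       th1 = th$th1, th2 = th$th2, max_msml = th$max_msml)
}
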