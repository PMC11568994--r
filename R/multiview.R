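# Multiviewed batches for descriptor training: one base image plus N
# augmented views, with shared keypoint identities tracked through every
# view.  With K keypoints surviving in all views, the batch holds K(1+N)
# samples; each anchor has N positives (the same keypoint in the other
# views) and (K-1)(N+1) negatives (every other keypoint in every view,
# including the anchor's own view).

#' Photometric view augmentation
#'
#' Applies an HSV jitter (always) and additive Gaussian pixel noise with
#' mean 0 and standard deviation `noise_sd` (with probability `noise_prob`),
#' then clips to [0, 1].  Coordinates are never altered.
#'
#' @param image H x W x 3 array, values in [0, 1].
#' @param hsv maximum absolute (hue, saturation, value) jitter; drawn
#'   uniformly per call.
#' @param noise_sd Gaussian noise standard deviation (default 0.05).
#' @param noise_prob probability that noise is applied (default 0.25).
#' @return the augmented image.
#' @export
photometric_augment <- function(image, hsv = c(0.02, 0.15, 0.15),
                                noise_sd = 0.05, noise_prob = 0.25) {
  stopifnot(length(dim(image)) == 3)
  out <- if (any(hsv > 0)) {
    # the HSV round trip already lands in [0, 1]
    shift_hsv(image, runif(3, -1, 1) * hsv)
  } else {
    image
  }
  if (noise_prob > 0 && runif(1) < noise_prob && noise_sd > 0) {
    out <- clamp01(out + array(rnorm(length(out), 0, noise_sd), dim(out)))
  }
  out
}

#' Build a multiviewed batch
#'
#' View 0 is the base image with an identity warp; views 1..N are affine
#' warps of the base image, each followed by [photometric_augment()].  The
#' geometric transforms are applied to both the images and the keypoint
#' coordinates, so each keypoint identity has known coordinates in all N+1
#' views.  A keypoint whose warped position leaves any view (with a `margin`
#' pixel border so nearest-pixel descriptor sampling stays valid) is removed
#' from all views, keeping K identical across views.
#'
#' @param image base H x W x 3 array.
#' @param kps a non-empty [keypoint_set()] detected on the base image.
#' @param n_views N >= 1, number of augmented views.
#' @param ranges an [affine_ranges()] for the spatial augmentation.
#' @param hsv,noise_sd,noise_prob photometric augmentation parameters.
#' @param margin border width in pixels keypoints must keep clear of.
#' @return a `multiview_batch`: list with `views` (N+1 images, index 1 =
#'   base), `warps` (N+1 matrices, index 1 = identity), `coords` (list of
#'   N+1 K x 2 matrices), `classes` (length K) and `n_views`.
#' @export
build_multiview_batch <- function(image, kps, n_views,
                                  ranges = affine_ranges(),
                                  hsv = c(0.02, 0.15, 0.15),
                                  noise_sd = 0.05, noise_prob = 0.25,
                                  margin = 3) {
  stopifnot(n_views >= 1, inherits(kps, "keypoint_set"))
  if (!nrow(kps)) {
    stopf("fundusreg_degenerate_batch", "keypoint set is empty")
  }
  sz <- dim(image)[1:2]
  base_xy <- cbind(kps$x, kps$y)
  warps <- vector("list", n_views + 1)
  views <- vector("list", n_views + 1)
  coords <- vector("list", n_views + 1)
  warps[[1]] <- diag(3)
  views[[1]] <- image
  coords[[1]] <- base_xy
  keep <- rep(TRUE, nrow(kps))
  for (v in seq_len(n_views)) {
    A <- sample_affine(ranges, sz)$matrix
    warps[[v + 1]] <- A
    views[[v + 1]] <- photometric_augment(
      warp_image(image, A, sz, fill = 0.05),
      hsv = hsv, noise_sd = noise_sd, noise_prob = noise_prob)
    p <- apply_homography(A, base_xy)
    coords[[v + 1]] <- p
    keep <- keep & p[, 1] >= margin & p[, 1] <= sz[2] - 1 - margin &
      p[, 2] >= margin & p[, 2] <= sz[1] - 1 - margin
  }
  keep <- keep & base_xy[, 1] >= margin & base_xy[, 1] <= sz[2] - 1 - margin &
    base_xy[, 2] >= margin & base_xy[, 2] <= sz[1] - 1 - margin
  if (!any(keep)) {
    stopf("fundusreg_degenerate_batch",
          "all keypoints left the view bounds; resample the augmentations")
  }
  coords <- lapply(coords, function(p) p[keep, , drop = FALSE])
  structure(list(views = views, warps = warps, coords = coords,
                 classes = kps$class[keep], n_views = n_views),
            class = "multiview_batch")
}

#' Sample bookkeeping of a multiviewed batch
#'
#' @param batch a [build_multiview_batch()] result.
#' @return list with `K`, `N`, `total` = K(1+N), `positives_per_anchor` = N
#'   and `negatives_per_anchor` = (K-1)(N+1).
#' @export
batch_combinatorics <- function(batch) {
  K <- length(batch$classes)
  N <- batch$n_views
  list(K = K, N = N, total = K * (1 + N), positives_per_anchor = N,
       negatives_per_anchor = (K - 1) * (N + 1))
}
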