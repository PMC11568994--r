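# Planar transforms: affine parameter sampling and 3x3 homography algebra.

#' Ranges for random affine view augmentation
#'
#' Container for the uniform sampling ranges of the affine augmentations used
#' to build multiviewed batches.  Defaults are the descriptor-training ranges:
#' rotations of +/-60 degrees, translations of 0.25 x image size per axis,
#' scaling in [0.75, 1.25] and shearing of +/-30 degrees.
#'
#' @param rotation maximum absolute rotation, degrees.
#' @param translation maximum absolute translation, fraction of the image
#'   size, applied independently per axis.
#' @param scale length-2 numeric, inclusive range of the isotropic scale
#'   factor.
#' @param shear maximum absolute shear, degrees.
#' @param perspective scale of the random projective terms (0 keeps the
#'   transform affine); used when sampling registration fixtures.
#' @return an object of class `affine_ranges`.
#' @export
affine_ranges <- function(rotation = 60, translation = 0.25,
                          scale = c(0.75, 1.25), shear = 30,
                          perspective = 0) {
  stopifnot(rotation >= 0, translation >= 0, length(scale) == 2,
            scale[1] <= scale[2], scale[1] > 0, shear >= 0, perspective >= 0)
  structure(list(rotation = rotation, translation = translation,
                 scale = scale, shear = shear, perspective = perspective),
            class = "affine_ranges")
}

#' Draw random affine parameters
#'
#' Parameters are drawn uniformly and independently from `ranges`, using the
#' current RNG stream (seed the stream for reproducibility).  The returned
#' matrix acts on 0-based (x, y) pixel coordinates about the image centre.
#'
#' @param ranges an [affine_ranges()] object.
#' @param size image size in pixels, either a scalar (square) or c(H, W).
#' @return a list with the drawn `rotation`, `translation`, `scale`, `shear`
#'   and the 3x3 `matrix`.
#' @export
sample_affine <- function(ranges, size) {
  stopifnot(inherits(ranges, "affine_ranges"))
  size <- if (length(size) == 1) c(size, size) else size
  rot <- runif(1, -ranges$rotation, ranges$rotation)
  tr <- c(runif(1, -ranges$translation, ranges$translation) * size[2],
          runif(1, -ranges$translation, ranges$translation) * size[1])
  sc <- runif(1, ranges$scale[1], ranges$scale[2])
  sh <- runif(1, -ranges$shear, ranges$shear)
  A <- affine_matrix(rot, tr, sc, sh, center = (rev(size) - 1) / 2)
  list(rotation = rot, translation = tr, scale = sc, shear = sh, matrix = A)
}

#' Build an affine matrix about a centre point
#'
#' Composition order (applied to a point): translate centre to origin, scale,
#' shear along x, rotate, translate back plus the requested offset.
#'
#' @param rotation degrees; @param translation c(tx, ty) pixels;
#' @param scale scalar or c(sx, sy); @param shear degrees (x direction);
#' @param center c(cx, cy) in pixels.
#' @return 3x3 matrix mapping homogeneous (x, y, 1).
#' @export
affine_matrix <- function(rotation = 0, translation = c(0, 0), scale = 1,
                          shear = 0, center = c(0, 0)) {
  th <- rotation * pi / 180
  sh <- tan(shear * pi / 180)
  sc <- if (length(scale) == 1) c(scale, scale) else scale
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  S <- diag(c(sc, 1))
  Sh <- matrix(c(1, 0, 0, sh, 1, 0, 0, 0, 1), 3, 3)
  Tc <- diag(3); Tc[1:2, 3] <- -center
  Tb <- diag(3); Tb[1:2, 3] <- center + translation
  Tb %*% R %*% Sh %*% S %*% Tc
}

#' Apply a homography to point coordinates
#'
#' @param h 3x3 matrix.
#' @param xy n x 2 matrix (or length-2 vector) of (x, y) coordinates.
#' @return n x 2 matrix of mapped coordinates; points mapped to infinity
#'   (vanishing denominator) come back non-finite.
#' @export
apply_homography <- function(h, xy) {
  xy <- rbind_coords(xy)
  p <- cbind(xy, 1) %*% t(h)
  w <- p[, 3]
  w[abs(w) < 1e-300] <- NA_real_
  cbind(p[, 1] / w, p[, 2] / w)
}

rbind_coords <- function(xy) {
  if (is.null(dim(xy))) matrix(xy, ncol = 2) else as.matrix(xy)
}

#' Scale-normalize a homography
#'
#' Divides by the (3,3) entry when it is non-zero, the conventional
#' representative of the projective equivalence class.
#' @param h 3x3 matrix.
#' @return 3x3 matrix with `h[3,3] == 1` when possible.
#' @export
normalize_homography <- function(h) {
  if (abs(h[3, 3]) > 1e-12) h / h[3, 3] else h
}

# Warp an image (H x W x C array, values [0,1]) by homography `h` mapping
# input coordinates to output coordinates; out-of-frame pixels take `fill`.
warp_image <- function(image, h, out_size = dim(image)[1:2], fill = 0) {
  stopifnot(length(dim(image)) == 3)
  hi <- solve(h)
  out <- cpp_warp_projective(image, hi, out_size[1], out_size[2], fill)
  array(out, c(out_size, dim(image)[3]))
}
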