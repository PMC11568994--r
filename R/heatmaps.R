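# Gaussian target heatmaps and discrete keypoint extraction.
#
# The detector is trained by heatmap regression: the binary keypoint ground
# truth is turned into smooth confidence surfaces with value 1 at every
# keypoint and values decaying with a Gaussian profile around it.  Three
# co-registered planes are used: one per keypoint class plus a combined plane
# holding every keypoint regardless of class.

HEATMAP_PLANES <- c("crossover", "bifurcation", "combined")

#' Create a heatmap stack
#'
#' @param planes H x W x 3 array in plane order crossover, bifurcation,
#'   combined; values in [0, 1].
#' @param sigma Gaussian standard deviation, pixels.
#' @return an object of class `heatmap_stack`.
#' @export
heatmap_stack <- function(planes, sigma) {
  stopifnot(length(dim(planes)) == 3, dim(planes)[3] == 3, sigma > 0)
  dimnames(planes) <- list(NULL, NULL, HEATMAP_PLANES)
  structure(list(planes = planes, sigma = sigma), class = "heatmap_stack")
}

#' Convert binary keypoint ground truth to Gaussian heatmaps
#'
#' Each class plane places a unit-height isotropic Gaussian of standard
#' deviation `sigma` at every keypoint of that class; overlapping Gaussians
#' are composed with the pointwise maximum so peaks keep amplitude 1 (the
#' targets are detection confidences, not densities).  The combined plane is
#' built the same way from all keypoints.
#'
#' @param gt a [keypoint_set()]; an empty set yields all-zero planes.
#' @param sigma Gaussian standard deviation in pixels, > 0.
#' @return a [heatmap_stack()].
#' @export
binary_to_heatmap <- function(gt, sigma = 5) {
  stopifnot(inherits(gt, "keypoint_set"), sigma > 0)
  sz <- image_size_of(gt)
  planes <- array(0, c(sz[1], sz[2], 3))
  paint <- function(plane, xs, ys) {
    r <- ceiling(7 * sigma)   # truncation below double-precision relevance
    for (i in seq_along(xs)) {
      x0 <- max(0, floor(xs[i] - r)); x1 <- min(sz[2] - 1, ceiling(xs[i] + r))
      y0 <- max(0, floor(ys[i] - r)); y1 <- min(sz[1] - 1, ceiling(ys[i] + r))
      gx <- exp(-((x0:x1) - xs[i])^2 / (2 * sigma^2))
      gy <- exp(-((y0:y1) - ys[i])^2 / (2 * sigma^2))
      g <- outer(gy, gx)
      win <- plane[(y0:y1) + 1, (x0:x1) + 1, drop = FALSE]
      plane[(y0:y1) + 1, (x0:x1) + 1] <- pmax(win, g)
    }
    plane
  }
  for (p in 1:2) {
    sel <- gt$class == HEATMAP_PLANES[p]
    planes[, , p] <- paint(planes[, , p], gt$x[sel], gt$y[sel])
  }
  planes[, , 3] <- paint(planes[, , 3], gt$x, gt$y)
  heatmap_stack(planes, sigma)
}

#' Extract discrete keypoints from a heatmap stack
#'
#' Detections are the pixels of the combined plane that are strict maxima of
#' their `window` x `window` neighbourhood and reach `threshold`.  The class
#' of each detection is the class whose plane has the larger value at that
#' pixel; exact ties resolve to bifurcation (deterministic tie-break).
#'
#' @param h a [heatmap_stack()] (values outside [0, 1] are clipped first).
#' @param threshold detection threshold in (0, 1]; default 0.35.
#' @param window odd neighbourhood size >= 3, pixels; default 7.
#' @return a [keypoint_set()]; possibly empty.
#' @export
extract_keypoints <- function(h, threshold = 0.35, window = 7) {
  stopifnot(inherits(h, "heatmap_stack"),
            threshold > 0, window >= 3, window %% 2 == 1)
  planes <- clamp01(h$planes)
  comb <- planes[, , 3]
  H <- nrow(comb); W <- ncol(comb)
  cand <- which(comb >= threshold, arr.ind = TRUE)
  r <- (window - 1) / 2
  xs <- ys <- numeric(0); cls <- character(0)
  if (nrow(cand)) {
    # pad with -Inf so border pixels compare only against in-frame pixels
    pad <- matrix(-Inf, H + 2 * r, W + 2 * r)
    pad[r + seq_len(H), r + seq_len(W)] <- comb
    for (i in seq_len(nrow(cand))) {
      rr <- cand[i, 1]; cc <- cand[i, 2]
      v <- comb[rr, cc]
      nb <- pad[(rr - 1):(rr + 2 * r - 1) + 1, (cc - 1):(cc + 2 * r - 1) + 1]
      nb[r + 1, r + 1] <- -Inf
      if (v > max(nb)) {
        xs <- c(xs, cc - 1); ys <- c(ys, rr - 1)
        cls <- c(cls, if (planes[rr, cc, 1] > planes[rr, cc, 2])
          "crossover" else "bifurcation")
      }
    }
  }
  keypoint_set(xs, ys, cls, c(H, W))
}

#' Persist a heatmap stack for inspection
#'
#' Writes the three planes as one 3-channel 16-bit TIFF (needs the `tiff`
#' package) or, if unavailable, an 8-bit PNG.
#' @param h a [heatmap_stack()]; @param path output file.
#' @export
write_heatmap <- function(h, path) {
  img <- clamp01(h$planes)
  if (requireNamespace("tiff", quietly = TRUE) &&
      grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(img, path, bits.per.sample = 16L)
  } else {
    png::writePNG(img, path)
  }
  invisible(path)
}
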