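# Labelled keypoint sets: vessel crossovers and bifurcations for one image.

KEYPOINT_CLASSES <- c("crossover", "bifurcation")

#' Create a labelled keypoint set
#'
#' A keypoint set holds the (x, y) pixel locations of vessel crossovers and
#' bifurcations for one image, in the package-wide 0-based (x = column,
#' y = row) convention.
#'
#' @param x,y numeric vectors of coordinates, `0 <= x < W`, `0 <= y < H`.
#' @param class character vector, each element `"crossover"` or
#'   `"bifurcation"`.
#' @param image_size c(H, W) of the image the points live in.
#' @return a `keypoint_set`: a data.frame with columns `x`, `y`, `class` and
#'   an `image_size` attribute.
#' @export
keypoint_set <- function(x = numeric(), y = numeric(),
                         class = character(), image_size) {
  stopifnot(length(x) == length(y), length(x) == length(class),
            length(image_size) == 2)
  if (length(x)) {
    stopifnot(all(class %in% KEYPOINT_CLASSES),
              all(x >= 0), all(x < image_size[2]),
              all(y >= 0), all(y < image_size[1]))
    if (anyDuplicated(paste(x, y, class))) {
      stop("duplicate (x, y, class) keypoints")
    }
  }
  structure(data.frame(x = as.numeric(x), y = as.numeric(y),
                       class = as.character(class),
                       stringsAsFactors = FALSE),
            image_size = as.integer(image_size),
            class = c("keypoint_set", "data.frame"))
}

image_size_of <- function(kps) attr(kps, "image_size")

#' @export
print.keypoint_set <- function(x, ...) {
  sz <- image_size_of(x)
  cat(sprintf("<keypoint_set: %d points (%d crossover, %d bifurcation), image %dx%d>\n",
              nrow(x), sum(x$class == "crossover"),
              sum(x$class == "bifurcation"), sz[1], sz[2]))
  invisible(x)
}

#' Read / write keypoint CSV files
#'
#' The on-disk format is a CSV with header `x,y,class`, coordinates 0-based.
#'
#' @param kps a [keypoint_set()].
#' @param path file path.
#' @param image_size c(H, W), required when reading.
#' @export
write_keypoints <- function(kps, path) {
  write.csv(as.data.frame(kps)[, c("x", "y", "class")], path,
            row.names = FALSE, quote = FALSE)
}

#' @rdname write_keypoints
#' @export
read_keypoints <- function(path, image_size) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  keypoint_set(d$x, d$y, d$class, image_size)
}

# Transform keypoint coordinates through a homography, keeping labels.
transform_keypoints <- function(kps, h, image_size = image_size_of(kps)) {
  if (!nrow(kps)) return(keypoint_set(image_size = image_size))
  p <- apply_homography(h, cbind(kps$x, kps$y))
  keep <- is.finite(p[, 1]) & is.finite(p[, 2]) &
    p[, 1] >= 0 & p[, 1] < image_size[2] &
    p[, 2] >= 0 & p[, 2] < image_size[1]
  keypoint_set(p[keep, 1], p[keep, 2], kps$class[keep], image_size)
}
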