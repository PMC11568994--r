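# Plain-text / PNG interchange formats.

#' Read / write an RGB image as PNG
#'
#' Values are in [0, 1], array layout H x W x 3.
#' @param image array; @param path file path.
#' @export
write_image <- function(image, path) {
  png::writePNG(clamp01(image), path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Read / write a homography as a 3x3 row-major text file
#'
#' One row per line, three whitespace-separated numbers each.
#' @param h 3x3 matrix; @param path file path.
#' @export
write_homography <- function(h, path) {
  writeLines(apply(h, 1, function(r) {
    paste(formatC(r, format = "g", digits = 17), collapse = " ")
  }), path)
  invisible(path)
}

#' @rdname write_homography
#' @export
read_homography <- function(path) {
  v <- scan(path, quiet = TRUE)
  stopifnot(length(v) == 9)
  matrix(v, 3, 3, byrow = TRUE)
}

#' Write control points as CSV
#'
#' Header `x_fixed,y_fixed,x_moving,y_moving`, 0-based pixel coordinates.
#' @param cps data.frame; @param path file path.
#' @export
write_control_points <- function(cps, path) {
  write.csv(cps[, c("x_fixed", "y_fixed", "x_moving", "y_moving")], path,
            row.names = FALSE, quote = FALSE)
}

#' @rdname write_control_points
#' @export
read_control_points <- function(path) {
  read.csv(path)
}

#' Write match set as CSV
#'
#' Columns `x_f,y_f,x_m,y_m,class,similarity,inlier`.
#' @param m a `match_set`; @param inliers logical vector; @param path file.
#' @export
write_matches <- function(m, inliers, path) {
  write.csv(data.frame(x_f = m$x_fixed, y_f = m$y_fixed, x_m = m$x_moving,
                       y_m = m$y_moving, class = m$class,
                       similarity = m$similarity, inlier = inliers),
            path, row.names = FALSE, quote = FALSE)
}
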