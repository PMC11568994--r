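# HSV colour jitter on [0,1] RGB arrays.

rgb_to_hsv_mat <- function(img) {
  d <- dim(img)
  m <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
             as.vector(img[, , 3]))
  grDevices::rgb2hsv(m, maxColorValue = 1)
}

hsv_to_rgb_array <- function(hsv, d) {
  h <- hsv[1, ] * 6
  s <- hsv[2, ]
  v <- hsv[3, ]
  i <- as.integer(floor(h) %% 6)
  f <- h - floor(h)
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  # per-sextant channel sources, selected by index arithmetic
  rm <- cbind(v, q, p, p, t, v)
  gm <- cbind(t, v, v, q, p, p)
  bm <- cbind(p, p, t, v, v, q)
  sel <- cbind(seq_along(i), i + 1L)
  array(c(rm[sel], gm[sel], bm[sel]), d)
}

# Shift hue (wrapping), saturation and value (clamped) by `delta` = c(dh, ds, dv).
shift_hsv <- function(img, delta) {
  array(cpp_hsv_shift(img, delta[1], delta[2], delta[3]), dim(img))
}

# Pure-R reference used in tests against the C++ kernel.
shift_hsv_ref <- function(img, delta) {
  d <- dim(img)
  hsv <- rgb_to_hsv_mat(img)
  hsv[1, ] <- (hsv[1, ] + delta[1]) %% 1
  hsv[2, ] <- clamp01(hsv[2, ] + delta[2])
  hsv[3, ] <- clamp01(hsv[3, ] + delta[3])
  hsv_to_rgb_array(hsv, d)
}
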