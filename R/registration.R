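# Matching and transform estimation: bidirectional per-class descriptor
# matching, coordinate rescaling between resolutions, and RANSAC homography
# estimation over normalized DLT solutions.

#' Mutual (bidirectional) per-class descriptor matching
#'
#' Matching is restricted to keypoints of the same class (crossovers with
#' crossovers, bifurcations with bifurcations).  Within each class, the pair
#' (a, b) is kept iff b is the most similar moving descriptor to a AND a is
#' the most similar fixed descriptor to b; ties resolve to the lowest index,
#' making the matching deterministic.
#'
#' @param desc_fixed,desc_moving `descriptor_set`s from
#'   [sample_descriptors()].
#' @param resolution c(H, W) the coordinates are expressed in (optional,
#'   carried along for rescaling).
#' @return a `match_set`: data.frame with columns `index_fixed`,
#'   `index_moving` (1-based into the descriptor sets), `class`,
#'   `similarity`, plus coordinate columns `x_fixed`, `y_fixed`, `x_moving`,
#'   `y_moving`.
#' @export
mutual_match <- function(desc_fixed, desc_moving, resolution = NULL) {
  out <- NULL
  for (cl in KEYPOINT_CLASSES) {
    fi <- which(desc_fixed$class == cl)
    mi <- which(desc_moving$class == cl)
    if (!length(fi) || !length(mi)) next
    S <- desc_fixed$desc[fi, , drop = FALSE] %*%
      t(desc_moving$desc[mi, , drop = FALSE])
    best_m <- apply(S, 1, which.max)     # ties: first (lowest) index
    best_f <- apply(S, 2, which.max)
    keep <- which(best_f[best_m] == seq_along(fi))
    if (length(keep)) {
      out <- rbind(out, data.frame(
        index_fixed = fi[keep], index_moving = mi[best_m[keep]],
        class = cl,
        similarity = S[cbind(keep, best_m[keep])],
        x_fixed = desc_fixed$x[fi[keep]], y_fixed = desc_fixed$y[fi[keep]],
        x_moving = desc_moving$x[mi[best_m[keep]]],
        y_moving = desc_moving$y[mi[best_m[keep]]],
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    out <- data.frame(index_fixed = integer(0), index_moving = integer(0),
                      class = character(0), similarity = numeric(0),
                      x_fixed = numeric(0), y_fixed = numeric(0),
                      x_moving = numeric(0), y_moving = numeric(0))
  }
  structure(out, resolution = resolution, class = c("match_set",
                                                    "data.frame"))
}

#' Rescale match coordinates between resolutions
#'
#' x is scaled by `W_to / W_from` and y by `H_to / H_from`, per image
#' independently (e.g. from the detection resolution up to the evaluation
#' resolution); indices and similarities are unchanged.
#'
#' @param m a `match_set`.
#' @param from_size,to_size c(H, W) source and target sizes (used for both
#'   images); `from_size_moving`/`to_size_moving` override the moving side.
#' @return the rescaled `match_set`.
#' @export
rescale_matches <- function(m, from_size, to_size,
                            from_size_moving = from_size,
                            to_size_moving = to_size) {
  stopifnot(all(from_size > 0), all(to_size > 0))
  m$x_fixed <- m$x_fixed * to_size[2] / from_size[2]
  m$y_fixed <- m$y_fixed * to_size[1] / from_size[1]
  m$x_moving <- m$x_moving * to_size_moving[2] / from_size_moving[2]
  m$y_moving <- m$y_moving * to_size_moving[1] / from_size_moving[1]
  attr(m, "resolution") <- to_size
  m
}

#' RANSAC configuration
#'
#' @param inlier_threshold reprojection inlier threshold, pixels (measured
#'   one way: fixed points mapped into the moving frame).
#' @param max_iter randomized-mode iteration budget.
#' @param confidence early-stop confidence for the randomized mode.
#' @param exhaustive evaluate all C(M, 4) minimal samples instead of random
#'   ones.
#' @param refit refit the best consensus set by least squares.
#' @return an object of class `ransac_config`.
#' @export
ransac_config <- function(inlier_threshold = 5, max_iter = 10000,
                          confidence = 0.999, exhaustive = FALSE,
                          refit = TRUE) {
  stopifnot(inlier_threshold > 0, max_iter >= 1)
  structure(list(inlier_threshold = inlier_threshold, max_iter = max_iter,
                 confidence = confidence, exhaustive = exhaustive,
                 refit = refit),
            class = "ransac_config")
}

#' Estimate a projective transform from matches with RANSAC
#'
#' Minimal 4-point samples are solved by the normalized direct linear
#' transform; the consensus set is the matches whose one-way reprojection
#' error is below the inlier threshold.  In exhaustive mode every C(M, 4)
#' minimal sample is evaluated; in randomized mode samples are drawn until
#' the confidence criterion or the iteration budget is reached.  The best
#' consensus is refit by least-squares DLT on all inliers.  Degenerate
#' (collinear) samples are skipped.
#'
#' @param m a `match_set` (or a data.frame with `x_fixed`, `y_fixed`,
#'   `x_moving`, `y_moving`), at least 4 rows.
#' @param cfg a [ransac_config()].
#' @return list with `h` (3x3 scale-normalized homography, fixed -> moving),
#'   `inliers` (logical), `n_samples` evaluated.
#' @export
estimate_homography <- function(m, cfg = ransac_config()) {
  M <- nrow(m)
  if (M < 4) {
    stopf("fundusreg_insufficient_matches",
          "homography estimation needs >= 4 matches, got %d", M)
  }
  src <- cbind(m$x_fixed, m$y_fixed)
  dst <- cbind(m$x_moving, m$y_moving)
  n_all <- choose(M, 4)
  best <- NULL
  n_done <- 0
  if (cfg$exhaustive || n_all <= cfg$max_iter) {
    samples <- t(combn(M, 4)) - 1L
    best <- cpp_ransac(src, dst, samples, cfg$inlier_threshold)
    n_done <- nrow(samples)
  } else {
    needed <- cfg$max_iter
    chunk <- 500L
    while (n_done < min(needed, cfg$max_iter)) {
      nb <- min(chunk, cfg$max_iter - n_done)
      samples <- matrix(0L, nb, 4)
      for (i in seq_len(nb)) samples[i, ] <- sample.int(M, 4) - 1L
      cand <- cpp_ransac(src, dst, samples, cfg$inlier_threshold)
      n_done <- n_done + nb
      if (is.null(best) || cand$count > best$count) best <- cand
      w <- max(best$count, 1) / M
      needed <- if (w >= 1) n_done else {
        log(1 - cfg$confidence) / log(1 - w^4)
      }
    }
  }
  if (is.null(best) || best$count < 4 || !length(best$H)) {
    stopf("fundusreg_insufficient_matches",
          "RANSAC found no valid consensus (best count %d)",
          if (is.null(best)) 0L else best$count)
  }
  h <- best$H
  inl <- as.logical(best$inliers)
  if (cfg$refit && sum(inl) >= 4) {
    h2 <- cpp_dlt(src[inl, , drop = FALSE], dst[inl, , drop = FALSE])
    if (length(h2) && all(is.finite(h2))) {
      e2 <- cpp_reproj_errors(h2, src, dst)
      inl2 <- e2 < cfg$inlier_threshold
      if (sum(inl2) >= sum(inl)) {
        h <- h2
        inl <- inl2
      }
    }
  }
  list(h = normalize_homography(h), inliers = inl, n_samples = n_done)
}

#' Number of descriptor comparisons for a pair
#'
#' The matching stage compares every fixed descriptor with every moving one,
#' so its complexity is O(n^2): `k_fixed * k_moving` comparisons.
#' @param k_fixed,k_moving keypoint counts, >= 0.
#' @return the comparison count.
#' @export
comparison_count <- function(k_fixed, k_moving) {
  stopifnot(k_fixed >= 0, k_moving >= 0)
  k_fixed * k_moving
}

#' Register an image pair end to end
#'
#' Detect -> describe -> sample descriptors -> mutual per-class match ->
#' (optional rescale) -> RANSAC homography.  Per-stage counts and timings
#' are recorded in the result.
#'
#' @param fixed,moving H x W x 3 arrays.
#' @param detector a trained `detector_model`.
#' @param descriptor a trained `descriptor_model`.
#' @param threshold,window detector extraction parameters.
#' @param ransac a [ransac_config()].
#' @param eval_size optional c(H, W): rescale match coordinates to this
#'   resolution before estimating the transform.
#' @param lenient if TRUE, failures return a structured failure record
#'   (`success = FALSE`) instead of raising.
#' @return a `registration_result`: list with `success`, `h`, `matches`,
#'   `inliers`, `counts`, `timings` (seconds) and, on failure, `reason`.
#' @export
register_pair <- function(fixed, moving, detector, descriptor,
                          threshold = 0.35, window = 7,
                          ransac = ransac_config(), eval_size = NULL,
                          lenient = FALSE) {
  tic <- function() Sys.time()
  el <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))
  run <- function() {
    t0 <- tic()
    kf <- detect(detector, fixed, threshold, window)
    km <- detect(detector, moving, threshold, window)
    t_detect <- el(t0)
    t0 <- tic()
    df <- sample_descriptors(describe(descriptor, fixed), kf)
    dm <- sample_descriptors(describe(descriptor, moving), km)
    t_desc <- el(t0)
    t0 <- tic()
    mm <- mutual_match(df, dm, resolution = dim(fixed)[1:2])
    t_match <- el(t0)
    if (!is.null(eval_size)) {
      mm <- rescale_matches(mm, dim(fixed)[1:2], eval_size,
                            dim(moving)[1:2], eval_size)
    }
    t0 <- tic()
    est <- estimate_homography(mm, ransac)
    t_ransac <- el(t0)
    structure(list(
      success = TRUE, h = est$h, matches = mm, inliers = est$inliers,
      counts = list(keypoints_fixed = nrow(kf), keypoints_moving = nrow(km),
                    comparisons = comparison_count(nrow(kf), nrow(km)),
                    matches = nrow(mm), inliers = sum(est$inliers)),
      timings = list(detect = t_detect, describe = t_desc,
                     match = t_match, ransac = t_ransac)
    ), class = "registration_result")
  }
  if (lenient) {
    tryCatch(run(), error = function(e) {
      structure(list(success = FALSE, reason = conditionMessage(e)),
                class = "registration_result")
    })
  } else {
    run()
  }
}
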