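# Seeded synthetic fundus scenes: dark branching vessel trees over a bright
# textured disc, with exact ground truth for vessel bifurcations (branch
# points within a tree) and crossovers (intersections between trees), plus
# registration pairs related by a known projective transform.
#
# The generator emulates the geometry of fundus photographs far enough to
# exercise detection, description, matching and evaluation end to end; it is
# not a photorealistic retina model.

#' Generate a synthetic fundus scene
#'
#' Draws `n_trees` vessel trees of cubic Bezier segments on a bright textured
#' circular disc.  Each tree undergoes `n_branch_events` branch events; every
#' branch event endpoint is a ground-truth bifurcation, and every crossing
#' between two different trees is a ground-truth crossover.  Keypoints closer
#' than 6 px are merged (first-listed point kept) and points within 6 px of
#' the disc border are dropped, so the ground truth stays recoverable by a
#' local-maxima detector.
#'
#' @param seed integer; the scene is a pure function of its arguments.
#' @param size side length in pixels (square image), >= 128.
#' @param n_trees number of vessel trees, >= 0.
#' @param n_branch_events branch events per tree, >= 0.
#' @return a `synthetic_scene`: list with `image` (H x W x 3, values [0, 1]),
#'   `keypoints` (a [keypoint_set()]), `vessel_mask` (H x W logical),
#'   `background` (the scene before vessels were drawn), `centerlines`
#'   (per-branch centreline samples), `disc` (centre and radius) and `seed`.
#' @export
generate_scene <- function(seed, size = 256, n_trees = 2,
                           n_branch_events = 5) {
  if (size < 128) {
    stopf("fundusreg_invalid_argument",
          "size %d too small to place the fundus disc (need >= 128)", size)
  }
  stopifnot(n_trees >= 0, n_branch_events >= 0)
  with_seed(seed, {
    H <- W <- as.integer(size)
    ctr <- c((W - 1) / 2, (H - 1) / 2)
    R <- 0.47 * size

    bg <- render_background(H, W, ctr, R)
    trees <- lapply(seq_len(n_trees), function(t) {
      grow_tree(t, n_trees, ctr, R, size, n_branch_events)
    })

    branches <- do.call(c, lapply(trees, `[[`, "branches")) %||% list()
    bif_raw <- do.call(rbind, lapply(trees, `[[`, "bifurcations"))
    if (is.null(bif_raw)) bif_raw <- matrix(numeric(), ncol = 2)
    cross_raw <- find_crossovers(branches)

    samples <- do.call(rbind, lapply(branches, function(b) {
      cbind(b$samples, b$halfwidth)
    }))
    vessel <- if (is.null(samples) || !nrow(samples)) {
      matrix(0, H, W)
    } else {
      cpp_render_strokes(H, W, samples)
    }
    vessel <- vessel * disc_mask(H, W, ctr, R)  # vessels live on the disc

    img <- bg
    vcol <- c(0.42, 0.10, 0.08)
    alpha <- 0.85 * vessel
    for (c in 1:3) img[, , c] <- img[, , c] * (1 - alpha) + vcol[c] * alpha

    kp <- label_keypoints(bif_raw, cross_raw, ctr, R, c(H, W))
    structure(list(
      image = clamp01(img),
      keypoints = kp,
      vessel_mask = vessel > 0.5,
      background = clamp01(bg),
      centerlines = branches,
      bifurcations_raw = bif_raw,
      crossovers_raw = cross_raw,
      disc = list(center = ctr, radius = R),
      seed = as.integer(seed)
    ), class = "synthetic_scene")
  })
}

disc_mask <- function(H, W, ctr, R) {
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  clamp01(R - 2 - sqrt((xs - ctr[1])^2 + (ys - ctr[2])^2))
}

render_background <- function(H, W, ctr, R) {
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  d <- sqrt((xs - ctr[1])^2 + (ys - ctr[2])^2)
  disc <- clamp01(R - d)                       # anti-aliased disc edge
  vign <- 1 - 0.30 * (d / R)^2
  coarse <- function(n, amp) {
    g <- array(runif(n * n, -1, 1), c(n, n, 1))
    s <- affine_matrix(scale = (max(H, W) - 1) / (n - 1))
    amp * warp_image(g, s, c(H, W))[, , 1]
  }
  tex <- coarse(9, 0.05) + coarse(17, 0.025)
  base <- c(0.86, 0.52, 0.30)
  chan_w <- c(1.0, 0.85, 0.6)
  img <- array(0, c(H, W, 3))
  for (c in 1:3) {
    inside <- (base[c] + chan_w[c] * tex) * vign
    img[, , c] <- disc * inside + (1 - disc) * 0.05
  }
  img
}

# One vessel tree: a FIFO queue of growing tips; each branch event extends
# the oldest tip by one Bezier segment and splits it in two, so the tree
# stays balanced and every event endpoint has vessel degree 3.
grow_tree <- function(t, n_trees, ctr, R, size, n_events) {
  phi <- 2 * pi * (t - 1) / max(1, n_trees) + runif(1, -0.35, 0.35)
  pos <- ctr + 0.88 * R * c(cos(phi), sin(phi))
  dir <- rot2(norm2(ctr - pos), runif(1, -0.35, 0.35))
  tips <- list(list(pos = pos, dir = dir, w = runif(1, 4.6, 5.4)))
  branches <- list()
  bifs <- NULL
  for (e in seq_len(n_events)) {
    tip <- tips[[1]]; tips <- tips[-1]
    seg <- bezier_branch(tip, ctr, R, size)
    branches[[length(branches) + 1]] <- seg
    bifs <- rbind(bifs, seg$end)
    for (s in c(-1, 1)) {
      ang <- s * runif(1, 0.28, 0.65)
      tips[[length(tips) + 1]] <- list(
        pos = seg$end, dir = rot2(seg$end_dir, ang),
        w = max(2, tip$w * 0.78))
    }
  }
  for (tip in tips) {                          # terminal segments
    seg <- bezier_branch(tip, ctr, R, size, terminal = TRUE)
    branches[[length(branches) + 1]] <- seg
  }
  for (i in seq_along(branches)) branches[[i]]$tree <- t
  list(branches = branches, bifurcations = bifs)
}

norm2 <- function(v) v / sqrt(sum(v^2))
rot2 <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                         sin(a) * v[1] + cos(a) * v[2])

bezier_branch <- function(tip, ctr, R, size, terminal = FALSE) {
  len <- runif(1, 0.16, 0.26) * size * if (terminal) 0.7 else 1
  dir <- tip$dir
  # steer back towards the disc centre when the endpoint would leave it
  endp <- tip$pos + dir * len
  if (sqrt(sum((endp - ctr)^2)) > 0.8 * R) {
    dir <- norm2(0.45 * dir + 0.55 * norm2(ctr - tip$pos))
    endp <- tip$pos + dir * len
    if (sqrt(sum((endp - ctr)^2)) > 0.85 * R) len <- len * 0.6
  }
  perp <- c(-dir[2], dir[1])
  j1 <- runif(1, -0.12, 0.12) * len
  j2 <- runif(1, -0.12, 0.12) * len
  p0 <- tip$pos
  p1 <- p0 + dir * len / 3 + perp * j1
  p2 <- p0 + dir * 2 * len / 3 + perp * j2
  p3 <- p0 + dir * len
  tt <- seq(0, 1, length.out = max(10, ceiling(len / 0.6)))
  bx <- (1 - tt)^3 * p0[1] + 3 * (1 - tt)^2 * tt * p1[1] +
    3 * (1 - tt) * tt^2 * p2[1] + tt^3 * p3[1]
  by <- (1 - tt)^3 * p0[2] + 3 * (1 - tt)^2 * tt * p1[2] +
    3 * (1 - tt) * tt^2 * p2[2] + tt^3 * p3[2]
  hw <- tip$w / 2 * (1 - 0.15 * tt)            # width tapers along the branch
  list(samples = cbind(bx, by), halfwidth = hw,
       start = p0, end = p3, end_dir = norm2(p3 - p2))
}

# Crossovers: close approaches between centreline samples of different trees,
# clustered so one crossing yields one keypoint.
find_crossovers <- function(branches) {
  if (!length(branches)) return(matrix(numeric(), ncol = 2))
  trees <- vapply(branches, `[[`, 1, "tree")
  hits <- NULL
  for (a in seq_along(branches)) {
    for (b in seq_along(branches)) {
      if (b <= a || trees[a] == trees[b]) next
      pa <- branches[[a]]$samples; pb <- branches[[b]]$samples
      d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
      idx <- which(d2 < 1.0, arr.ind = TRUE)
      if (nrow(idx)) {
        hits <- rbind(hits, (pa[idx[, 1], , drop = FALSE] +
                               pb[idx[, 2], , drop = FALSE]) / 2)
      }
    }
  }
  if (is.null(hits)) return(matrix(numeric(), ncol = 2))
  cluster_points(hits, 4)
}

cluster_points <- function(pts, radius) {
  kept <- NULL
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    if (is.null(kept)) { kept <- matrix(p, 1); members <- list(p); next }
    d <- sqrt((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2)
    j <- which(d < radius)
    if (length(j)) {
      j <- j[1]
      members[[j]] <- rbind(members[[j]], p)
      kept[j, ] <- colMeans(members[[j]])
    } else {
      kept <- rbind(kept, p)
      members[[length(members) + 1]] <- matrix(p, 1)
    }
  }
  kept
}

label_keypoints <- function(bif, cross, ctr, R, image_size, min_sep = 6) {
  pts <- rbind(
    if (nrow(bif)) cbind(bif, 2) else NULL,      # 2 = bifurcation
    if (nrow(cross)) cbind(cross, 1) else NULL)  # 1 = crossover
  if (is.null(pts) || !nrow(pts)) return(keypoint_set(image_size = image_size))
  d <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  pts <- pts[d < R - min_sep, , drop = FALSE]
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (!keep[i]) next
    if (i < nrow(pts)) {
      later <- (i + 1):nrow(pts)
      dd <- sqrt((pts[later, 1] - pts[i, 1])^2 +
                   (pts[later, 2] - pts[i, 2])^2)
      keep[later][dd < min_sep] <- FALSE         # merge: keep first listed
    }
  }
  pts <- pts[keep, , drop = FALSE]
  keypoint_set(pts[, 1], pts[, 2],
               c("crossover", "bifurcation")[pts[, 3]], image_size)
}

#' Photometric corruption parameters for registration fixtures
#'
#' @param hsv maximum absolute HSV shifts (hue, saturation, value).
#' @param blur range of the Gaussian blur standard deviation, pixels.
#' @param halo maximum amplitude of the multiplicative illumination halo.
#' @return an object of class `photometric_params`; pass `NULL` to
#'   [generate_pair()] for no corruption.
#' @export
photometric_params <- function(hsv = c(0.015, 0.10, 0.10),
                               blur = c(0.4, 0.9), halo = 0.18) {
  structure(list(hsv = hsv, blur = blur, halo = halo),
            class = "photometric_params")
}

#' Default transform ranges for a fixture category
#'
#' Category S pairs keep high overlap, category P pairs are displaced by up
#' to 0.30 x image size so the overlap drops, and category A uses the S
#' geometry but additionally erases vessel segments in the moving image
#' (emulating keypoints vanishing under pathology progression).
#' @param category one of "S", "P", "A".
#' @return an [affine_ranges()] with a perspective component.
#' @export
pair_ranges <- function(category = c("S", "P", "A")) {
  category <- match.arg(category)
  switch(category,
    S = affine_ranges(rotation = 12, translation = 0.06,
                      scale = c(0.95, 1.05), shear = 4, perspective = 0.08),
    P = affine_ranges(rotation = 18, translation = 0.30,
                      scale = c(0.90, 1.10), shear = 6, perspective = 0.12),
    A = affine_ranges(rotation = 12, translation = 0.06,
                      scale = c(0.95, 1.05), shear = 4, perspective = 0.08))
}

#' Generate a registration pair fixture from a scene
#'
#' The moving image is the scene warped by a random projective transform
#' `h_true` (drawn from `transform_ranges`) and then photometrically
#' corrupted (illumination halo, Gaussian blur, HSV shift).  Ten control
#' points are sampled on vessel centrelines inside the overlap; their moving
#' coordinates are the exact images of the fixed ones under `h_true`.
#' Category "A" fixtures additionally erase a random subset of vessel
#' segments in the moving image.
#'
#' @param scene a [generate_scene()] result.
#' @param seed integer seed for the transform, corruption and control points.
#' @param transform_ranges an [affine_ranges()]; defaults to
#'   [pair_ranges()] for `category`.
#' @param photometric a [photometric_params()] or `NULL` for none.
#' @param category fixture category tag: "S", "P" or "A".
#' @param n_control number of control points (default 10).
#' @return a `registration_pair`: list with `fixed`, `moving`, `h_true`
#'   (fixed -> moving), `control_points` (data.frame
#'   `x_fixed,y_fixed,x_moving,y_moving`), `overlap_fraction`, `category`
#'   and `seed`.
#' @export
generate_pair <- function(scene, seed, transform_ranges = NULL,
                          photometric = photometric_params(),
                          category = c("S", "P", "A"), n_control = 10) {
  stopifnot(inherits(scene, "synthetic_scene"))
  category <- match.arg(category)
  ranges <- transform_ranges %||% pair_ranges(category)
  sz <- dim(scene$image)[1:2]
  with_seed(seed, {
    af <- sample_affine(ranges, sz)
    h_true <- af$matrix
    if (ranges$perspective > 0) {
      h_true[3, 1:2] <- runif(2, -ranges$perspective, ranges$perspective) /
        max(sz)
    }
    h_true <- normalize_homography(h_true)

    moving <- warp_image(scene$image, h_true, sz, fill = 0.05)

    if (category == "A" && length(scene$centerlines)) {
      nb <- length(scene$centerlines)
      erase <- which(runif(nb) < 0.3)
      if (!length(erase)) erase <- sample.int(nb, 1)
      sm <- do.call(rbind, lapply(scene$centerlines[erase], function(b) {
        cbind(b$samples, b$halfwidth + 0.5)
      }))
      mask_f <- cpp_render_strokes(sz[1], sz[2], sm)
      mask_m <- warp_image(array(mask_f, c(sz, 1)), h_true, sz, 0)[, , 1]
      bg_m <- warp_image(scene$background, h_true, sz, fill = 0.05)
      a <- clamp01(mask_m)
      for (c in 1:3) {
        moving[, , c] <- moving[, , c] * (1 - a) + bg_m[, , c] * a
      }
    }

    cps <- sample_control_points(scene, h_true, sz, n_control)
    if (!is.null(photometric)) {
      moving <- corrupt_photometric(moving, photometric, sz)
    }

    structure(list(
      fixed = scene$image, moving = clamp01(moving), h_true = h_true,
      control_points = cps,
      overlap_fraction = overlap_fraction(h_true, sz),
      category = category, seed = as.integer(seed), scene = scene
    ), class = "registration_pair")
  })
}

sample_control_points <- function(scene, h, sz, n_control) {
  pool <- do.call(rbind, lapply(scene$centerlines, `[[`, "samples"))
  if (is.null(pool) || !nrow(pool)) {
    stopf("fundusreg_retry_exhausted",
          "scene has no vessel centrelines to place control points on")
  }
  q <- apply_homography(h, pool)
  m <- 5
  ok <- pool[, 1] >= m & pool[, 1] <= sz[2] - 1 - m &
    pool[, 2] >= m & pool[, 2] <= sz[1] - 1 - m &
    is.finite(q[, 1]) & q[, 1] >= m & q[, 1] <= sz[2] - 1 - m &
    is.finite(q[, 2]) & q[, 2] >= m & q[, 2] <= sz[1] - 1 - m
  pool <- pool[ok, , drop = FALSE]
  sep <- 0.07 * max(sz)
  for (try in 1:20) {
    ord <- sample.int(nrow(pool))
    sel <- integer(0)
    for (i in ord) {
      if (!length(sel)) { sel <- i; next }
      d <- sqrt((pool[sel, 1] - pool[i, 1])^2 + (pool[sel, 2] - pool[i, 2])^2)
      if (all(d >= sep)) sel <- c(sel, i)
      if (length(sel) == n_control) break
    }
    if (length(sel) == n_control) {
      p <- pool[sel, , drop = FALSE]
      pm <- apply_homography(h, p)
      return(data.frame(x_fixed = p[, 1], y_fixed = p[, 2],
                        x_moving = pm[, 1], y_moving = pm[, 2]))
    }
    sep <- sep * 0.8
  }
  stopf("fundusreg_retry_exhausted",
        "could not place %d control points inside the overlap", n_control)
}

corrupt_photometric <- function(img, p, sz) {
  stopifnot(inherits(p, "photometric_params"))
  # multiplicative illumination halo at a random centre
  a <- runif(1, -p$halo * 0.8, p$halo)
  cx <- runif(1, 0.2, 0.8) * sz[2]
  cy <- runif(1, 0.2, 0.8) * sz[1]
  s <- runif(1, 0.35, 0.6) * max(sz)
  xs <- matrix(rep(0:(sz[2] - 1), each = sz[1]), sz[1], sz[2])
  ys <- matrix(rep(0:(sz[1] - 1), sz[2]), sz[1], sz[2])
  halo <- 1 + a * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * s^2))
  for (c in 1:3) img[, , c] <- img[, , c] * halo
  # slight defocus blur
  sigma <- runif(1, p$blur[1], p$blur[2])
  r <- max(1, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  img <- array(cpp_sepconv(img, k), dim(img))
  # global HSV shift
  shift_hsv(clamp01(img), runif(3, -1, 1) * p$hsv)
}

overlap_fraction <- function(h, sz, n_grid = 96) {
  gx <- seq(0, sz[2] - 1, length.out = n_grid)
  gy <- seq(0, sz[1] - 1, length.out = n_grid)
  pts <- cbind(rep(gx, each = n_grid), rep(gy, n_grid))
  q <- apply_homography(h, pts)
  mean(is.finite(q[, 1]) & is.finite(q[, 2]) &
         q[, 1] >= 0 & q[, 1] <= sz[2] - 1 &
         q[, 2] >= 0 & q[, 2] <= sz[1] - 1)
}

#' Write a scene or pair fixture to disk
#'
#' Images go out as PNG, keypoints as `x,y,class` CSV, control points as
#' `x_fixed,y_fixed,x_moving,y_moving` CSV and the true homography as a
#' 3x3 row-major text file.
#' @param scene a `synthetic_scene`; @param pair a `registration_pair`;
#' @param dir output directory; @param prefix filename prefix.
#' @export
write_scene <- function(scene, dir, prefix = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  png::writePNG(scene$image, file.path(dir, paste0(prefix, ".png")))
  write_keypoints(scene$keypoints, file.path(dir, paste0(prefix, "_keypoints.csv")))
  invisible(dir)
}

#' @rdname write_scene
#' @export
write_pair <- function(pair, dir, prefix = "pair") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  png::writePNG(pair$fixed, file.path(dir, paste0(prefix, "_fixed.png")))
  png::writePNG(pair$moving, file.path(dir, paste0(prefix, "_moving.png")))
  write.csv(pair$control_points,
            file.path(dir, paste0(prefix, "_controlpoints.csv")),
            row.names = FALSE, quote = FALSE)
  write_homography(pair$h_true, file.path(dir, paste0(prefix, "_h_true.txt")))
  invisible(dir)
}
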