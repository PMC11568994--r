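# Synthetic fundus scenes and registration pair fixtures.

test_that("scene generation is deterministic and validates arguments", {
  s1 <- generate_scene(7, 256, 2, 5)
  s2 <- generate_scene(7, 256, 2, 5)
  expect_identical(s1$image, s2$image)
  expect_identical(as.data.frame(s1$keypoints), as.data.frame(s2$keypoints))
  expect_error(generate_scene(7, 64), class = "fundusreg_invalid_argument")
})

test_that("a single unbranched tree yields no keypoints", {
  s <- generate_scene(7, 256, n_trees = 1, n_branch_events = 0)
  expect_equal(nrow(s$keypoints), 0L)
})

test_that("scene invariants: keypoints inside the disc, bifurcations on vessels", {
  for (seed in c(3, 11, 29)) {
    s <- generate_scene(seed, 256, 2, 4)
    kp <- s$keypoints
    d <- sqrt((kp$x - s$disc$center[1])^2 + (kp$y - s$disc$center[2])^2)
    expect_true(all(d < s$disc$radius))
    bif <- kp[kp$class == "bifurcation", ]
    on_mask <- mapply(function(x, y) {
      s$vessel_mask[round(y) + 1, round(x) + 1]
    }, bif$x, bif$y)
    expect_true(all(on_mask))
    # minimum separation after merging
    if (nrow(kp) > 1) {
      dm <- as.matrix(dist(cbind(kp$x, kp$y)))
      diag(dm) <- Inf
      expect_gte(min(dm), 6)
    }
  }
})

test_that("bifurcation count matches a re-trace of the centreline graph", {
  s <- generate_scene(3, 256, 2, 4)
  # oracle: rebuild the junction set from the rendered centrelines alone --
  # a junction is a point where >= 3 branch endpoints/starts coincide
  ends <- do.call(rbind, lapply(s$centerlines, function(b) {
    rbind(b$samples[1, ], b$samples[nrow(b$samples), ])
  }))
  # count points where 3 segments meet (1 parent end + 2 child starts)
  deg3 <- 0
  seen <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(ends))) {
    p <- ends[i, ]
    if (nrow(seen) && any(sqrt((seen[, 1] - p[1])^2 +
                               (seen[, 2] - p[2])^2) < 1e-6)) next
    seen <- rbind(seen, p)
    mult <- sum(sqrt((ends[, 1] - p[1])^2 + (ends[, 2] - p[2])^2) < 1e-6)
    if (mult >= 3) deg3 <- deg3 + 1
  }
  # 2 trees x 4 events = 8 junction points in the rendered geometry
  expect_equal(deg3, 8)
  # labelled bifurcations = junctions minus those merged or outside the disc
  n_bif <- sum(s$keypoints$class == "bifurcation")
  expect_lte(n_bif, deg3)
  expect_gte(n_bif, deg3 - 4)   # at most a few merges at this density
})

test_that("identity transform with no corruption reproduces the image", {
  s <- generate_scene(5, 256, 2, 4)
  p <- generate_pair(s, 9,
                     transform_ranges = affine_ranges(0, 0, c(1, 1), 0),
                     photometric = NULL, category = "S")
  expect_equal(p$moving, p$fixed, tolerance = 1e-12)
  expect_equal(control_point_error(p$h_true, p$control_points), 0,
               tolerance = 1e-9)
})

test_that("a pure translation shifts every control point by the offset", {
  s <- generate_scene(6, 256, 2, 4)
  p <- generate_pair(s, 10,
                     transform_ranges = affine_ranges(0, 0, c(1, 1), 0),
                     photometric = NULL, category = "S")
  h <- diag(3); h[1, 3] <- 20; h[2, 3] <- -10
  p$h_true <- h   # mimic: use the helper directly on known transform
  cp <- p$control_points
  q <- apply_homography(h, cbind(cp$x_fixed, cp$y_fixed))
  expect_equal(q[, 1], cp$x_fixed + 20)
  expect_equal(q[, 2], cp$y_fixed - 10)
})

test_that("control points map exactly through h_true for random fixtures", {
  worst <- 0
  for (seed in 1:10) {
    s <- generate_scene(seed, 256, 2, 5)
    p <- generate_pair(s, seed + 100, category = sample(c("S", "P", "A"), 1))
    q <- apply_homography(p$h_true,
                          cbind(p$control_points$x_fixed,
                                p$control_points$y_fixed))
    worst <- max(worst, max(abs(q - cbind(p$control_points$x_moving,
                                          p$control_points$y_moving))))
    expect_equal(nrow(p$control_points), 10)
  }
  expect_lt(worst, 1e-9)
})

test_that("overlap fraction matches an independent finer-grid computation", {
  s <- generate_scene(8, 256, 2, 4)
  p <- generate_pair(s, 12, category = "P")
  sz <- dim(s$image)[1:2]
  gx <- seq(0, sz[2] - 1, length.out = 200)
  gy <- seq(0, sz[1] - 1, length.out = 200)
  pts <- cbind(rep(gx, each = 200), rep(gy, 200))
  q <- apply_homography(p$h_true, pts)
  frac <- mean(q[, 1] >= 0 & q[, 1] <= sz[2] - 1 &
                 q[, 2] >= 0 & q[, 2] <= sz[1] - 1)
  expect_equal(p$overlap_fraction, frac, tolerance = 0.02)
})

test_that("category P fixtures overlap less than category S on average", {
  ov <- sapply(1:20, function(i) {
    s <- generate_scene(i, 256, 2, 4)
    c(S = generate_pair(s, i + 500, category = "S")$overlap_fraction,
      P = generate_pair(s, i + 900, category = "P")$overlap_fraction)
  })
  expect_lt(mean(ov["P", ]), mean(ov["S", ]))
})

test_that("pair generation is deterministic for fixed arguments", {
  s <- generate_scene(9, 256, 2, 4)
  p1 <- generate_pair(s, 77, category = "A")
  p2 <- generate_pair(s, 77, category = "A")
  expect_identical(p1$moving, p2$moving)
  expect_identical(p1$h_true, p2$h_true)
  expect_identical(p1$control_points, p2$control_points)
})

test_that("fixture round-trips through the plain-text formats", {
  s <- generate_scene(4, 128 + 8, 2, 3)
  dir <- withr::local_tempdir()
  write_scene(s, dir, "sc")
  img <- read_image(file.path(dir, "sc.png"))
  expect_equal(dim(img), dim(s$image))
  expect_lt(max(abs(img - s$image)), 1 / 255)   # 8-bit quantization
  kp <- read_keypoints(file.path(dir, "sc_keypoints.csv"), dim(img)[1:2])
  expect_equal(as.data.frame(kp), as.data.frame(s$keypoints))
  p <- generate_pair(s, 2, category = "S")
  write_pair(p, dir, "pr")
  h <- read_homography(file.path(dir, "pr_h_true.txt"))
  expect_equal(h, p$h_true, tolerance = 1e-12)
  cps <- read_control_points(file.path(dir, "pr_controlpoints.csv"))
  expect_equal(cps, p$control_points, tolerance = 1e-12)
})
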