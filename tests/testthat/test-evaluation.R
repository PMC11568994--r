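# Registration-score metrics, category aggregation and VTKRS.

test_that("control-point error basics and loop oracle", {
  cps <- data.frame(x_fixed = c(10, 20), y_fixed = c(10, 30),
                    x_moving = c(10, 20), y_moving = c(10, 30))
  expect_equal(control_point_error(diag(3), cps), 0)
  off <- transform(cps, x_moving = x_fixed + 3, y_moving = y_fixed + 4)
  expect_equal(control_point_error(diag(3), off), 5)  # 3-4-5 triangle
  set.seed(60)
  H <- rand_homography(256)
  cps2 <- data.frame(x_fixed = runif(10, 20, 200), y_fixed = runif(10, 20, 200),
                     x_moving = runif(10, 20, 200), y_moving = runif(10, 20, 200))
  oracle <- 0
  for (i in 1:10) {
    p <- c(cps2$x_fixed[i], cps2$y_fixed[i], 1)
    q <- H %*% p; q <- q[1:2] / q[3]
    oracle <- oracle + sqrt(sum((q - c(cps2$x_moving[i], cps2$y_moving[i]))^2))
  }
  expect_equal(control_point_error(H, cps2), oracle / 10, tolerance = 1e-12)
})

test_that("a transform sending a control point to infinity is a failure", {
  H <- diag(3); H[3, ] <- c(-1 / 10, 0, 1)   # vanishing line through x = 10
  cps <- data.frame(x_fixed = 10, y_fixed = 5, x_moving = 0, y_moving = 0)
  expect_equal(control_point_error(H, cps), Inf)
})

test_that("registration score endpoints and the single-pair worked example", {
  expect_equal(registration_score(rep(0, 5))$auc, 1.0)
  expect_equal(registration_score(rep(26, 5))$auc, 0.0)
  sc <- registration_score(13)
  expect_equal(sc$success_ratio, as.numeric(sc$thresholds >= 13))
  expect_equal(sc$auc, 13 / 25)
})

test_that("success ratios are monotone and improve when errors drop", {
  set.seed(61)
  errs <- c(runif(20, 0, 30), Inf, Inf)
  sc <- registration_score(errs)
  expect_true(all(diff(sc$success_ratio) >= 0))
  better <- errs; better[1] <- 0
  sc2 <- registration_score(better)
  expect_true(all(sc2$success_ratio >= sc$success_ratio))
  expect_gte(sc2$auc, sc$auc)
})

test_that("category aggregation reproduces the weighted-average arithmetic", {
  # one pair per category with a deterministic error realizing a known AUC
  errs <- c(A = 10, P = 15, S = 5)
  out <- aggregate_by_category(unname(errs), names(errs),
                               weights = c(A = 14, P = 49, S = 71))
  expect_equal(unname(out$auc["A"]), 16 / 25)
  expect_equal(out$avg, mean(out$auc))
  expect_equal(out$w_avg,
               sum(c(14, 49, 71) * out$auc[c("A", "P", "S")]) / 134)
  # the printed-value cross-check with FIRE pair counts
  w_avg <- (14 * 0.6 + 49 * 0.4 + 71 * 0.9) / 134
  expect_equal(round(w_avg, 4), 0.6858)
  expect_equal(mean(c(0.6, 0.4, 0.9)), 0.6333, tolerance = 1e-4)
})

test_that("w_avg equals avg for equal weights; empty categories warn", {
  out <- aggregate_by_category(c(5, 6, 7), c("A", "P", "S"),
                               weights = c(A = 1, P = 1, S = 1))
  expect_equal(out$w_avg, out$avg)
  expect_warning(
    out2 <- aggregate_by_category(c(5, 6), c("A", "P")),
    "empty category")
  expect_true(is.na(out2$auc["S"]))
  expect_equal(out2$avg, mean(out2$auc[c("A", "P")]))
})

# Synthetic perfect-matching fixture: matches are exact correspondences
# under a known homography with controllable similarities.
perfect_match_set <- function(H, n_cross, n_bif, size = 256) {
  n <- n_cross + n_bif
  src <- cbind(runif(n, 20, size - 20), runif(n, 20, size - 20))
  dst <- apply_homography(H, src)
  structure(data.frame(
    index_fixed = 1:n, index_moving = 1:n,
    class = c(rep("crossover", n_cross), rep("bifurcation", n_bif)),
    similarity = runif(n, 0.8, 1),
    x_fixed = src[, 1], y_fixed = src[, 2],
    x_moving = dst[, 1], y_moving = dst[, 2]),
    class = c("match_set", "data.frame"))
}

test_that("perfect descriptors make VTKRS equal the unlimited score", {
  set.seed(62)
  pairs <- lapply(1:3, function(i) {
    H <- rand_homography(256)
    m <- perfect_match_set(H, 8, 8)
    cps <- data.frame(x_fixed = runif(10, 20, 236), y_fixed = runif(10, 20, 236))
    q <- apply_homography(H, cbind(cps$x_fixed, cps$y_fixed))
    cps$x_moving <- q[, 1]; cps$y_moving <- q[, 2]
    list(m = m, cps = cps)
  })
  v <- vtkrs_from_matches(lapply(pairs, `[[`, "m"),
                          lapply(pairs, `[[`, "cps"), n_range = 3:10)
  # noiseless exact matches: every n gives an exact fit, score 1 everywhere
  expect_true(all(abs(v$auc_per_n - 1) < 1e-12))
  unlimited <- registration_score(vapply(pairs, function(p) {
    est <- estimate_homography(p$m, ransac_config(exhaustive = TRUE))
    control_point_error(est$h, p$cps)
  }, 0))
  expect_equal(v$auc, unlimited$auc)
})

test_that("VTKRS with n covering all matches equals the unlimited score", {
  set.seed(63)
  # imperfect matches: add noise so scores differ across pairs
  pairs <- lapply(1:4, function(i) {
    H <- rand_homography(256)
    m <- perfect_match_set(H, 6, 6)
    m$x_moving <- m$x_moving + rnorm(12, 0, 2)
    m$y_moving <- m$y_moving + rnorm(12, 0, 2)
    cps <- data.frame(x_fixed = runif(10, 20, 236), y_fixed = runif(10, 20, 236))
    q <- apply_homography(H, cbind(cps$x_fixed, cps$y_fixed))
    cps$x_moving <- q[, 1]; cps$y_moving <- q[, 2]
    list(m = m, cps = cps)
  })
  # n = 6 per class exhausts every class, so the last point of the curve is
  # the unlimited registration score
  v <- vtkrs_from_matches(lapply(pairs, `[[`, "m"),
                          lapply(pairs, `[[`, "cps"), n_range = 6)
  unlimited <- registration_score(vapply(pairs, function(p) {
    est <- estimate_homography(p$m, ransac_config(exhaustive = TRUE))
    control_point_error(est$h, p$cps)
  }, 0))
  expect_equal(v$auc_per_n, unlimited$auc, tolerance = 1e-12)
})

test_that("a class with fewer matches than n contributes all it has", {
  set.seed(64)
  H <- rand_homography(256)
  m <- perfect_match_set(H, 2, 8)      # only 2 crossover matches
  cps <- data.frame(x_fixed = runif(10, 20, 236), y_fixed = runif(10, 20, 236))
  q <- apply_homography(H, cbind(cps$x_fixed, cps$y_fixed))
  cps$x_moving <- q[, 1]; cps$y_moving <- q[, 2]
  for (n in c(3, 5, 8)) {
    v <- vtkrs_from_matches(list(m), list(cps), n_range = n)
    # kept matches = min(n, 2) crossovers + min(n, 8) bifurcations
    expect_true(is.finite(v$errors[1, 1]))
  }
  # with exactly 6 kept matches the exhaustive budget is C(6,4) = 15
  m6 <- perfect_match_set(H, 3, 3)
  est <- estimate_homography(m6, ransac_config(exhaustive = TRUE))
  expect_equal(est$n_samples, choose(6, 4))
})

test_that("a pair with under 4 kept matches counts as failed at that n", {
  set.seed(65)
  H <- rand_homography(256)
  m <- perfect_match_set(H, 1, 1)      # 2 matches total
  cps <- data.frame(x_fixed = 100, y_fixed = 100,
                    x_moving = 100, y_moving = 100)
  v <- vtkrs_from_matches(list(m), list(cps), n_range = 3:5)
  expect_true(all(is.infinite(v$errors)))
  expect_equal(v$auc, 0)
})
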