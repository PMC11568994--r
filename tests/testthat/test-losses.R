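# Contrastive objectives: closed forms, brute-force oracle equivalence,
# limits, invariances and numerical stability.

test_that("cosine similarity is the dot product of unit descriptors", {
  set.seed(1)
  a <- rnorm(16); a <- a / sqrt(sum(a^2))
  expect_equal(similarity(a, a), 1.0, tolerance = 1e-12)
  b <- c(1, rep(0, 15))
  c2 <- c(0, 1, rep(0, 14))
  expect_equal(similarity(b, c2), 0.0)
  for (r in 1:10) {
    u <- rnorm(32); u <- u / sqrt(sum(u^2))
    v <- rnorm(32); v <- v / sqrt(sum(v^2))
    oracle <- 0
    for (d in seq_along(u)) oracle <- oracle + u[d] * v[d]
    expect_equal(similarity(u, v), oracle, tolerance = 1e-12)
  }
  expect_error(similarity(2 * a, a), class = "fundusreg_invalid_argument")
})

test_that("identical descriptors give the closed-form losses", {
  set.seed(2)
  # SupCon, N = 1, K = 2: every exponent equal, per-term log(K-1+NK) = log 3,
  # (N+1)*N*K = 4 terms scaled by 1/N.
  expect_equal(supcon_loss(identical_tensor(2, 2, 8)), 4 * log(3),
               tolerance = 1e-9)
  # MP-InfoNCE, K = 2, any N: per-term log(2K-1) = log 3, normalization
  # cancels the term count.
  for (V in c(2, 3, 5, 10)) {
    expect_equal(mp_infonce_loss(identical_tensor(V, 2, 8)), log(3),
                 tolerance = 1e-9)
  }
})

test_that("vectorized losses match literal nested-loop transcriptions", {
  set.seed(3)
  worst_sup <- worst_mp <- 0
  for (r in 1:110) {
    V <- sample(c(2, 3, 4, 10), 1)
    K <- sample(2:8, 1)
    t <- rand_tensor(V, K, 8)
    s1 <- supcon_loss(t); s2 <- supcon_oracle(t)
    m1 <- mp_infonce_loss(t); m2 <- mp_infonce_oracle(t)
    worst_sup <- max(worst_sup, abs(s1 - s2) / abs(s2))
    worst_mp <- max(worst_mp, abs(m1 - m2) / abs(m2))
  }
  expect_lt(worst_sup, 1e-8)
  expect_lt(worst_mp, 1e-8)
})

test_that("tau -> Inf limit sends SupCon to (N+1)*K*log(K-1+NK)", {
  set.seed(4)
  for (r in 1:5) {
    V <- sample(2:4, 1); K <- sample(2:5, 1)
    t <- rand_tensor(V, K, 8, tau = 1e8)
    N <- V - 1
    expect_equal(supcon_loss(t), (N + 1) * K * log(K - 1 + N * K),
                 tolerance = 1e-6)
  }
})

test_that("for N = 1 the per-anchor log-ratio terms of both losses agree", {
  set.seed(5)
  for (r in 1:20) {
    K <- sample(2:8, 1)
    t <- rand_tensor(2, K, 8)
    st <- supcon_terms(t)
    mt <- mp_infonce_terms(t)
    # match on (anchor view, partner view, keypoint)
    merged <- merge(st, mt, by = c("i", "j", "k"))
    expect_equal(nrow(merged), nrow(mt))
    expect_lt(max(abs(merged$term.x - merged$term.y)), 1e-10)
  }
})

test_that("losses are invariant to keypoint relabeling; SupCon to view permutation", {
  set.seed(6)
  t <- rand_tensor(4, 5, 8)
  pk <- sample(5)
  tk <- multiview_descriptor_tensor(t$z[, pk, , drop = FALSE], t$tau)
  expect_equal(supcon_loss(tk), supcon_loss(t), tolerance = 1e-10)
  expect_equal(mp_infonce_loss(tk), mp_infonce_loss(t), tolerance = 1e-10)
  # SupCon sums over ordered view pairs, so any view permutation is neutral
  pa <- sample(4)
  ta <- multiview_descriptor_tensor(t$z[pa, , , drop = FALSE], t$tau)
  expect_equal(supcon_loss(ta), supcon_loss(t), tolerance = 1e-10)
  # MP-InfoNCE anchors only the lower-indexed view of each unordered pair
  # and its denominator is anchor-specific, so reversing the view order
  # generally changes the value: the loss follows its printed form rather
  # than being view-symmetric.
  t2 <- rand_tensor(2, 4, 8)
  t2r <- multiview_descriptor_tensor(t2$z[2:1, , , drop = FALSE], t2$tau)
  expect_false(isTRUE(all.equal(mp_infonce_loss(t2), mp_infonce_loss(t2r),
                                tolerance = 1e-10)))
})

test_that("moving positives toward their anchors decreases both losses", {
  set.seed(7)
  V <- 3; K <- 4; D <- 16
  base <- rand_tensor(1, K, D)$z[1, , ]     # anchors, one per keypoint
  make <- function(alpha) {
    # each view's keypoint k descriptor = slerp-ish blend toward anchor k
    z <- array(0, c(V, K, D))
    noise <- array(rnorm(V * K * D), c(V, K, D))
    for (v in 1:V) for (k in 1:K) {
      u <- (1 - alpha) * noise[v, k, ] + alpha * base[k, ]
      z[v, k, ] <- u / sqrt(sum(u^2))
    }
    multiview_descriptor_tensor(z, 0.1)
  }
  set.seed(8); t_far <- make(0.2)
  set.seed(8); t_near <- make(0.9)
  expect_lt(supcon_loss(t_near), supcon_loss(t_far))
  expect_lt(mp_infonce_loss(t_near), mp_infonce_loss(t_far))
})

test_that("max-subtraction keeps the losses finite at tau = 0.01", {
  set.seed(9)
  t <- rand_tensor(3, 4, 8, tau = 0.01)
  expect_true(is.finite(supcon_loss(t)))
  expect_true(is.finite(mp_infonce_loss(t)))
  t2 <- identical_tensor(2, 3, 8, tau = 0.01)   # all similarities exactly 1
  expect_true(is.finite(supcon_loss(t2)))
})

test_that("K < 2 is rejected", {
  set.seed(10)
  expect_error(supcon_loss(rand_tensor(3, 1, 8)),
               class = "fundusreg_invalid_argument")
  expect_error(mp_infonce_loss(rand_tensor(3, 1, 8)),
               class = "fundusreg_invalid_argument")
})

test_that("triplet hinge evaluates as max(0, margin - s_ap + s_an)", {
  expect_equal(triplet_loss(1, 0), 0)
  expect_equal(triplet_loss(0.5, 0.5), 0.05)
  expect_equal(triplet_loss(0.2, 0.9), 0.75)
  expect_equal(triplet_loss(0.9, 0.2, margin = 0.3), 0)
})

test_that("loss gradients match central finite differences", {
  set.seed(11)
  ns <- asNamespace("fundusreg")
  t <- rand_tensor(3, 4, 6)
  eps <- 1e-6
  for (core in list(ns$supcon_core, ns$mp_infonce_core)) {
    g <- core(t, grad = TRUE)
    for (probe in 1:5) {
      i <- sample(3, 1); k <- sample(4, 1); d <- sample(6, 1)
      zp <- t$z; zp[i, k, d] <- zp[i, k, d] + eps
      zm <- t$z; zm[i, k, d] <- zm[i, k, d] - eps
      lp <- core(structure(list(z = zp, tau = t$tau),
                           class = "multiview_descriptor_tensor"))$loss
      lm <- core(structure(list(z = zm, tau = t$tau),
                           class = "multiview_descriptor_tensor"))$loss
      expect_equal(g$gZ[i, k, d], (lp - lm) / (2 * eps), tolerance = 1e-4)
    }
  }
})
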