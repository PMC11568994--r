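# Shared fixtures and small oracles, built in code at test time.

# Random unit-norm multiview descriptor tensor.
rand_tensor <- function(V, K, D, tau = 0.1) {
  z <- array(rnorm(V * K * D), c(V, K, D))
  n <- sqrt(apply(z^2, c(1, 2), sum))
  for (d in seq_len(D)) z[, , d] <- z[, , d] / n
  multiview_descriptor_tensor(z, tau)
}

# Tensor in which every descriptor is the same unit vector.
identical_tensor <- function(V, K, D, tau = 0.1) {
  v <- rnorm(D)
  v <- v / sqrt(sum(v^2))
  multiview_descriptor_tensor(
    array(rep(v, each = V * K), c(V, K, D)), tau)
}

# Literal nested-loop transcriptions of the two contrastive objectives,
# kept deliberately naive and independent of the package implementation.
supcon_oracle <- function(t) {
  z <- t$z; tau <- t$tau
  V <- dim(z)[1]; K <- dim(z)[2]; N <- V - 1
  tot <- 0
  for (i in 1:V) for (j in setdiff(1:V, i)) for (k in 1:K) {
    num <- exp(sum(z[i, k, ] * z[j, k, ]) / tau)
    den <- 0
    for (c in setdiff(1:K, k)) den <- den + exp(sum(z[i, k, ] * z[i, c, ]) / tau)
    for (l in setdiff(1:V, i)) for (c in 1:K) {
      den <- den + exp(sum(z[i, k, ] * z[l, c, ]) / tau)
    }
    tot <- tot - log(num / den)
  }
  tot / N
}

mp_infonce_oracle <- function(t) {
  z <- t$z; tau <- t$tau
  V <- dim(z)[1]; K <- dim(z)[2]
  tot <- 0
  for (i in 1:(V - 1)) for (j in (i + 1):V) for (k in 1:K) {
    num <- exp(sum(z[i, k, ] * z[j, k, ]) / tau)
    den <- 0
    for (c in setdiff(1:K, k)) den <- den + exp(sum(z[i, k, ] * z[i, c, ]) / tau)
    for (c in 1:K) den <- den + exp(sum(z[i, k, ] * z[j, c, ]) / tau)
    tot <- tot - log(num / den)
  }
  tot / (choose(V, 2) * K)
}

# Per-anchor log-ratio terms (for the N = 1 term-identity property).
supcon_terms <- function(t) {
  z <- t$z; tau <- t$tau
  V <- dim(z)[1]; K <- dim(z)[2]
  out <- NULL
  for (i in 1:V) for (j in setdiff(1:V, i)) for (k in 1:K) {
    num <- exp(sum(z[i, k, ] * z[j, k, ]) / tau)
    den <- 0
    for (c in setdiff(1:K, k)) den <- den + exp(sum(z[i, k, ] * z[i, c, ]) / tau)
    for (l in setdiff(1:V, i)) for (c in 1:K) {
      den <- den + exp(sum(z[i, k, ] * z[l, c, ]) / tau)
    }
    out <- rbind(out, data.frame(i = i, j = j, k = k,
                                 term = -log(num / den)))
  }
  out
}

mp_infonce_terms <- function(t) {
  z <- t$z; tau <- t$tau
  V <- dim(z)[1]; K <- dim(z)[2]
  out <- NULL
  for (i in 1:(V - 1)) for (j in (i + 1):V) for (k in 1:K) {
    num <- exp(sum(z[i, k, ] * z[j, k, ]) / tau)
    den <- 0
    for (c in setdiff(1:K, k)) den <- den + exp(sum(z[i, k, ] * z[i, c, ]) / tau)
    for (c in 1:K) den <- den + exp(sum(z[i, k, ] * z[j, c, ]) / tau)
    out <- rbind(out, data.frame(i = i, j = j, k = k,
                                 term = -log(num / den)))
  }
  out
}

# Exhaustive double-argmax matching oracle (single class).
mutual_match_oracle <- function(S) {
  out <- NULL
  for (a in seq_len(nrow(S))) {
    b <- which.max(S[a, ])
    if (which.max(S[, b]) == a) out <- rbind(out, c(a, b))
  }
  out
}

# Random descriptor set with unit-norm rows.
rand_descriptor_set <- function(K, D, classes = NULL) {
  M <- matrix(rnorm(K * D), K, D)
  M <- M / sqrt(rowSums(M^2))
  structure(list(desc = M,
                 class = classes %||% rep("crossover", K),
                 x = runif(K, 0, 99), y = runif(K, 0, 99)),
            class = "descriptor_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random projective transform with a controlled deviation from identity.
rand_homography <- function(size = 256, strength = 1) {
  A <- affine_matrix(rotation = runif(1, -20, 20) * strength,
                     translation = runif(2, -15, 15) * strength,
                     scale = 1 + runif(1, -0.08, 0.08) * strength,
                     shear = runif(1, -8, 8) * strength,
                     center = c(size - 1, size - 1) / 2)
  A[3, 1:2] <- runif(2, -1, 1) * 1e-4 * strength
  normalize_homography(A)
}

# Cached small trained models for the end-to-end tests (built once per run).
scene_cache <- new.env()

desk_scenes <- function(n = 12, size = 256) {
  key <- sprintf("scenes_%d_%d", n, size)
  if (is.null(scene_cache[[key]])) {
    scene_cache[[key]] <- lapply(seq_len(n), function(s) {
      generate_scene(s, size, n_trees = 4, n_branch_events = 8)
    })
  }
  scene_cache[[key]]
}

desk_detector <- function() {
  if (is.null(scene_cache$detector)) {
    scenes <- desk_scenes()
    train <- lapply(scenes[1:10], function(s) {
      list(image = s$image, heatmaps = binary_to_heatmap(s$keypoints, 3))
    })
    scene_cache$detector <- train_detector(
      train,
      detector_config(levels = 3, base = 8, crop_size = 128,
                      max_steps = 2000, val_every = 50, lr_init = 1e-3),
      seed = 1)
  }
  scene_cache$detector
}

desk_descriptor_config <- function(loss = "mp_infonce", n_views = 9,
                                   steps = 1200) {
  descriptor_config(dim = 32, widths = c(16, 16, 32, 64),
                    dilations = c(1, 2, 4, 8), loss = loss,
                    n_views = n_views, steps = steps, lr = 6e-4,
                    max_keypoints = 24)
}

# Held-out evaluation pair: the scene warped by an affine drawn from the
# descriptor-training augmentation ranges, photometrically augmented, with
# the true warp recorded.
with_warp_pair <- function(scene, seed, fn) {
  set.seed(seed)
  sz <- dim(scene$image)[1:2]
  A <- sample_affine(affine_ranges(), sz)$matrix
  moving <- photometric_augment(
    fundusreg:::warp_image(scene$image, A, sz, fill = 0.05))
  fn(list(fixed = scene$image, moving = moving, h_true = A))
}

# Mutual-match counts against the known true warp of a fixture pair:
# c(hits, total) where a hit is a mutual match whose moving point lies
# within `tol` px of h_true(fixed point).  Pool counts across draws for the
# precision estimate.
match_counts <- function(pair, detector, descriptor, tol = 3) {
  kf <- detect(detector, pair$fixed)
  km <- detect(detector, pair$moving)
  if (nrow(kf) < 2 || nrow(km) < 2) return(c(0, 0))
  df <- sample_descriptors(describe(descriptor, pair$fixed), kf)
  dm <- sample_descriptors(describe(descriptor, pair$moving), km)
  m <- mutual_match(df, dm)
  if (!nrow(m)) return(c(0, 0))
  p <- apply_homography(pair$h_true, cbind(m$x_fixed, m$y_fixed))
  err <- sqrt((p[, 1] - m$x_moving)^2 + (p[, 2] - m$y_moving)^2)
  c(sum(err < tol), length(err))
}
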