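# Minimal fully-convolutional network engine used by the detector and
# descriptor models: 3x3 (optionally dilated) and 1x1 convolutions with
# 'same' zero padding via im2col + GEMM in C++, ReLU, 2x2 max pooling and
# nearest-neighbour upsampling, and an Adam optimizer over nested parameter
# lists.  All computation is double precision on the CPU and deterministic
# for a fixed RNG state.

conv_init <- function(c_in, c_out, k = 3, d = 1) {
  sd <- sqrt(2 / (k * k * c_in))
  list(W = matrix(rnorm(k * k * c_in * c_out, 0, sd), k * k * c_in, c_out),
       b = rep(0, c_out), k = k, d = d)
}

conv_fwd <- function(layer, x) {
  cpp_conv2d_fwd(x, layer$W, layer$b, layer$k, layer$d)
}

conv_bwd <- function(layer, x, gy, need_gx = TRUE) {
  cpp_conv2d_bwd(x, layer$W, gy, layer$k, layer$d, need_gx)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = map_leaves(function(p) p * 0, strip_meta(params)),
       v = map_leaves(function(p) p * 0, strip_meta(params)),
       t = 0L)
}

# Parameters are nested lists whose leaves are numeric arrays; conv layers
# carry integer metadata (k, d) that the optimizer must skip.
strip_meta <- function(params) {
  if (is.list(params)) {
    keep <- setdiff(names(params), c("k", "d"))
    if (is.null(names(params))) keep <- seq_along(params)
    lapply(params[keep], strip_meta)
  } else {
    params
  }
}

merge_meta <- function(params, updated) {
  if (is.list(params)) {
    keep <- setdiff(names(params), c("k", "d"))
    if (is.null(names(params))) keep <- seq_along(params)
    for (nm in keep) params[[nm]] <- merge_meta(params[[nm]], updated[[nm]])
    params
  } else {
    updated
  }
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  p0 <- strip_meta(params)
  g0 <- strip_meta(grads)
  state$m <- map_leaves(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, g0)
  state$v <- map_leaves(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, g0)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- map_leaves(function(p, m, v) {
    p - lr * (m / c1) / (sqrt(v / c2) + eps)
  }, p0, state$m, state$v)
  list(params = merge_meta(params, upd), state = state)
}

# --- Descriptor network ----------------------------------------------------
# Fully convolutional, dilation-based (no spatial downsampling), so the
# output field has the input's resolution; a final 1x1 projection gives D
# channels which are L2-normalized per pixel outside this module.

desc_init <- function(cfg) {
  widths <- cfg$widths
  dil <- cfg$dilations
  layers <- vector("list", length(widths) + 1)
  c_in <- 3
  for (i in seq_along(widths)) {
    layers[[i]] <- conv_init(c_in, widths[i], k = 3, d = dil[i])
    c_in <- widths[i]
  }
  layers[[length(widths) + 1]] <- conv_init(c_in, cfg$dim, k = 1, d = 1)
  names(layers) <- c(paste0("conv", seq_along(widths)), "proj")
  layers
}

desc_receptive_field <- function(cfg) 1 + 2 * sum(cfg$dilations)

# Forward over one raster; returns raw (unnormalized) D-channel field and,
# optionally, the activation cache for backprop.
desc_fwd <- function(params, x, keep_cache = FALSE) {
  n <- length(params)
  cache <- if (keep_cache) vector("list", n) else NULL
  h <- x
  for (i in seq_len(n)) {
    if (keep_cache) cache[[i]] <- h
    h <- conv_fwd(params[[i]], h)
    if (i < n) h <- relu(h)
  }
  list(y = h, cache = cache)
}

zero_grads <- function(params) {
  map_leaves(function(p) p * 0, strip_meta(params))
}

# --- U-Net -----------------------------------------------------------------
# Encoder-decoder with skip connections; `levels` resolution levels (the
# deepest is the bottleneck), two 3x3 conv+ReLU blocks per level, channel
# width doubling with depth, nearest-neighbour upsampling and concatenation
# skips, and a linear 1x1 output head with `out_channels` planes.

unet_init <- function(levels = 4, base = 32, in_channels = 3,
                      out_channels = 3) {
  p <- list()
  c_in <- in_channels
  for (l in seq_len(levels)) {
    w <- base * 2^(l - 1)
    p[[paste0("enc", l)]] <- list(c1 = conv_init(c_in, w),
                                  c2 = conv_init(w, w))
    c_in <- w
  }
  for (l in seq_len(levels - 1)) {
    w <- base * 2^(l - 1)
    up_in <- base * 2^l + w          # upsampled deeper features + skip
    p[[paste0("dec", l)]] <- list(c1 = conv_init(up_in, w),
                                  c2 = conv_init(w, w))
  }
  p$head <- conv_init(base, out_channels, k = 1)
  attr(p, "levels") <- levels
  attr(p, "base") <- base
  p
}

unet_fwd <- function(params, x, keep_cache = FALSE) {
  L <- attr(params, "levels")
  cache <- list(enc_in = list(), enc_mid = list(), enc_out = list(),
                pool_idx = list(), dec_in = list(), dec_mid = list(),
                dec_out = list())
  h <- x
  skips <- vector("list", L)
  for (l in seq_len(L)) {
    e <- params[[paste0("enc", l)]]
    cache$enc_in[[l]] <- h
    a <- relu(conv_fwd(e$c1, h))
    cache$enc_mid[[l]] <- a
    a <- relu(conv_fwd(e$c2, a))
    cache$enc_out[[l]] <- a
    skips[[l]] <- a
    if (l < L) {
      mp <- cpp_maxpool2(a)
      cache$pool_idx[[l]] <- mp$idx
      h <- mp$y
    } else {
      h <- a
    }
  }
  for (l in (L - 1):1) {
    d <- params[[paste0("dec", l)]]
    up <- cpp_upsample2(h)
    cat_in <- abind3(up, skips[[l]])
    cache$dec_in[[l]] <- cat_in
    a <- relu(conv_fwd(d$c1, cat_in))
    cache$dec_mid[[l]] <- a
    a <- relu(conv_fwd(d$c2, a))
    cache$dec_out[[l]] <- a
    h <- a
  }
  y <- conv_fwd(params$head, h)
  out <- list(y = y)
  if (keep_cache) out$cache <- cache
  out
}

unet_bwd <- function(params, cache, gy) {
  L <- attr(params, "levels")
  g <- zero_grads(params)
  bw <- conv_bwd(params$head, cache$dec_out[[1]], gy)
  g$head$W <- bw$gW; g$head$b <- as.numeric(bw$gb)
  gh <- bw$gx
  gskip <- vector("list", L)
  for (l in seq_len(L - 1)) {
    d <- params[[paste0("dec", l)]]
    gh <- gh * (cache$dec_out[[l]] > 0)
    bw2 <- conv_bwd(d$c2, cache$dec_mid[[l]], gh)
    g[[paste0("dec", l)]]$c2$W <- bw2$gW
    g[[paste0("dec", l)]]$c2$b <- as.numeric(bw2$gb)
    gm <- bw2$gx * (cache$dec_mid[[l]] > 0)
    bw1 <- conv_bwd(d$c1, cache$dec_in[[l]], gm)
    g[[paste0("dec", l)]]$c1$W <- bw1$gW
    g[[paste0("dec", l)]]$c1$b <- as.numeric(bw1$gb)
    nup <- dim(cache$dec_in[[l]])[3] - dim(cache$enc_out[[l]])[3]
    gcat <- bw1$gx
    gup <- gcat[, , seq_len(nup), drop = FALSE]
    gskip[[l]] <- gcat[, , nup + seq_len(dim(cache$enc_out[[l]])[3]),
                       drop = FALSE]
    gh <- cpp_upsample2_bwd(gup)
  }
  # gh now flows into the bottleneck output; add skip gradients on the way up
  for (l in L:1) {
    e <- params[[paste0("enc", l)]]
    ga <- gh
    if (l < L) {
      ga <- cpp_maxpool2_bwd(gh, cache$pool_idx[[l]])
      ga <- ga + gskip[[l]]
    }
    ga <- ga * (cache$enc_out[[l]] > 0)
    bw2 <- conv_bwd(e$c2, cache$enc_mid[[l]], ga)
    g[[paste0("enc", l)]]$c2$W <- bw2$gW
    g[[paste0("enc", l)]]$c2$b <- as.numeric(bw2$gb)
    gm <- bw2$gx * (cache$enc_mid[[l]] > 0)
    bw1 <- conv_bwd(e$c1, cache$enc_in[[l]], gm, need_gx = l > 1)
    g[[paste0("enc", l)]]$c1$W <- bw1$gW
    g[[paste0("enc", l)]]$c1$b <- as.numeric(bw1$gb)
    if (l > 1) gh <- bw1$gx
  }
  g
}

abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

# Replicate-pad an image so H and W are multiples of `m`; returns padded
# array plus the original size for cropping the output back.
pad_to_multiple <- function(x, m) {
  d <- dim(x)
  H2 <- ceiling(d[1] / m) * m
  W2 <- ceiling(d[2] / m) * m
  if (H2 == d[1] && W2 == d[2]) return(list(x = x, size = d[1:2]))
  out <- array(0, c(H2, W2, d[3]))
  out[seq_len(d[1]), seq_len(d[2]), ] <- x
  if (H2 > d[1]) {
    out[(d[1] + 1):H2, seq_len(d[2]), ] <-
      out[rep(d[1], H2 - d[1]), seq_len(d[2]), ]
  }
  if (W2 > d[2]) out[, (d[2] + 1):W2, ] <- out[, rep(d[2], W2 - d[2]), ]
  list(x = out, size = d[1:2])
}
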