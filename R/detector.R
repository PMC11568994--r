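# Keypoint detector: a fully convolutional encoder-decoder (U-Net) that
# regresses the three-plane heatmap stack (crossover, bifurcation, combined)
# from an RGB fundus image, trained with mean squared error.

#' Detector training configuration
#'
#' Defaults follow the heatmap-regression training recipe: Adam starting at
#' learning rate 1e-4, decayed by a factor of 0.1 whenever the validation
#' loss has not improved for 2500 single-image batches, stopping when the
#' learning rate drops below 1e-7; spatial augmentation with rotations of
#' +/-90 degrees, scaling in [0.9, 1.1] and shearing of +/-20 degrees, plus
#' HSV jitter; 25% of the scenes reserved for validation.
#'
#' @param lr_init,lr_factor,lr_patience,lr_floor learning-rate schedule.
#' @param rotation,scale,shear spatial augmentation ranges.
#' @param hsv_jitter maximum absolute (h, s, v) jitter, or `NULL` to disable.
#' @param val_fraction fraction of scenes held out for validation.
#' @param val_every validate every this many batches.
#' @param max_steps optional cap on the number of optimizer steps (the
#'   learning-rate floor remains the default stopping rule).
#' @param crop_size optional square crop side used per training batch;
#'   `NULL` trains on full images.
#' @param levels,base U-Net depth (resolution levels) and base channel width.
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(lr_init = 1e-4, lr_factor = 0.1,
                            lr_patience = 2500, lr_floor = 1e-7,
                            rotation = 90, scale = c(0.9, 1.1), shear = 20,
                            hsv_jitter = c(0.02, 0.15, 0.15),
                            val_fraction = 0.25, val_every = 25,
                            max_steps = Inf, crop_size = NULL,
                            levels = 4, base = 32) {
  stopifnot(lr_floor < lr_init, val_fraction > 0, val_fraction < 1,
            lr_factor > 0, lr_factor < 1, lr_patience >= 1)
  structure(list(lr_init = lr_init, lr_factor = lr_factor,
                 lr_patience = lr_patience, lr_floor = lr_floor,
                 rotation = rotation, scale = scale, shear = shear,
                 hsv_jitter = hsv_jitter, val_fraction = val_fraction,
                 val_every = val_every, max_steps = max_steps,
                 crop_size = crop_size, levels = levels, base = base),
            class = "detector_config")
}

# The plateau learning-rate schedule as a standalone state machine so it can
# be exercised against a scripted loss sequence: feed one validation loss at
# a time; multiply lr by `factor` after `patience` batches without
# improvement; stop when lr < floor.
lr_scheduler <- function(lr_init, factor, patience, floor) {
  env <- new.env()
  env$lr <- lr_init
  env$best <- Inf
  env$bad <- 0
  list(
    observe = function(val_loss, batches = 1) {
      if (val_loss < env$best - 1e-12) {
        env$best <- val_loss
        env$bad <- 0
      } else {
        env$bad <- env$bad + batches
        if (env$bad >= patience) {
          env$lr <- env$lr * factor
          env$bad <- 0
        }
      }
      env$lr
    },
    lr = function() env$lr,
    stopped = function() env$lr < floor
  )
}

#' Train the keypoint detection network
#'
#' Minimizes the mean squared error between the predicted and target
#' three-plane heatmap stacks, jointly over the planes, with single-image
#' batches, spatial + HSV augmentation, and a validate/plateau learning-rate
#' schedule.  Returns the parameters with the best validation loss.
#'
#' @param train_scenes list of `list(image =, heatmaps =)` pairs, where
#'   `heatmaps` is a [heatmap_stack()]; at least 2 (>= 1 train, >= 1
#'   validation).
#' @param cfg a [detector_config()].
#' @param seed integer; training is deterministic given (seed, cfg, data).
#' @return a `detector_model`: list with `params`, `cfg`, `history` and
#'   `format_version`.
#' @export
train_detector <- function(train_scenes, cfg = detector_config(), seed = 1) {
  if (!length(train_scenes)) {
    stopf("fundusreg_invalid_argument", "empty training set")
  }
  stopifnot(length(train_scenes) >= 2)
  with_seed(seed, {
    n <- length(train_scenes)
    n_val <- max(1, round(cfg$val_fraction * n))
    idx <- sample.int(n)
    val_idx <- idx[seq_len(n_val)]
    tr_idx <- setdiff(idx, val_idx)

    params <- unet_init(cfg$levels, cfg$base)
    opt <- adam_init(params)
    sched <- lr_scheduler(cfg$lr_init, cfg$lr_factor, cfg$lr_patience,
                          cfg$lr_floor)
    best <- list(loss = Inf, params = params)
    history <- list(train = numeric(0), val = numeric(0), lr = numeric(0))
    step <- 0
    mult <- 2^(cfg$levels - 1)

    val_loss <- function(p) {
      mean(vapply(val_idx, function(i) {
        s <- train_scenes[[i]]
        pd <- pad_to_multiple(s$image, mult)
        y <- unet_fwd(p, pd$x)$y[seq_len(pd$size[1]), seq_len(pd$size[2]), ,
                                 drop = FALSE]
        mean((y - s$heatmaps$planes)^2)
      }, 0))
    }

    while (step < cfg$max_steps && !sched$stopped()) {
      step <- step + 1
      s <- train_scenes[[tr_idx[(step - 1) %% length(tr_idx) + 1]]]
      aug <- augment_scene(s$image, s$heatmaps$planes, cfg, mult)
      fw <- unet_fwd(params, aug$x, keep_cache = TRUE)
      resid <- fw$y - aug$t
      loss <- mean(resid^2)
      grads <- unet_bwd(params, fw$cache, 2 * resid / length(resid))
      st <- adam_step(params, grads, opt, sched$lr())
      params <- st$params
      opt <- st$state
      history$train <- c(history$train, loss)
      if (step %% cfg$val_every == 0 || step == cfg$max_steps) {
        vl <- val_loss(params)
        history$val <- c(history$val, vl)
        history$lr <- c(history$lr, sched$lr())
        if (vl < best$loss) best <- list(loss = vl, params = params)
        sched$observe(vl, batches = cfg$val_every)
      }
    }
    structure(list(params = best$params, cfg = cfg,
                   best_val_loss = best$loss, history = history,
                   format_version = 1L),
              class = "detector_model")
  })
}

# Joint spatial augmentation of an image and its heatmap targets (same
# affine warp for both), HSV jitter on the image only, optional random crop.
augment_scene <- function(image, planes, cfg, mult) {
  sz <- dim(image)[1:2]
  A <- sample_affine(
    affine_ranges(rotation = cfg$rotation, translation = 0,
                  scale = cfg$scale, shear = cfg$shear), sz)$matrix
  x <- warp_image(image, A, sz, fill = 0.05)
  t <- warp_image(planes, A, sz, fill = 0)
  if (!is.null(cfg$hsv_jitter)) {
    x <- clamp01(shift_hsv(x, runif(3, -1, 1) * cfg$hsv_jitter))
  }
  if (!is.null(cfg$crop_size) && all(sz > cfg$crop_size)) {
    cs <- cfg$crop_size
    oy <- sample.int(sz[1] - cs + 1, 1) - 1
    ox <- sample.int(sz[2] - cs + 1, 1) - 1
    x <- x[oy + seq_len(cs), ox + seq_len(cs), , drop = FALSE]
    t <- t[oy + seq_len(cs), ox + seq_len(cs), , drop = FALSE]
  }
  px <- pad_to_multiple(x, mult)
  pt <- pad_to_multiple(t, mult)
  list(x = px$x, t = pt$x)
}

#' Predict the heatmap stack for an image
#'
#' @param model a `detector_model`.
#' @param image H x W x 3 array; padded and cropped internally to satisfy
#'   the network's downsampling factor.
#' @return a [heatmap_stack()] with values clipped to [0, 1].
#' @export
predict_heatmaps <- function(model, image) {
  stopifnot(inherits(model, "detector_model"))
  mult <- 2^(model$cfg$levels - 1)
  pd <- pad_to_multiple(image, mult)
  y <- unet_fwd(model$params, pd$x)$y
  y <- y[seq_len(pd$size[1]), seq_len(pd$size[2]), , drop = FALSE]
  heatmap_stack(clamp01(y), sigma = attr(model, "sigma") %||% 5)
}

#' Detect keypoints in an image
#'
#' Runs the detector network and extracts discrete keypoints from the
#' predicted heatmaps with a strict local-maxima filter and an intensity
#' threshold.
#'
#' @inheritParams predict_heatmaps
#' @param threshold detection threshold (default 0.35).
#' @param window local-maxima window, odd, pixels (default 7).
#' @return a [keypoint_set()].
#' @export
detect <- function(model, image, threshold = 0.35, window = 7) {
  extract_keypoints(predict_heatmaps(model, image), threshold, window)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single-file archive holding the parameters, the
#' configuration and a format version.
#' @param model a `detector_model` or `descriptor_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (is.null(m$format_version)) {
    stopf("fundusreg_invalid_argument", "not a model checkpoint: %s", path)
  }
  m
}
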