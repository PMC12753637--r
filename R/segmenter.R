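#' Training configuration for the segmentation model
#'
#' Defaults follow the settings used to train the production model:
#' Adam with learning rate 1e-4 for 100 epochs, mini-batch size 8,
#' weighted cross-entropy with class weights (0.4, 0.9, 0.9) for
#' background / positive / negative, rotation up to 30 degrees and
#' horizontal/vertical flips with probability 0.5, inputs rescaled from
#' 0-255 to \[0, 1\], and a 0.5 foreground acceptance threshold when
#' converting probabilities to masks. Desk-scale runs typically override
#' `epochs = 5`.
#'
#' @param learning_rate positive Adam step size.
#' @param epochs non-negative integer.
#' @param batch_size positive integer.
#' @param class_weights positive weights for background, positive,
#'   negative.
#' @param rotation_max_deg augmentation rotation bound (degrees).
#' @param flip_probability probability of each of horizontal and vertical
#'   flip.
#' @param mask_threshold foreground acceptance threshold in (0, 1).
#' @param pretrained_encoder load externally pretrained encoder weights
#'   (default FALSE: random initialisation; supply a checkpoint instead).
#' @param seed integer seed controlling initialisation, shuffling and
#'   augmentation.
#' @return an object of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-4,
                            epochs = 100L,
                            batch_size = 8L,
                            class_weights = c(0.4, 0.9, 0.9),
                            rotation_max_deg = 30,
                            flip_probability = 0.5,
                            mask_threshold = 0.5,
                            pretrained_encoder = FALSE,
                            seed = 1L) {
  stopifnot(learning_rate > 0, epochs >= 0, batch_size >= 1,
            length(class_weights) == 3, all(class_weights > 0),
            flip_probability >= 0, flip_probability <= 1,
            mask_threshold > 0, mask_threshold < 1)
  structure(
    list(learning_rate = as.numeric(learning_rate),
         epochs = as.integer(epochs),
         batch_size = as.integer(batch_size),
         class_weights = as.numeric(class_weights),
         rotation_max_deg = as.numeric(rotation_max_deg),
         flip_probability = as.numeric(flip_probability),
         mask_threshold = as.numeric(mask_threshold),
         pretrained_encoder = isTRUE(pretrained_encoder),
         seed = as.integer(seed)),
    class = "training_config"
  )
}

# architecture descriptors -------------------------------------------------

unet_arch <- function(variant = c("full", "reduced")) {
  variant <- match.arg(variant)
  if (variant == "full") {
    # residual encoder in the ResNet-34 pattern: 7x7/2 stem with 64 maps,
    # stages (3,4,6,3) at widths (64,128,256,512), 1024-map bottleneck
    # at 1/32 resolution (8x8 for a 256x256 input)
    list(variant = variant, stem_width = 64L, stem_stride = 2L,
         use_pool = TRUE,
         stage_widths = c(64L, 128L, 256L, 512L),
         stage_blocks = c(3L, 4L, 6L, 3L),
         stage_strides = c(1L, 2L, 2L, 2L),
         bottleneck_width = 1024L, head_width = 32L)
  } else {
    # desk-scale variant: stages halved, base width 16; the stem keeps
    # the 7x7 kernel but runs at stride 1 so the shallow network retains
    # full-resolution chromatic features for the small-cell regime
    list(variant = variant, stem_width = 16L, stem_stride = 1L,
         use_pool = FALSE,
         stage_widths = c(16L, 32L),
         stage_blocks = c(1L, 1L),
         stage_strides = c(1L, 2L),
         bottleneck_width = 64L, head_width = 16L)
  }
}

#' Build the encoder-decoder segmentation model
#'
#' The encoder is a residual-block stack in the ResNet-34 pattern: a 7x7
#' stride-2 stem producing 64 feature maps, four residual stages, and a
#' bottleneck emitting 1024 feature maps at 1/32 of the input resolution.
#' The decoder upsamples with 2x2 stride-2 transpose convolutions, fusing
#' a skip connection from each encoder stage, and ends in a three-class
#' softmax head (background, positive, negative). Residual blocks use
#' plain convolution + ReLU (no batch normalisation), which keeps
#' training exactly deterministic. A reduced-depth variant (stages
#' halved, base width 16) is provided for CPU-scale experiments.
#'
#' Inputs must be RGB with height and width divisible by 32;
#' non-conforming sizes are rejected rather than silently padded so the
#' mask/image correspondence stays exact.
#'
#' @param config a [training_config()]; its seed fixes the random
#'   initialisation.
#' @param variant `"full"` (default) or `"reduced"`.
#' @return an object of class `tps_unet`.
#' @export
build_model <- function(config = training_config(),
                        variant = c("full", "reduced")) {
  stopifnot(inherits(config, "training_config"))
  if (config$pretrained_encoder) {
    stop("no pretrained encoder weights are bundled; load a checkpoint ",
         "with load_checkpoint() instead", call. = FALSE)
  }
  arch <- unet_arch(match.arg(variant))
  ops <- list()
  layers <- list()
  add_op <- function(out, type, a, b = NULL, par = NULL,
                     k = NULL, s = NULL, p = NULL) {
    ops[[length(ops) + 1L]] <<- list(out = out, type = type, a = a, b = b,
                                     par = par, k = k, s = s, p = p)
  }
  add_conv <- function(out, a, par, in_ch, out_ch, k, s) {
    layers[[par]] <<- list(type = "conv", k = k, s = s, p = (k - 1L) %/% 2L,
                           in_ch = in_ch, out_ch = out_ch)
    add_op(out, "conv", a, par = par, k = k, s = s, p = (k - 1L) %/% 2L)
  }
  add_tconv <- function(out, a, par, in_ch, out_ch) {
    layers[[par]] <<- list(type = "tconv", in_ch = in_ch, out_ch = out_ch)
    add_op(out, "tconv", a, par = par)
  }

  # encoder
  add_conv("stem_pre", "input", "stem", 3L, arch$stem_width, 7L,
           arch$stem_stride)
  add_op("stem", "relu", "stem_pre")
  cur <- "stem"; cur_ch <- arch$stem_width
  if (arch$use_pool) { add_op("pool", "maxpool", cur); cur <- "pool" }
  skip_ids <- character(); skip_chs <- integer()
  for (s in seq_along(arch$stage_widths)) {
    w <- arch$stage_widths[s]
    for (b in seq_len(arch$stage_blocks[s])) {
      stride <- if (b == 1L) arch$stage_strides[s] else 1L
      nm <- sprintf("stage%d_block%d", s, b)
      add_conv(paste0(nm, "_c1"), cur, paste0(nm, "_conv1"), cur_ch, w, 3L, stride)
      add_op(paste0(nm, "_r1"), "relu", paste0(nm, "_c1"))
      add_conv(paste0(nm, "_c2"), paste0(nm, "_r1"), paste0(nm, "_conv2"),
               w, w, 3L, 1L)
      if (stride != 1L || cur_ch != w) {
        add_conv(paste0(nm, "_sc"), cur, paste0(nm, "_proj"), cur_ch, w, 1L, stride)
        sc <- paste0(nm, "_sc")
      } else sc <- cur
      add_op(paste0(nm, "_sum"), "add", paste0(nm, "_c2"), sc)
      add_op(nm, "relu", paste0(nm, "_sum"))
      cur <- nm; cur_ch <- w
    }
    skip_ids <- c(skip_ids, cur); skip_chs <- c(skip_chs, cur_ch)
  }
  add_conv("bott_pre", cur, "bottleneck", cur_ch, arch$bottleneck_width, 3L, 1L)
  add_op("bott", "relu", "bott_pre")
  cur <- "bott"; cur_ch <- arch$bottleneck_width

  # decoder: walk back up through the encoder resolutions, fusing the
  # deepest encoder output available at each resolution as the skip
  stem_res <- if (arch$stem_stride == 2L) 1L else 0L
  base_res <- stem_res + (if (arch$use_pool) 1L else 0L)
  n_down <- base_res + sum(arch$stage_strides == 2L)   # total halvings
  stage_res <- vapply(seq_along(arch$stage_strides), function(s) {
    base_res + sum(arch$stage_strides[1:s] == 2L)
  }, 0L)                                        # halvings at each stage output
  skip_plan <- list()
  for (lvl in seq.int(n_down - 1L, 0L)) {
    hit <- which(stage_res == lvl)
    skip_plan[[length(skip_plan) + 1L]] <-
      if (length(hit) > 0) {
        list(id = skip_ids[max(hit)], ch = skip_chs[max(hit)])
      } else if (lvl == stem_res) {
        list(id = "stem", ch = arch$stem_width)
      } else {
        list(id = NA_character_, ch = 0L)
      }
  }
  for (i in seq_along(skip_plan)) {
    sp <- skip_plan[[i]]
    out_ch <- if (sp$ch > 0L) sp$ch else arch$head_width
    add_tconv(sprintf("up%d_t", i), cur, sprintf("up%d_tconv", i),
              cur_ch, out_ch)
    add_op(sprintf("up%d_tr", i), "relu", sprintf("up%d_t", i))
    cur <- sprintf("up%d_tr", i); cur_ch <- out_ch
    if (sp$ch > 0L) {
      add_op(sprintf("up%d_cat", i), "concat", cur, sp$id)
      cur <- sprintf("up%d_cat", i); cur_ch <- cur_ch + sp$ch
    }
    add_conv(sprintf("up%d_c", i), cur, sprintf("up%d_conv", i),
             cur_ch, out_ch, 3L, 1L)
    add_op(sprintf("up%d", i), "relu", sprintf("up%d_c", i))
    cur <- sprintf("up%d", i); cur_ch <- out_ch
  }
  add_conv("logits", cur, "head", cur_ch, 3L, 1L, 1L)

  params <- with_seed(config$seed, {
    lapply(layers, function(ly) {
      if (ly$type == "conv") {
        fan_in <- ly$k * ly$k * ly$in_ch
        list(W = matrix(stats::rnorm(fan_in * ly$out_ch, 0,
                                     sqrt(2 / fan_in)),
                        fan_in, ly$out_ch),
             b = numeric(ly$out_ch))
      } else {
        list(W = matrix(stats::rnorm(4L * ly$in_ch * ly$out_ch, 0,
                                     sqrt(2 / ly$in_ch)),
                        4L * ly$in_ch, ly$out_ch),
             b = numeric(ly$out_ch))
      }
    })
  })

  structure(
    list(variant = arch$variant, arch = arch, ops = ops, layers = layers,
         params = params, config = config, divisor = 32L),
    class = "tps_unet"
  )
}

#' @export
print.tps_unet <- function(x, ...) {
  n_par <- sum(vapply(x$params, function(p) length(p$W) + length(p$b), 0))
  cat(sprintf("tps_unet (%s variant): %d layers, %s parameters\n",
              x$variant, length(x$layers), format(n_par, big.mark = ",")))
  invisible(x)
}

check_input_shape <- function(model, image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) {
    stop("input must be an H x W x 3 RGB array", call. = FALSE)
  }
  if (d[1] %% model$divisor != 0L || d[2] %% model$divisor != 0L) {
    stop(sprintf(
      "input size %dx%d not accepted: height and width must be divisible by %d",
      d[1], d[2], model$divisor), call. = FALSE)
  }
  invisible(d)
}

forward_graph <- function(model, x, keep = FALSE) {
  vals <- new.env(parent = emptyenv())
  caches <- if (keep) new.env(parent = emptyenv()) else NULL
  assign("input", x, envir = vals)
  for (op in model$ops) {
    a <- get(op$a, envir = vals)
    res <- switch(op$type,
      conv = conv_fwd(a, model$params[[op$par]], op$k, op$s, op$p, keep),
      tconv = tconv_fwd(a, model$params[[op$par]], keep),
      maxpool = maxpool_fwd(a, keep),
      relu = list(y = pmax(a, 0), cache = NULL),
      add = list(y = a + get(op$b, envir = vals), cache = NULL),
      concat = {
        bv <- get(op$b, envir = vals)
        da <- dim(a); db <- dim(bv)
        list(y = array(c(a, bv), c(da[1], da[2], da[3] + db[3])),
             cache = NULL)
      },
      stop("unknown op type: ", op$type)
    )
    assign(op$out, res$y, envir = vals)
    if (keep && !is.null(res$cache)) assign(op$out, res$cache, envir = caches)
  }
  list(vals = vals, caches = caches)
}

backward_graph <- function(model, fw, dlogits) {
  grads <- new.env(parent = emptyenv())
  gpar <- list()
  assign("logits", dlogits, envir = grads)
  acc <- function(id, g) {
    if (exists(id, envir = grads, inherits = FALSE)) {
      assign(id, get(id, envir = grads) + g, envir = grads)
    } else assign(id, g, envir = grads)
  }
  for (op in rev(model$ops)) {
    if (!exists(op$out, envir = grads, inherits = FALSE)) next
    dy <- get(op$out, envir = grads)
    rm(list = op$out, envir = grads)
    switch(op$type,
      conv = {
        bw <- conv_bwd(dy, get(op$out, envir = fw$caches),
                       model$params[[op$par]], op$k, op$s, op$p)
        gpar[[op$par]] <- if (is.null(gpar[[op$par]])) {
          list(W = bw$dW, b = bw$db)
        } else list(W = gpar[[op$par]]$W + bw$dW,
                    b = gpar[[op$par]]$b + bw$db)
        acc(op$a, bw$dx)
      },
      tconv = {
        bw <- tconv_bwd(dy, get(op$out, envir = fw$caches),
                        model$params[[op$par]])
        gpar[[op$par]] <- if (is.null(gpar[[op$par]])) {
          list(W = bw$dW, b = bw$db)
        } else list(W = gpar[[op$par]]$W + bw$dW,
                    b = gpar[[op$par]]$b + bw$db)
        acc(op$a, bw$dx)
      },
      maxpool = acc(op$a, maxpool_bwd(dy, get(op$out, envir = fw$caches))),
      relu = acc(op$a, dy * (get(op$a, envir = fw$vals) > 0)),
      add = { acc(op$a, dy); acc(op$b, dy) },
      concat = {
        Ca <- dim(get(op$a, envir = fw$vals))[3]
        acc(op$a, dy[, , seq_len(Ca), drop = FALSE])
        acc(op$b, dy[, , -seq_len(Ca), drop = FALSE])
      }
    )
  }
  gpar
}

#' Per-pixel class probabilities for an image
#'
#' Runs the model forward and applies the softmax head, giving an
#' `H x W x 3` array of class probabilities (background, positive,
#' negative) summing to 1 at every pixel.
#'
#' @param model a [build_model()] model.
#' @param image `H x W x 3` RGB array (0-255 inputs are rescaled).
#' @return the class probability map.
#' @export
predict_probs <- function(model, image) {
  stopifnot(inherits(model, "tps_unet"))
  image <- normalize_image(image)
  check_input_shape(model, image)
  fw <- forward_graph(model, image, keep = FALSE)
  softmax_hw(get("logits", envir = fw$vals))
}

#' Predict a label mask
#'
#' A pixel is assigned the foreground class (1 positive, 2 negative) with
#' the larger probability when that probability reaches
#' `mask_threshold`; otherwise it is background. Ties between the two
#' foreground classes break toward the positive class.
#'
#' @inheritParams predict_probs
#' @param mask_threshold foreground acceptance threshold (default 0.5).
#' @return an integer label mask.
#' @export
predict_mask <- function(model, image, mask_threshold = 0.5) {
  probs <- predict_probs(model, image)
  mask_from_probs(probs, mask_threshold)
}

#' @rdname predict_mask
#' @param probs an `H x W x 3` class probability map.
#' @export
mask_from_probs <- function(probs, mask_threshold = 0.5) {
  p1 <- probs[, , 2]; p2 <- probs[, , 3]
  best <- pmax(p1, p2)
  out <- matrix(0L, dim(probs)[1], dim(probs)[2])
  fg <- best >= mask_threshold
  out[fg & p1 >= p2] <- 1L
  out[fg & p1 < p2] <- 2L
  out
}

#' Weighted cross-entropy loss
#'
#' Mean over pixels of `w[target] * (-log p[target])`: the class-weighted
#' pixel classification loss used to counter the background/foreground
#' imbalance, with weights (0.4, 0.9, 0.9) by default. With unit weights
#' it reduces to plain cross-entropy. Probabilities are clamped at 1e-12
#' so the loss is always finite.
#'
#' @param probs `H x W x 3` class probability map.
#' @param target label mask of matching shape.
#' @param class_weights positive weights for classes 0, 1, 2.
#' @return a non-negative scalar.
#' @export
wce_loss <- function(probs, target, class_weights = c(0.4, 0.9, 0.9)) {
  target <- validate_mask(target)
  d <- dim(probs)
  if (length(d) != 3L || d[3] != 3L || !all(d[1:2] == dim(target))) {
    stop("probs must be H x W x 3 matching the target mask", call. = FALSE)
  }
  n <- d[1] * d[2]
  tvec <- as.vector(target)
  pt <- pmax(as.vector(probs)[seq_len(n) + n * tvec], 1e-12)
  sum(class_weights[tvec + 1L] * (-log(pt))) / n
}

#' Paired augmentation of an image and its mask
#'
#' Applies the same geometric transform to both: horizontal and vertical
#' flips, each with `flip_probability`, then rotation by an angle drawn
#' uniformly from \[-rotation_max_deg, rotation_max_deg\]. The image is
#' resampled bilinearly; the mask uses nearest-neighbour so labels stay
#' in \{0, 1, 2\}. Pixels rotated in from outside the canvas take the
#' background colour (image) and label 0 (mask).
#'
#' @param image `H x W x 3` array.
#' @param mask matching label mask.
#' @param config a [training_config()] (uses `flip_probability`,
#'   `rotation_max_deg`).
#' @param seed optional seed; by default draws from the current RNG
#'   stream (as during training).
#' @return list with transformed `image` and `mask`.
#' @export
augment <- function(image, mask, config = training_config(), seed = NULL) {
  stopifnot(all(dim(image)[1:2] == dim(mask)))
  run <- function() {
    if (stats::runif(1) < config$flip_probability) {
      image <- image[, dim(image)[2]:1, , drop = FALSE]
      mask <- mask[, ncol(mask):1, drop = FALSE]
    }
    if (stats::runif(1) < config$flip_probability) {
      image <- image[dim(image)[1]:1, , , drop = FALSE]
      mask <- mask[nrow(mask):1, , drop = FALSE]
    }
    angle <- stats::runif(1, -config$rotation_max_deg, config$rotation_max_deg)
    if (abs(angle) > 1e-12) {
      rot <- rotate_pair(image, mask, angle)
      image <- rot$image; mask <- rot$mask
    }
    list(image = image, mask = mask)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# rotate image (bilinear) and mask (nearest) about the canvas centre
rotate_pair <- function(image, mask, angle_deg) {
  H <- nrow(mask); W <- ncol(mask)
  th <- angle_deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  dr <- rep(seq_len(H) - cy, times = W)
  dc <- rep(seq_len(W) - cx, each = H)
  sr <- cy + cos(th) * dr - sin(th) * dc
  sc <- cx + sin(th) * dr + cos(th) * dc

  # mask: nearest neighbour
  ri <- round(sr); ci <- round(sc)
  ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
  new_mask <- matrix(0L, H, W)
  new_mask[ok] <- mask[cbind(ri[ok], ci[ok])]

  # image: bilinear with background fill outside the canvas
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  cl <- function(v, n) pmin(pmax(v, 1), n)
  inb <- sr >= 1 & sr <= H & sc >= 1 & sc <= W
  new_image <- array(0, dim(image))
  for (ch in seq_len(dim(image)[3])) {
    page <- image[, , ch]
    v <- (1 - fr) * (1 - fc) * page[cbind(cl(r0, H), cl(c0, W))] +
         (1 - fr) * fc       * page[cbind(cl(r0, H), cl(c0 + 1, W))] +
         fr       * (1 - fc) * page[cbind(cl(r0 + 1, H), cl(c0, W))] +
         fr       * fc       * page[cbind(cl(r0 + 1, H), cl(c0 + 1, W))]
    v[!inb] <- .stain_colors$background[ch]
    new_image[, , ch] <- matrix(v, H, W)
  }
  list(image = new_image, mask = new_mask)
}

#' Train the segmentation model
#'
#' Mini-batch gradient descent with the Adam optimizer on the weighted
#' cross-entropy loss, with seeded shuffling and augmentation. The run is
#' fully deterministic for a fixed config seed on a single CPU.
#'
#' @param model a [build_model()] model.
#' @param dataset non-empty list of `list(image, mask)` pairs (images
#'   `H x W x 3` in \[0, 1\], masks valid label matrices of the same
#'   spatial size).
#' @param config a [training_config()].
#' @param val_set optional held-out list of pairs; when supplied the
#'   per-epoch validation loss is recorded.
#' @param verbose print per-epoch losses.
#' @return list with the trained `model` and `history` (data frame with
#'   columns epoch, train_loss, val_loss).
#' @export
train <- function(model, dataset, config = model$config, val_set = NULL,
                  verbose = FALSE) {
  stopifnot(inherits(model, "tps_unet"), inherits(config, "training_config"))
  if (length(dataset) == 0L) stop("dataset is empty", call. = FALSE)
  for (d in dataset) {
    validate_mask(d$mask)
    check_input_shape(model, d$image)
  }
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  if (config$epochs == 0L) return(list(model = model, history = history))

  adam <- list(t = 0L,
               m = lapply(model$params, function(p)
                 list(W = p$W * 0, b = p$b * 0)),
               v = lapply(model$params, function(p)
                 list(W = p$W * 0, b = p$b * 0)))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  w <- config$class_weights

  old_seed_state <- with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(length(dataset))
      epoch_losses <- numeric()
      for (start in seq(1L, length(perm), by = config$batch_size)) {
        idx <- perm[start:min(start + config$batch_size - 1L, length(perm))]
        gacc <- NULL
        for (i in idx) {
          pair <- dataset[[i]]
          aug <- augment(pair$image, pair$mask, config)
          fw <- forward_graph(model, aug$image, keep = TRUE)
          lw <- wce_from_logits(get("logits", envir = fw$vals), aug$mask, w)
          epoch_losses <- c(epoch_losses, lw$loss)
          g <- backward_graph(model, fw, lw$dlogits)
          gacc <- if (is.null(gacc)) g else {
            for (nm in names(g)) {
              gacc[[nm]]$W <- gacc[[nm]]$W + g[[nm]]$W
              gacc[[nm]]$b <- gacc[[nm]]$b + g[[nm]]$b
            }
            gacc
          }
        }
        nb <- length(idx)
        adam$t <- adam$t + 1L
        corr1 <- 1 - b1^adam$t; corr2 <- 1 - b2^adam$t
        for (nm in names(gacc)) {
          for (fld in c("W", "b")) {
            g1 <- gacc[[nm]][[fld]] / nb
            adam$m[[nm]][[fld]] <- b1 * adam$m[[nm]][[fld]] + (1 - b1) * g1
            adam$v[[nm]][[fld]] <- b2 * adam$v[[nm]][[fld]] + (1 - b2) * g1^2
            model$params[[nm]][[fld]] <- model$params[[nm]][[fld]] -
              config$learning_rate * (adam$m[[nm]][[fld]] / corr1) /
              (sqrt(adam$v[[nm]][[fld]] / corr2) + eps)
          }
        }
      }
      val_loss <- NA_real_
      if (!is.null(val_set)) {
        vl <- vapply(val_set, function(pair) {
          fw <- forward_graph(model, pair$image, keep = FALSE)
          wce_from_logits(get("logits", envir = fw$vals), pair$mask, w)$loss
        }, 0)
        val_loss <- mean(vl)
      }
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = mean(epoch_losses), val_loss = val_loss))
      if (verbose) {
        message(sprintf("epoch %d/%d: train loss %.5f%s", epoch,
                        config$epochs, mean(epoch_losses),
                        if (is.na(val_loss)) ""
                        else sprintf(", val loss %.5f", val_loss)))
      }
    }
    NULL
  })

  list(model = model, history = history)
}

#' Save and load model checkpoints
#'
#' Checkpoints are self-describing: they carry a format tag, the package
#' version, the architecture variant, an echo of the training config and
#' the parameter blobs.
#'
#' @param model a `tps_unet` model.
#' @param path checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "tps_unet"))
  saveRDS(list(format = "pdl1tps_checkpoint", format_version = 1L,
               package_version = as.character(utils::packageVersion("pdl1tps")),
               variant = model$variant, config = model$config,
               params = model$params),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "pdl1tps_checkpoint")) {
    stop("not a pdl1tps checkpoint: ", path, call. = FALSE)
  }
  model <- build_model(ck$config, ck$variant)
  for (nm in names(ck$params)) {
    stopifnot(all(dim(model$params[[nm]]$W) == dim(ck$params[[nm]]$W)))
  }
  model$params <- ck$params
  model
}

#' Write a training history to CSV
#'
#' @param history the history data frame returned by [train()].
#' @param path output CSV path (columns epoch, train_loss, val_loss).
#' @export
write_history <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
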