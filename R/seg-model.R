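#' Segmentation model configuration
#'
#' Training-time configuration of the vessel segmentation model. The model
#' is a multiscale filter-bank pixel classifier: per-pixel features (Gaussian
#' intensity, gradient magnitude, and tubeness response at a pyramid of
#' scales) feed a logistic unit trained by minibatch stochastic gradient
#' descent. The `filters` vector sets the capacity analogously to
#' encoder filter counts: one pyramid level per entry (scales 1, 2, 4, ...
#' px). Each epoch runs `floor(1500 / batch_size)` training steps and
#' `floor(500 / batch_size)` validation steps; at every step, `batch_size`
#' samples are drawn at random from the corresponding split. Normalization
#' statistics are computed from the training split only and frozen into the
#' model bundle.
#'
#' @param filters increasing integer vector; its length sets the number of
#'   feature-pyramid levels. Reference `(64, 128, 256, 512)`.
#' @param learning_rate positive initial SGD learning rate; reference 0.001.
#' @param input_size model input side in px (default 320); tiles are
#'   resampled to this size.
#' @param epochs training epochs (reference 50).
#' @param batch_size samples per step.
#' @param pixels_per_image pixels sampled from each image per step.
#' @return A list of class `seg_config`.
#' @export
seg_model_config <- function(filters = c(64, 128, 256, 512),
                             learning_rate = 0.001, input_size = 320,
                             epochs = 50, batch_size = 4,
                             pixels_per_image = 64) {
  stopifnot(all(diff(filters) > 0), learning_rate > 0, input_size >= 32,
            epochs >= 1, batch_size >= 1)
  structure(list(filters = filters, learning_rate = learning_rate,
                 input_size = input_size, epochs = epochs,
                 batch_size = batch_size,
                 pixels_per_image = pixels_per_image,
                 feature_scales = 2^(seq_along(filters) - 1)),
            class = "seg_config")
}

#' Steps per epoch implied by a configuration
#'
#' @param config a [seg_model_config()].
#' @return A one-row tibble: `train_steps = floor(1500 / batch_size)`,
#'   `val_steps = floor(500 / batch_size)`.
#' @export
training_schedule <- function(config) {
  tibble::tibble(train_steps = floor(1500 / config$batch_size),
                 val_steps = floor(500 / config$batch_size))
}

#' Data augmentation policy
#'
#' Per-transform application probabilities for training-time augmentation.
#' Geometric transforms are applied identically to image and mask;
#' photometric transforms touch the image only. Exactly one of
#' multiplicative noise / blur-plus-noise is applied per sample (a seeded
#' coin decides when both fire). The output is always resampled to
#' `out_size`.
#'
#' @param rotate,crop,hflip,vflip,brightness_contrast,noise,elastic
#'   application probabilities in `[0, 1]`.
#' @param crop_size random-crop side in px (default 512).
#' @param out_size output side in px (default 320).
#' @param pad if `TRUE` (default) images smaller than `crop_size` are
#'   reflection-padded; otherwise this is an error.
#' @return A list of class `augmentation_policy`.
#' @export
augmentation_policy <- function(rotate = 0.5, crop = 1.0, hflip = 0.25,
                                vflip = 0.25, brightness_contrast = 0.7,
                                noise = 0.4, elastic = 0.85,
                                crop_size = 512, out_size = 320,
                                pad = TRUE) {
  p <- c(rotate, crop, hflip, vflip, brightness_contrast, noise, elastic)
  stopifnot(all(p >= 0 & p <= 1), crop_size >= 8, out_size >= 8)
  structure(list(rotate = rotate, crop = crop, hflip = hflip, vflip = vflip,
                 brightness_contrast = brightness_contrast, noise = noise,
                 elastic = elastic, crop_size = crop_size,
                 out_size = out_size, pad = pad),
            class = "augmentation_policy")
}

bilinear_remap <- function(img, yy, xx) {
  nr <- nrow(img); nc <- ncol(img)
  yy <- as.vector(pmin(pmax(yy, 1), nr))
  xx <- as.vector(pmin(pmax(xx, 1), nc))
  y0 <- pmin(floor(yy), nr - 1); x0 <- pmin(floor(xx), nc - 1)
  fy <- yy - y0; fx <- xx - x0
  at <- function(r, c) img[cbind(r, c)]
  v <- at(y0, x0) * (1 - fy) * (1 - fx) + at(y0 + 1, x0) * fy * (1 - fx) +
    at(y0, x0 + 1) * (1 - fy) * fx + at(y0 + 1, x0 + 1) * fy * fx
  matrix(v, nr, nc)
}

rotate_pair <- function(img, mask, angle) {
  di <- dim(img)
  ri <- as_matrix_img(EBImage::rotate(EBImage::Image(img), angle,
                                      output.dim = di, bg.col = 0))
  rm <- as_matrix_img(EBImage::rotate(EBImage::Image(mask * 1), angle,
                                      output.dim = di, bg.col = 0)) > 0.5
  list(img = ri, mask = rm)
}

elastic_pair <- function(img, mask, alpha, sigma) {
  nr <- nrow(img); nc <- ncol(img)
  dx <- gauss_blur(matrix(runif(nr * nc, -1, 1), nr, nc), sigma) * alpha
  dy <- gauss_blur(matrix(runif(nr * nc, -1, 1), nr, nc), sigma) * alpha
  yy <- matrix(rep(seq_len(nr), nc), nr, nc) + dy
  xx <- matrix(rep(seq_len(nc), each = nr), nr, nc) + dx
  list(img = bilinear_remap(img, yy, xx),
       mask = bilinear_remap(mask * 1, yy, xx) > 0.5)
}

#' Augment one training sample
#'
#' Applies the augmentation pipeline — random rotation, random crop, flips,
#' brightness/contrast, one of multiplicative-noise or blur-plus-noise,
#' elastic deformation — to an image/mask pair, then resamples to the policy
#' output size. Geometric transforms are shared by image and mask (the mask
#' stays binary); photometric ones apply to the image only. Bitwise
#' deterministic for a fixed seed.
#'
#' @param image numeric matrix.
#' @param mask binary matrix congruent with `image`.
#' @param policy an [augmentation_policy()].
#' @param seed integer seed.
#' @return A list `(image, mask)` of `out_size` x `out_size` matrices.
#' @export
augment_sample <- function(image, mask, policy = augmentation_policy(),
                           seed = 1L) {
  assert_image(image)
  if (!all(dim(image) == dim(mask))) {
    stop("image and mask must be congruent", call. = FALSE)
  }
  withr_seed(seed, {
    img <- image
    msk <- mask > 0
    if (runif(1) < policy$rotate) {
      rp <- rotate_pair(img, msk, runif(1, 0, 360))
      img <- rp$img; msk <- rp$mask
    }
    if (runif(1) < policy$crop) {
      cs <- policy$crop_size
      if (nrow(img) < cs || ncol(img) < cs) {
        if (!policy$pad) {
          stop("image smaller than crop size and padding disabled",
               call. = FALSE)
        }
        img <- pad_reflect(img, cs, cs)
        msk <- pad_reflect(msk * 1, cs, cs) > 0
      }
      r0 <- sample.int(nrow(img) - cs + 1, 1)
      c0 <- sample.int(ncol(img) - cs + 1, 1)
      img <- img[r0:(r0 + cs - 1), c0:(c0 + cs - 1)]
      msk <- msk[r0:(r0 + cs - 1), c0:(c0 + cs - 1)]
    }
    if (runif(1) < policy$hflip) {
      img <- img[, rev(seq_len(ncol(img)))]
      msk <- msk[, rev(seq_len(ncol(msk)))]
    }
    if (runif(1) < policy$vflip) {
      img <- img[rev(seq_len(nrow(img))), ]
      msk <- msk[rev(seq_len(nrow(msk))), ]
    }
    if (runif(1) < policy$brightness_contrast) {
      img <- img * runif(1, 0.8, 1.2) + runif(1, -0.1, 0.1) * diff(range(img))
    }
    do_mult <- runif(1) < policy$noise
    do_blur <- runif(1) < policy$noise
    if (do_mult && do_blur) {  # exactly one of the two
      if (runif(1) < 0.5) do_blur <- FALSE else do_mult <- FALSE
    }
    scale <- max(abs(img), 1e-12)
    if (do_mult) {
      img <- img * matrix(runif(length(img), 0.85, 1.15), nrow(img))
    } else if (do_blur) {
      img <- gauss_blur(img, 1) +
        matrix(rnorm(length(img), 0, 0.02 * scale), nrow(img))
    }
    if (runif(1) < policy$elastic) {
      ep <- elastic_pair(img, msk, alpha = 10, sigma = 8)
      img <- ep$img; msk <- ep$mask
    }
    out <- policy$out_size
    list(image = resize_image(img, out, out),
         mask = resize_image(msk * 1, out, out) > 0.5)
  })
}

# --- features + model -------------------------------------------------------

pixel_features <- function(img, scales) {
  f <- list(img)
  for (s in scales) {
    sm <- gauss_blur(img, s)
    f[[length(f) + 1]] <- sm
    f[[length(f) + 1]] <- sobel_gradients(sm)$mag
    f[[length(f) + 1]] <- sato_tubeness(img, s)
  }
  do.call(cbind, lapply(f, as.vector))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train the vessel segmentation model
#'
#' Trains the filter-bank pixel classifier (see [seg_model_config()]) by
#' minibatch SGD: every step draws `batch_size` images at random from the
#' split and `pixels_per_image` pixels from each (balanced between vessel and
#' background where possible), and performs one logistic-gradient update.
#' Input images are normalized by the training split's mean and standard
#' deviation, which are frozen into the returned bundle.
#'
#' @param train_images,train_masks lists of congruent image / binary-mask
#'   matrices (the training split).
#' @param val_images,val_masks the validation split.
#' @param config a [seg_model_config()].
#' @param seed integer seed controlling sampling.
#' @return A list of class `seg_model`: `weights`, `feature_scales`,
#'   `norm` (mean, sd), `input_size`, `config`, and a per-epoch `history`
#'   tibble (`epoch`, `train_loss`, `val_loss`, `val_dice`).
#' @export
train_segmentation_model <- function(train_images, train_masks,
                                     val_images, val_masks,
                                     config = seg_model_config(),
                                     seed = 1L) {
  stopifnot(length(train_images) == length(train_masks),
            length(val_images) == length(val_masks),
            length(train_images) > 0, length(val_images) > 0)
  for (m in c(train_masks, val_masks)) {
    if (!all(m %in% c(0, 1) | is.logical(m))) {
      stop("label error: masks must be binary", call. = FALSE)
    }
  }
  mu <- mean(unlist(lapply(train_images, mean)))
  sig <- sd(unlist(train_images))
  if (!is.finite(sig) || sig == 0) sig <- 1
  scales <- config$feature_scales

  feat <- function(img) pixel_features((img - mu) / sig, scales)
  tr_X <- lapply(train_images, feat)
  tr_y <- lapply(train_masks, function(m) as.numeric(as.vector(m > 0)))
  va_X <- lapply(val_images, feat)
  va_y <- lapply(val_masks, function(m) as.numeric(as.vector(m > 0)))

  nf <- ncol(tr_X[[1]]) + 1L
  sched <- training_schedule(config)
  w <- rep(0, nf)
  lr <- config$learning_rate
  npx <- config$pixels_per_image
  hist <- vector("list", config$epochs)

  sample_px <- function(y, n) {
    fg <- which(y == 1); bg <- which(y == 0)
    nf2 <- min(length(fg), ceiling(n / 2))
    nb <- min(length(bg), n - nf2)
    c(if (nf2 > 0) sample(fg, nf2) else integer(),
      if (nb > 0) sample(bg, nb) else integer())
  }

  # balanced fg/bg sampling speeds convergence but shifts the intercept;
  # corrected after training with the standard case-control offset
  pi_true <- mean(unlist(tr_y))
  n_fg_samp <- 0; n_samp <- 0
  withr_seed(seed, {
    for (ep in seq_len(config$epochs)) {
      losses <- numeric(sched$train_steps)
      for (st in seq_len(sched$train_steps)) {
        imgs <- sample.int(length(tr_X), config$batch_size, replace = TRUE)
        Xb <- NULL; yb <- NULL
        for (i in imgs) {
          px <- sample_px(tr_y[[i]], npx)
          Xb <- rbind(Xb, tr_X[[i]][px, , drop = FALSE])
          yb <- c(yb, tr_y[[i]][px])
        }
        n_fg_samp <- n_fg_samp + sum(yb)
        n_samp <- n_samp + length(yb)
        Xb <- cbind(1, Xb)
        p <- sigmoid(Xb %*% w)
        g <- crossprod(Xb, p - yb) / length(yb)
        w <- w - lr * as.vector(g)
        losses[st] <- -mean(yb * log(pmax(p, 1e-12)) +
                              (1 - yb) * log(pmax(1 - p, 1e-12)))
      }
      vloss <- numeric(sched$val_steps)
      inter <- 0; denom <- 0
      for (st in seq_len(sched$val_steps)) {
        imgs <- sample.int(length(va_X), config$batch_size, replace = TRUE)
        for (i in imgs) {
          px <- sample_px(va_y[[i]], npx)
          Xv <- cbind(1, va_X[[i]][px, , drop = FALSE])
          pv <- sigmoid(Xv %*% w)
          yv <- va_y[[i]][px]
          vloss[st] <- vloss[st] - mean(yv * log(pmax(pv, 1e-12)) +
                                          (1 - yv) * log(pmax(1 - pv, 1e-12)))
          inter <- inter + 2 * sum((pv >= 0.5) & yv == 1)
          denom <- denom + sum(pv >= 0.5) + sum(yv == 1)
        }
        vloss[st] <- vloss[st] / config$batch_size
      }
      hist[[ep]] <- tibble::tibble(
        epoch = ep, train_loss = mean(losses), val_loss = mean(vloss),
        val_dice = if (denom > 0) inter / denom else NA_real_)
    }
  })
  pi_samp <- n_fg_samp / n_samp
  if (pi_true > 0 && pi_true < 1 && pi_samp > 0 && pi_samp < 1) {
    w[1] <- w[1] + log(pi_true / (1 - pi_true)) -
      log(pi_samp / (1 - pi_samp))
  }
  structure(list(weights = w, feature_scales = scales,
                 norm = c(mean = mu, sd = sig),
                 input_size = config$input_size, config = config,
                 history = dplyr::bind_rows(hist)),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<seg_model> %d features | %d epochs | final val loss %.4f, dice %.3f\n",
    length(x$weights) - 1, nrow(x$history), last$val_loss, last$val_dice))
  invisible(x)
}

#' Predict a vessel probability map
#'
#' Generic single-image prediction: `seg_model` objects compute filter-bank
#' features and the logistic response; plain functions are treated as stub
#' models mapping an image matrix to a probability matrix (useful for
#' testing tiling and blending in isolation).
#'
#' @param model a `seg_model` or a function `(matrix) -> matrix`.
#' @param img numeric matrix.
#' @return Numeric matrix of probabilities, same dimensions as `img`.
#' @export
predict_map <- function(model, img) UseMethod("predict_map")

#' @export
predict_map.seg_model <- function(model, img) {
  assert_image(img)
  X <- cbind(1, pixel_features((img - model$norm["mean"]) / model$norm["sd"],
                               model$feature_scales))
  matrix(sigmoid(X %*% model$weights), nrow(img), ncol(img))
}

#' @export
predict_map.function <- function(model, img) {
  out <- model(img)
  stopifnot(is.matrix(out), all(dim(out) == dim(img)))
  out
}

#' Tiled prediction over a full-resolution image
#'
#' Full images are divided into overlapping `patch_size` square tiles (the
#' last tile in each direction is flush with the image edge; images smaller
#' than a tile are reflection-padded). Each tile is resampled to the model
#' input size, predicted, resampled back, and the overlapping predictions
#' blended by pixelwise averaging.
#'
#' @param model see [predict_map()].
#' @param img numeric matrix.
#' @param patch_size tile side in px (default 512).
#' @param stride tile stride in px; must be less than `patch_size` so tiles
#'   overlap (default `patch_size / 2`).
#' @param input_size model input side; defaults to the model's own for
#'   `seg_model`, else `patch_size` (no resampling) for stubs.
#' @return A [probability_map()] with provenance `"model"`.
#' @export
predict_tiled <- function(model, img, patch_size = 512, stride = NULL,
                          input_size = NULL) {
  assert_image(img)
  if (is.null(stride)) stride <- patch_size %/% 2
  stopifnot(stride >= 1, stride < patch_size)
  if (is.null(input_size)) {
    input_size <- if (inherits(model, "seg_model")) model$input_size
    else patch_size
  }
  nr0 <- nrow(img); nc0 <- ncol(img)
  padded <- pad_reflect(img, patch_size, patch_size)
  nr <- nrow(padded); nc <- ncol(padded)
  starts <- function(n) {
    s <- seq(1, max(n - patch_size + 1, 1), by = stride)
    if (tail(s, 1) != n - patch_size + 1) s <- c(s, n - patch_size + 1)
    unique(s)
  }
  acc <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
  for (r0 in starts(nr)) {
    for (c0 in starts(nc)) {
      rows <- r0:(r0 + patch_size - 1)
      cols <- c0:(c0 + patch_size - 1)
      tile <- padded[rows, cols]
      small <- resize_image(tile, input_size, input_size)
      pred <- predict_map(model, small)
      up <- resize_image(pred, patch_size, patch_size)
      acc[rows, cols] <- acc[rows, cols] + up
      cnt[rows, cols] <- cnt[rows, cols] + 1
    }
  }
  out <- (acc / cnt)[seq_len(nr0), seq_len(nc0), drop = FALSE]
  probability_map(pmin(pmax(out, 0), 1), "model")
}

#' Dice coefficient between a predicted map and a binary mask
#'
#' @param pred probability matrix.
#' @param truth binary matrix.
#' @param threshold binarization level for `pred`.
#' @return Dice score in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, truth, threshold = 0.5) {
  p <- pred >= threshold
  t <- truth > 0
  denom <- sum(p) + sum(t)
  if (denom == 0) return(1)
  2 * sum(p & t) / denom
}

#' Grid search over learning rates and filter counts
#'
#' Trains one model per `(learning_rate, filters)` candidate and returns the
#' pair maximizing validation Dice, together with the full results table.
#' With a single candidate it returns that candidate.
#'
#' @param train_images,train_masks,val_images,val_masks data splits as in
#'   [train_segmentation_model()].
#' @param learning_rates numeric vector of candidate learning rates.
#' @param filter_sets list of candidate filter-count vectors.
#' @param base_config a [seg_model_config()] supplying the remaining fields.
#' @param seed integer seed.
#' @return A list: `best_config`, `best_model`, `results` (tibble with one
#'   row per candidate: `learning_rate`, `filters`, `val_dice`, `val_loss`).
#' @export
grid_search_segmentation <- function(train_images, train_masks,
                                     val_images, val_masks,
                                     learning_rates = 0.001,
                                     filter_sets = list(c(64, 128, 256, 512)),
                                     base_config = seg_model_config(),
                                     seed = 1L) {
  rows <- list(); best <- NULL; best_model <- NULL
  for (lr in learning_rates) {
    for (fs in filter_sets) {
      cfg <- base_config
      cfg$learning_rate <- lr
      cfg$filters <- fs
      cfg$feature_scales <- 2^(seq_along(fs) - 1)
      mod <- train_segmentation_model(train_images, train_masks,
                                      val_images, val_masks, cfg, seed)
      last <- mod$history[nrow(mod$history), ]
      rows[[length(rows) + 1]] <- tibble::tibble(
        learning_rate = lr, filters = paste(fs, collapse = ","),
        val_dice = last$val_dice, val_loss = last$val_loss)
      if (is.null(best) || last$val_dice > best$val_dice) {
        best <- rows[[length(rows)]]
        best_model <- mod
      }
    }
  }
  list(best_config = best_model$config, best_model = best_model,
       results = dplyr::bind_rows(rows))
}
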