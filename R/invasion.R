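#' Per-plane focus features for invasion classification
#'
#' A Z-plane "shows invasion" when it contains a sufficient amount of
#' in-focus cell area: cells that have invaded down to that depth are sharp,
#' while out-of-focus planes carry only blur from cells above. These
#' sharpness statistics feed the invasion classifier: variance of the
#' Laplacian, Tenengrad gradient energy, mean and 95th percentile of local
#' variance, high-frequency energy ratio, and global intensity spread.
#'
#' @param img numeric matrix (one Z-plane).
#' @return Named numeric vector of 6 features.
#' @export
invasion_features <- function(img) {
  assert_image(img)
  rng <- diff(range(img))
  if (rng == 0) {
    return(c(lap_var = 0, tenengrad = 0, locvar_mean = 0, locvar_q95 = 0,
             highfreq = 0, spread = 0))
  }
  x <- (img - min(img)) / rng
  lap <- laplacian_filter(x)
  g <- sobel_gradients(x)$mag
  lv <- local_variance(x, 7)
  blur <- gauss_blur(x, 3)
  hf <- x - blur
  c(lap_var = stats::var(as.vector(lap)),
    tenengrad = mean(g^2),
    locvar_mean = mean(lv),
    locvar_q95 = as.numeric(quantile(lv, 0.95)),
    highfreq = mean(hf^2) / max(mean(blur^2), 1e-12),
    spread = sd(as.vector(x)))
}

augment_plane <- function(img, k, flip_h, flip_v) {
  out <- img
  if (k > 0) for (i in seq_len(k)) out <- t(out[rev(seq_len(nrow(out))), ])
  if (flip_h) out <- out[, rev(seq_len(ncol(out)))]
  if (flip_v) out <- out[rev(seq_len(nrow(out))), ]
  out
}

#' Train the invasion-plane classifier
#'
#' Binary classifier deciding, per Z-plane, whether the plane shows invaded
#' (in-focus) cells. Planes are expanded by seeded augmentation (rotations by
#' multiples of 90 degrees plus horizontal/vertical flips), reduced to focus
#' features ([invasion_features()]), standardized, and fit with a
#' single-hidden-layer neural network whose width and training length are
#' configurable. A stratified held-out split reports accuracy achieved on
#' unseen planes.
#'
#' @param images list of plane matrices.
#' @param labels logical/0-1 vector: `TRUE` = invaded. Both classes must be
#'   present.
#' @param hidden hidden units (default 8).
#' @param epochs optimizer iteration cap (default 200).
#' @param augment_per_image additional augmented copies per plane (default 3).
#' @param holdout fraction of planes held out for evaluation (default 0.2).
#' @param seed integer seed.
#' @return A list of class `invasion_classifier`: `fit` (nnet), `center`,
#'   `scale`, `holdout_accuracy`, `n_train`.
#' @export
train_invasion_classifier <- function(images, labels, hidden = 8,
                                      epochs = 200, augment_per_image = 3,
                                      holdout = 0.2, seed = 1L) {
  stopifnot(length(images) == length(labels))
  y <- as.integer(labels > 0)
  if (length(unique(y)) < 2) {
    stop("label error: both classes must be present", call. = FALSE)
  }
  withr_seed(seed, {
    # stratified holdout split
    idx1 <- which(y == 1); idx0 <- which(y == 0)
    h1 <- sample(idx1, max(1, floor(length(idx1) * holdout)))
    h0 <- sample(idx0, max(1, floor(length(idx0) * holdout)))
    hold <- c(h1, h0)
    tr <- setdiff(seq_along(y), hold)

    expand <- function(ids) {
      feats <- list(); ys <- integer()
      for (i in ids) {
        feats[[length(feats) + 1]] <- invasion_features(images[[i]])
        ys <- c(ys, y[i])
        for (a in seq_len(augment_per_image)) {
          im <- augment_plane(images[[i]], sample(0:3, 1),
                              runif(1) < 0.5, runif(1) < 0.5)
          feats[[length(feats) + 1]] <- invasion_features(im)
          ys <- c(ys, y[i])
        }
      }
      list(X = do.call(rbind, feats), y = ys)
    }
    trd <- expand(tr)
    ctr <- colMeans(trd$X)
    scl <- apply(trd$X, 2, sd)
    scl[scl == 0] <- 1
    Xs <- scale(trd$X, ctr, scl)
    fit <- nnet::nnet(Xs, trd$y, size = hidden, decay = 1e-3,
                      maxit = epochs, entropy = TRUE, trace = FALSE)
    model <- structure(list(fit = fit, center = ctr, scale = scl,
                            n_train = length(tr)),
                       class = "invasion_classifier")
    Xh <- do.call(rbind, lapply(hold, function(i) {
      invasion_features(images[[i]])
    }))
    ph <- predict_invasion(model, NULL, features = Xh)
    model$holdout_accuracy <- mean((ph >= 0.5) == (y[hold] == 1))
    model
  })
}

#' @export
print.invasion_classifier <- function(x, ...) {
  cat(sprintf(
    "<invasion_classifier> %d training planes | held-out accuracy %.3f\n",
    x$n_train, x$holdout_accuracy))
  invisible(x)
}

#' Invasion probability of plane images
#'
#' @param model an `invasion_classifier`, or a function mapping a plane
#'   matrix to a probability (stub models for testing).
#' @param images list of plane matrices.
#' @param features optional precomputed feature matrix (rows = planes),
#'   bypassing `images`.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_invasion <- function(model, images, features = NULL) {
  if (is.function(model)) {
    return(vapply(images, function(im) as.numeric(model(im)), numeric(1)))
  }
  stopifnot(inherits(model, "invasion_classifier"))
  if (is.null(features)) {
    features <- do.call(rbind, lapply(images, invasion_features))
  }
  Xs <- scale(features, model$center, model$scale)
  as.numeric(predict(model$fit, Xs))
}

#' Classify every plane of a Z-stack
#'
#' Runs the invasion classifier over each plane (top plane first) and
#' thresholds the probabilities: a plane with probability greater than or
#' equal to `threshold` is classified invaded.
#'
#' @param model see [predict_invasion()].
#' @param stack a [zstack()].
#' @param threshold classification threshold (default 0.5, inclusive).
#' @return A tibble of class `invasion_call`: `plane` (0-based, top-first),
#'   `probability`, `invaded`; `threshold` kept as an attribute.
#' @export
classify_stack <- function(model, stack, threshold = 0.5) {
  stopifnot(inherits(stack, "zstack"))
  if (n_planes(stack) == 0) stop("empty input: stack has no planes",
                                 call. = FALSE)
  p <- predict_invasion(model, stack$planes)
  out <- tibble::tibble(plane = seq_along(p) - 1L, probability = p,
                        invaded = p >= threshold)
  attr(out, "threshold") <- threshold
  attr(out, "z_step_um") <- stack$z_step_um
  class(out) <- c("invasion_call", class(out))
  out
}

#' Invasion depth from per-plane calls
#'
#' Invasion depth is the distance between the top Z-plane and the deepest
#' Z-plane classified as invaded: `deepest_invaded_index * z_step_um` with
#' 0-based top-first indexing, and 0 when no plane is invaded. The deepest
#' invaded plane governs even when shallower planes are classified
#' not-invaded.
#'
#' @param call an [classify_stack()] result (or any tibble with `plane` and
#'   `invaded` columns).
#' @param z_step_um Z step in um; defaults to the value recorded in `call`.
#' @return A one-row tibble: `deepest_invaded_index` (`NA` when none) and
#'   `depth_um`.
#' @export
compute_invasion_depth <- function(call, z_step_um = NULL) {
  stopifnot(is.data.frame(call), nrow(call) > 0)
  if (is.null(z_step_um)) z_step_um <- attr(call, "z_step_um")
  stopifnot(is.numeric(z_step_um), z_step_um > 0)
  inv <- call$plane[call$invaded]
  if (length(inv) == 0) {
    return(tibble::tibble(deepest_invaded_index = NA_integer_, depth_um = 0))
  }
  deepest <- max(inv)
  tibble::tibble(deepest_invaded_index = as.integer(deepest),
                 depth_um = deepest * z_step_um)
}

#' Confusion counts
#'
#' @param tp,tn,fp,fn nonnegative counts; positive class = invaded.
#' @return A list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  v <- c(tp, tn, fp, fn)
  stopifnot(all(v >= 0), sum(v) > 0)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, and specificity
#' `TN/(TN+FP)`. Ratios with a zero denominator are reported as `NA` and
#' flagged in the `defined` column rather than silently coerced to 0.
#'
#' @param counts a [confusion_counts()].
#' @return A tibble with columns `metric`, `value`, `defined`.
#' @examples
#' classification_metrics(confusion_counts(tp = 6, tn = 42, fp = 2, fn = 0))
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  sens_def <- (tp + fn) > 0
  spec_def <- (tn + fp) > 0
  tibble::tibble(
    metric = c("accuracy", "sensitivity", "specificity"),
    value = c((tp + tn) / total,
              if (sens_def) tp / (tp + fn) else NA_real_,
              if (spec_def) tn / (tn + fp) else NA_real_),
    defined = c(TRUE, sens_def, spec_def)
  )
}
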