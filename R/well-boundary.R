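#' Canny edge detection
#'
#' Classic Canny detector: Gaussian smoothing, Sobel gradients,
#' quantized-direction non-maximum suppression, and hysteresis. The high
#' hysteresis threshold is derived from the Otsu threshold of the gradient
#' magnitudes so no absolute intensity scale is assumed; the low threshold is
#' a fixed fraction of the high one.
#'
#' @param img numeric matrix.
#' @param sigma Gaussian pre-smoothing sigma in pixels.
#' @param low_frac low hysteresis threshold as a fraction of the high one.
#' @return Logical matrix of edge pixels.
#' @export
canny_edges <- function(img, sigma = 1.4, low_frac = 0.5) {
  assert_image(img)
  sm <- gauss_blur(img, sigma)
  g <- sobel_gradients(sm)
  mag <- g$mag
  if (max(mag) <= 0) return(matrix(FALSE, nrow(img), ncol(img)))
  # quantize gradient direction into 4 sectors and suppress non-maxima
  ang <- atan2(g$gy, g$gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- floor((ang + pi / 8) / (pi / 4)) %% 4
  n1 <- mag; n2 <- mag
  # sector 0: horizontal gradient -> compare across columns, etc.
  cand <- list(
    `0` = list(c(0, 1), c(0, -1)),
    `1` = list(c(1, 1), c(-1, -1)),
    `2` = list(c(1, 0), c(-1, 0)),
    `3` = list(c(1, -1), c(-1, 1))
  )
  keep <- matrix(FALSE, nrow(img), ncol(img))
  for (s in 0:3) {
    o <- cand[[s + 1]]
    a <- shift_mat(mag, o[[1]][1], o[[1]][2])
    b <- shift_mat(mag, o[[2]][1], o[[2]][2])
    keep <- keep | (sector == s & mag >= a & mag >= b)
  }
  nms <- mag * keep
  v <- nms[nms > 0]
  # clip extreme outliers so the Otsu split tracks the bulk of the gradient
  # histogram rather than a handful of very steep pixels
  v <- pmin(v, quantile(v, 0.995))
  hi <- otsu_threshold(v)
  lo <- hi * low_frac
  strong <- nms >= hi
  weak <- nms >= lo
  if (!any(strong)) return(strong)
  # hysteresis: keep weak components containing at least one strong pixel
  lab <- label_components(weak)
  strong_labs <- unique(lab[strong])
  strong_labs <- strong_labs[strong_labs > 0]
  weak & matrix(lab %in% strong_labs, nrow(lab), ncol(lab))
}

superellipse_mask <- function(nr, nc, cx, cy, a, b, n) {
  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr), nc), nr, nc)
  (abs((xs - cx) / a))^n + (abs((ys - cy) / b))^n <= 1
}

#' Well boundary container
#'
#' Delimits the analyzable interior of a culture well, either as a
#' superellipse `|x/a|^n + |y/b|^n = 1` fitted to image edges or as a
#' fallback circle centered on the image.
#'
#' @param kind `"superellipse"` or `"circle"`.
#' @param center numeric `(x, y)` center in pixels.
#' @param a,b semi-axes in pixels (equal to the radius for a circle).
#' @param n superellipse exponent (2 for an ellipse; circles use 2).
#' @param dim image dimensions `c(nrow, ncol)` the mask is rendered in.
#' @return An object of class `well_boundary` with a logical interior `mask`.
#' @export
well_boundary <- function(kind, center, a, b, n = 2, dim) {
  stopifnot(kind %in% c("superellipse", "circle"), a > 0, b > 0, n > 0)
  mask <- superellipse_mask(dim[1], dim[2], center[1], center[2], a, b, n)
  if (!any(mask)) stop("well boundary has empty interior", call. = FALSE)
  structure(list(kind = kind, center = center, a = a, b = b, n = n,
                 mask = mask),
            class = "well_boundary")
}

#' @export
print.well_boundary <- function(x, ...) {
  cat(sprintf(
    "<well_boundary> %s | center (%.1f, %.1f) | a=%.1f b=%.1f n=%.2f | area %d px\n",
    x$kind, x$center[1], x$center[2], x$a, x$b, x$n, sum(x$mask)))
  invisible(x)
}

fit_superellipse_once <- function(xe, ye, center_prior = NULL,
                                  prior_scale = 1) {
  cx0 <- mean(range(xe)); cy0 <- mean(range(ye))
  # radial residual ((|dx/a|^n + |dy/b|^n)^(1/n) - 1): unlike the raw
  # implicit form, it has no degenerate small-n / huge-axis valley. A soft
  # center prior resolves the arc ambiguity of partially detected rims —
  # plate-reader fields are centered on their wells.
  obj <- function(par) {
    cx <- par[1]; cy <- par[2]
    a <- exp(par[3]); b <- exp(par[4]); n <- exp(par[5])
    s <- (abs((xe - cx) / a))^n + (abs((ye - cy) / b))^n
    v <- s^(1 / n) - 1
    v[!is.finite(v)] <- 1e6
    pen <- if (is.null(center_prior)) 0 else
      length(xe) * 0.05 * (((cx - center_prior[1])^2 +
                              (cy - center_prior[2])^2) / prior_scale^2)
    sum(v^2) + pen
  }
  a0 <- max(abs(xe - cx0)); b0 <- max(abs(ye - cy0))
  best <- NULL
  for (n0 in c(2, 4)) {
    fit <- tryCatch(
      stats::optim(c(cx0, cy0, log(a0), log(b0), log(n0)), obj,
                   method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) return(NULL)
  list(center = c(best$par[1], best$par[2]), a = exp(best$par[3]),
       b = exp(best$par[4]), n = exp(best$par[5]),
       rmse = sqrt(best$value / length(xe)))
}

fit_superellipse <- function(xe, ye, center_prior = NULL, prior_scale = 1) {
  fit <- fit_superellipse_once(xe, ye, center_prior, prior_scale)
  if (is.null(fit)) return(NULL)
  # one robust refit: drop edge points far from the fitted curve (texture
  # edges inside the well) and fit the rim again
  s <- (abs((xe - fit$center[1]) / fit$a))^fit$n +
    (abs((ye - fit$center[2]) / fit$b))^fit$n
  v <- s^(1 / fit$n) - 1
  keep <- is.finite(v) & abs(v) <= 2.5 * max(mad(v[is.finite(v)]), 1e-6)
  if (sum(keep) >= 100 && sum(keep) < length(xe)) {
    refit <- fit_superellipse_once(xe[keep], ye[keep], center_prior,
                                   prior_scale)
    if (!is.null(refit)) fit <- refit
  }
  fit
}

#' Detect the analyzable well boundary of a projection image
#'
#' Fits a superellipse `|x/a|^n + |y/b|^n = 1` to the Canny edges of the
#' image by least squares on the implicit form. When the edges do not
#' support a fit (fewer than `min_edges` edge pixels, an out-of-frame or
#' degenerate solution, or a residual above `max_rmse`), a circle centered
#' on the image with radius `fallback_frac * min(nrow, ncol) / 2` is used
#' instead, so the operation always succeeds.
#'
#' @param img numeric matrix, at least 64 x 64.
#' @param min_edges minimum number of Canny edge pixels required to attempt
#'   the superellipse fit.
#' @param max_rmse residual cap (RMSE of the implicit form) above which the
#'   fit is declared failed.
#' @param fallback_frac radius of the fallback circle as a fraction of
#'   `min(nrow, ncol) / 2`.
#' @return A [well_boundary()].
#' @examples
#' img <- matrix(0, 128, 128)
#' img[(row(img) - 64)^2 + (col(img) - 64)^2 < 50^2] <- 1
#' detect_well_boundary(img)
#' @export
detect_well_boundary <- function(img, min_edges = 100, max_rmse = 0.15,
                                 fallback_frac = 0.95) {
  assert_image(img)
  if (nrow(img) < 64 || ncol(img) < 64) {
    stop("image must be at least 64 x 64", call. = FALSE)
  }
  fallback <- function() {
    r <- fallback_frac * min(dim(img)) / 2
    well_boundary("circle", center = c((ncol(img) + 1) / 2,
                                       (nrow(img) + 1) / 2),
                  a = r, b = r, n = 2, dim = dim(img))
  }
  edges <- canny_edges(img)
  if (sum(edges) < min_edges) return(fallback())
  idx <- which(edges)
  ye <- (idx - 1) %% nrow(img) + 1
  xe <- (idx - 1) %/% nrow(img) + 1
  # the rim is the outermost structure: fit on outer-annulus edges so cell
  # texture in the well interior cannot drag the fit inward
  r <- sqrt((xe - (ncol(img) + 1) / 2)^2 + (ye - (nrow(img) + 1) / 2)^2)
  outer <- r >= 0.55 * min(dim(img)) / 2
  if (sum(outer) >= min_edges) {
    xe <- xe[outer]
    ye <- ye[outer]
  }
  fit <- fit_superellipse(xe, ye,
                          center_prior = c((ncol(img) + 1) / 2,
                                           (nrow(img) + 1) / 2),
                          prior_scale = 0.1 * min(dim(img)))
  ok <- !is.null(fit) && fit$rmse <= max_rmse &&
    fit$a > 4 && fit$b > 4 && fit$n > 0.5 && fit$n < 50 &&
    fit$center[1] > 1 && fit$center[1] < ncol(img) &&
    fit$center[2] > 1 && fit$center[2] < nrow(img) &&
    fit$a < ncol(img) && fit$b < nrow(img)
  if (!ok) return(fallback())
  well_boundary("superellipse", center = fit$center, a = fit$a, b = fit$b,
                n = fit$n, dim = dim(img))
}
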