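#' Fit a two-component Gaussian mixture to pixel intensities
#'
#' Projection images of labeled cells in a well have a bimodal intensity
#' histogram: a dark background mode (hydrogel, plastic) and a bright
#' foreground mode (cells). Two Gaussian components are fit to the intensity
#' sample by EM; the component with the larger mean is taken as foreground.
#' The fit supplies the foreground mean and standard deviation used by the
#' coverage threshold (see [threshold_foreground()]), which makes the
#' threshold robust to overall brightness and contrast differences between
#' images.
#'
#' @param pixels numeric vector (or matrix) of intensities; at least 100
#'   values with nonzero variance. For well images, pass only the pixels
#'   inside the well boundary so background plastic outside the well does
#'   not contaminate the background component.
#' @param seed integer seed (the EM initialization is deterministic; the seed
#'   only governs the optional subsampling of very large pixel samples).
#' @param max_sample subsample cap for the EM fit; fitting on more pixels
#'   than this changes the estimates negligibly but costs time.
#' @return A tibble of class `gmm_fit` with one row per component:
#'   `component`, `mean`, `sd`, `weight`, `foreground` (logical).
#' @examples
#' set.seed(1)
#' px <- c(rnorm(7000, 25, 5), rnorm(3000, 180, 12))
#' fit_bimodal_gmm(px)
#' @export
fit_bimodal_gmm <- function(pixels, seed = 1L, max_sample = 50000L) {
  v <- as.numeric(pixels)
  v <- v[is.finite(v)]
  if (length(v) < 100) {
    stop("need at least 100 pixels to fit the mixture", call. = FALSE)
  }
  if (sd(v) == 0) {
    stop("degenerate input: constant intensities", call. = FALSE)
  }
  if (length(v) > max_sample) {
    v <- withr_seed(seed, sample(v, max_sample))
  }
  uv <- unique(v)
  if (length(uv) == 2) {
    # exactly two intensity levels: the mixture is the empirical split
    uv <- sort(uv)
    eps <- 1e-8 * diff(uv)
    mu <- uv
    sig <- c(eps, eps)
    w <- c(mean(v == uv[1]), mean(v == uv[2]))
    bimodal <- TRUE
  } else {
    fit <- Mclust(v, G = 2, modelNames = "V", verbose = FALSE)
    if (is.null(fit)) {
      stop("degenerate input: mixture fit failed", call. = FALSE)
    }
    fit1 <- Mclust(v, G = 1, verbose = FALSE)
    # evidence for two modes: 2-component BIC beats 1-component
    bimodal <- is.null(fit1) || fit$bic > fit1$bic
    mu <- as.numeric(fit$parameters$mean)
    sig <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
    if (length(sig) == 1) sig <- rep(sig, 2)
    w <- as.numeric(fit$parameters$pro)
  }
  fg <- which.max(mu)
  out <- tibble::tibble(
    component = 1:2,
    mean = mu,
    sd = sig,
    weight = w,
    foreground = seq_len(2) == fg
  )
  attr(out, "bimodal") <- bimodal
  class(out) <- c("gmm_fit", class(out))
  out
}

# run expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

gmm_foreground <- function(fit) {
  stopifnot(inherits(fit, "gmm_fit"))
  fit[fit$foreground, ]
}

#' Threshold an image at the GMM-derived cutoff
#'
#' The cutoff intensity is `mu_foreground + lambda * sigma_foreground`.
#' With `lambda = 0` pixels at least as bright as the foreground mean pass;
#' `lambda > 0` passes fewer pixels, `lambda < 0` passes more. The
#' comparison is inclusive (`>=`), which is immaterial for continuous
#' intensities.
#'
#' @param img numeric matrix.
#' @param fit a [fit_bimodal_gmm()] result.
#' @param lambda multiplier of the foreground standard deviation; default 0.
#' @return Logical matrix: `TRUE` where the pixel passes the threshold.
#' @export
threshold_foreground <- function(img, fit, lambda = 0) {
  assert_image(img)
  fg <- gmm_foreground(fit)
  img >= fg$mean + lambda * fg$sd
}

#' Cell coverage fraction inside the well
#'
#' Counts thresholded foreground pixels inside the well boundary and divides
#' by the well interior area, the standard coverage readout for co-culture
#' well plates.
#'
#' @param mask logical matrix from [threshold_foreground()].
#' @param boundary a [well_boundary()] of the same dimensions.
#' @param lambda the lambda used to build `mask` (recorded in the output).
#' @return A one-row tibble: `cell_area_px`, `well_area_px`, `fraction`,
#'   `lambda`.
#' @export
compute_coverage <- function(mask, boundary, lambda = NA_real_) {
  stopifnot(is.matrix(mask), inherits(boundary, "well_boundary"))
  if (!all(dim(mask) == dim(boundary$mask))) {
    stop("mask and boundary dimensions differ", call. = FALSE)
  }
  well_area <- sum(boundary$mask)
  if (well_area == 0) stop("empty well boundary", call. = FALSE)
  cell_area <- sum(mask & boundary$mask)
  tibble::tibble(
    cell_area_px = as.integer(cell_area),
    well_area_px = as.integer(well_area),
    fraction = cell_area / well_area,
    lambda = lambda
  )
}

#' One-call coverage analysis of a projection image
#'
#' Detects (or accepts) the well boundary, fits the bimodal GMM on the
#' well-interior pixels, thresholds at `mu_fg + lambda * sigma_fg`, and
#' returns the coverage row. This is the per-image unit of the batch
#' pipeline.
#'
#' @param img numeric matrix (a Z-projection).
#' @param boundary optional precomputed [well_boundary()]; detected from the
#'   image when `NULL`.
#' @inheritParams threshold_foreground
#' @inheritParams fit_bimodal_gmm
#' @param keep_mask if `TRUE`, attach the thresholded mask as attribute
#'   `"mask"` for visualization.
#' @param cv_homogeneous coefficient-of-variation split for wells with no
#'   bimodal structure (see Details).
#' @return A one-row tibble as [compute_coverage()], plus `mu_fg`, `sigma_fg`
#'   and `bimodal`.
#' @details
#' The GMM threshold assumes a bimodal well: cells plus visible background.
#' Fully covered and fully empty wells are homogeneous, and forcing two
#' components onto one mode would split it and threshold away roughly half
#' of the well. When the one-component model wins on BIC the well is treated
#' as homogeneous and classified all-foreground versus all-background by its
#' intensity coefficient of variation: fluorescence has a physical zero, and
#' bright, signal-dominated wells show a much smaller relative spread than
#' dark, noise-dominated ones. `cv_homogeneous` (default 0.15) is that
#' split.
#' @export
analyze_coverage <- function(img, boundary = NULL, lambda = 0, seed = 1L,
                             keep_mask = FALSE, cv_homogeneous = 0.15) {
  assert_image(img)
  if (is.null(boundary)) boundary <- detect_well_boundary(img)
  inside <- img[boundary$mask]
  fit <- fit_bimodal_gmm(inside, seed = seed)
  if (isTRUE(attr(fit, "bimodal"))) {
    mask <- threshold_foreground(img, fit, lambda)
  } else {
    covered <- sd(inside) / max(mean(inside), 1e-12) < cv_homogeneous
    mask <- matrix(covered, nrow(img), ncol(img))
  }
  out <- compute_coverage(mask, boundary, lambda = lambda)
  fg <- gmm_foreground(fit)
  out$mu_fg <- fg$mean
  out$sigma_fg <- fg$sd
  out$bimodal <- isTRUE(attr(fit, "bimodal"))
  if (keep_mask) attr(out, "mask") <- mask & boundary$mask
  out
}
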