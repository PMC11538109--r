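#' Sato tubeness filter (2D)
#'
#' Hessian-eigenvalue line filter for bright curvilinear structures. At each
#' scale sigma the image is Gaussian-smoothed, the Hessian computed by finite
#' differences, and the response taken as `sigma^2 * |lambda2|` where lambda2
#' is the more negative eigenvalue (zero where lambda2 >= 0, i.e. where the
#' intensity profile is not ridge-like). The multiscale response is the
#' pixelwise maximum over scales.
#'
#' @param img numeric matrix.
#' @param scales vector of Gaussian scales in pixels; default `c(1, 2, 4)`,
#'   spanning vessel half-widths of roughly 1-4 px.
#' @return Numeric matrix of tubeness responses (>= 0).
#' @export
sato_tubeness <- function(img, scales = c(1, 2, 4)) {
  assert_image(img)
  out <- matrix(0, nrow(img), ncol(img))
  for (s in scales) {
    sm <- gauss_blur(img, s)
    # second differences with replicated edges: rows = y, cols = x
    dyy <- shift_rep(sm, -1, 0) + shift_rep(sm, 1, 0) - 2 * sm
    dxx <- shift_rep(sm, 0, -1) + shift_rep(sm, 0, 1) - 2 * sm
    dxy <- (shift_rep(sm, -1, -1) + shift_rep(sm, 1, 1) -
              shift_rep(sm, -1, 1) - shift_rep(sm, 1, -1)) / 4
    tr <- dxx + dyy
    det_h <- dxx * dyy - dxy * dxy
    disc <- sqrt(pmax(tr * tr / 4 - det_h, 0))
    l1 <- tr / 2 + disc
    l2 <- tr / 2 - disc  # more negative eigenvalue on bright ridges
    resp <- s^2 * pmax(-l2, 0)
    resp[l2 >= 0] <- 0
    out <- pmax(out, resp)
  }
  out
}

#' Unsharp masking
#'
#' Sharpens an image by adding back `amount` times the difference between the
#' image and its Gaussian blur: `img + amount * (img - blur(img, radius))`.
#'
#' @param img numeric matrix.
#' @param radius Gaussian sigma in pixels (default 5).
#' @param amount strength multiplier (default 1).
#' @return Numeric matrix, clamped below at 0.
#' @export
unsharp_mask <- function(img, radius = 5, amount = 1) {
  assert_image(img)
  pmax(img + amount * (img - gauss_blur(img, radius)), 0)
}

#' 2D vesselness from a Z-stack via Sato filtering
#'
#' The non-learned preparation path for Z-stack input: each plane is Sato
#' tubeness filtered and unsharp-masked, the stack is reduced by max-intensity
#' projection (preserving clearly marked vessels at varying depths), and a
#' binary vessel mask is built on the projection by Canny-seeded region
#' growing (edge pixels seed a positive-gradient growth over 8-connected
#' neighbors), closed morphologically, and cleaned of blob-like components
#' (circularity > `circ_max`). The mask is applied to the projected
#' vesselness to suppress background, and the result rescaled to `[0, 1]`.
#'
#' @param stack a [zstack()].
#' @param scales Sato scales in pixels.
#' @param unsharp_radius,unsharp_amount unsharp-mask parameters.
#' @param grow_tol region-growing tolerance: a neighbor joins when its
#'   intensity is at least the boundary pixel's intensity minus this value.
#' @param grow_smooth_sigma Gaussian sigma (px) of the smoothed copy the
#'   region growing runs on; the monotone-ascent rule needs a smooth
#'   landscape, otherwise pixel noise lets the region zig-zag uphill into
#'   the background.
#' @param close_size disc radius (px) of the morphological closing.
#' @param circ_max components with circularity above this are removed
#'   (default 0.8).
#' @param seed_quantile in addition to Canny edge pixels, pixels above this
#'   quantile of the smoothed vesselness seed the region growing. Edge
#'   detection alone can miss short, dim vessel segments entirely (no pixel
#'   of their outline clears the hysteresis threshold), which would drop them
#'   from the mask; crest pixels are unambiguous seeds.
#' @param min_area_px small disconnected mask components below this area are
#'   removed.
#' @return A `probability_map`: numeric matrix in `[0, 1]` with attribute
#'   `provenance = "sato"`.
#' @export
sato_vesselness_2d <- function(stack, scales = c(1, 2, 4),
                               unsharp_radius = 5, unsharp_amount = 1,
                               grow_tol = 0, grow_smooth_sigma = 1.5,
                               seed_quantile = 0.95, close_size = 3,
                               circ_max = 0.8, min_area_px = 80) {
  stopifnot(inherits(stack, "zstack"))
  filtered <- purrr::map(stack$planes, function(p) {
    unsharp_mask(sato_tubeness(p, scales), unsharp_radius, unsharp_amount)
  })
  proj <- Reduce(pmax, filtered)
  if (max(proj) <= min(proj)) {
    return(probability_map(proj * 0, "sato"))
  }
  sm <- gauss_blur(proj, grow_smooth_sigma)
  seeds <- canny_edges(proj) | (sm >= quantile(sm, seed_quantile))
  mask <- .region_grow(sm, seeds, grow_tol)
  kern <- EBImage::makeBrush(2 * close_size + 1, shape = "disc")
  mask <- as_matrix_img(EBImage::closing(EBImage::Image(mask * 1),
                                         kern)) > 0
  mask <- filter_components_circularity(mask, circ_max = circ_max,
                                        min_area_px = min_area_px)
  out <- sm * mask
  probability_map(rescale01(out), "sato")
}

#' Probability-map container
#'
#' @param img numeric matrix with values in `[0, 1]`.
#' @param provenance `"model"` (learned segmentation) or `"sato"`.
#' @return The matrix with class `probability_map` and a `provenance`
#'   attribute.
#' @export
probability_map <- function(img, provenance = c("model", "sato")) {
  assert_image(img)
  provenance <- match.arg(provenance)
  if (min(img) < -1e-9 || max(img) > 1 + 1e-9) {
    stop("probability map values must lie in [0, 1]", call. = FALSE)
  }
  structure(pmin(pmax(img, 0), 1), provenance = provenance,
            class = c("probability_map", "matrix", "array"))
}

# Remove connected components whose circularity exceeds circ_max, plus
# (optionally) small disconnected components below min_area_px.
filter_components_circularity <- function(mask, circ_max = 0.8,
                                          min_area_px = 0) {
  lab <- label_components(mask)
  nlab <- max(lab)
  if (nlab == 0) return(mask > 0)
  keep <- mask > 0
  for (i in seq_len(nlab)) {
    comp <- lab == i
    if (sum(comp) < min_area_px || circularity(comp) > circ_max) {
      keep[comp] <- FALSE
    }
  }
  keep
}

# Remove components whose 1-px skeleton has no junction (>= 3 skeleton
# neighbors under 8-connectivity): blobs and bare segments carry no branching.
filter_components_junctionless <- function(mask) {
  lab <- label_components(mask)
  nlab <- max(lab)
  if (nlab == 0) return(mask > 0)
  keep <- mask > 0
  skel <- thin_skeleton(mask)
  nb <- neighbor_count8(skel)
  junction <- skel == 1 & nb >= 3
  for (i in seq_len(nlab)) {
    comp <- lab == i
    if (!any(junction & comp)) keep[comp] <- FALSE
  }
  keep
}

#' Medial-axis centerline weights
#'
#' For each pixel of a binary vessel mask, the weight
#' `d_bg / (d_bg + d_medial)` — where `d_bg` is the Euclidean distance to the
#' nearest background pixel and `d_medial` the distance to the nearest
#' medial-axis (1-px skeleton) pixel — equals 1 on the medial axis, 0 at the
#' component border, and 0.5 midway. It is a distance transform relative to
#' the local vessel width, used to pull segmentation probabilities into
#' focus on the centerlines.
#'
#' @param mask logical or 0/1 matrix.
#' @return Numeric matrix of weights in `[0, 1]`; 0 outside the mask.
#' @export
medial_axis_weights <- function(mask) {
  m <- mask > 0
  if (!any(m)) return(matrix(0, nrow(mask), ncol(mask)))
  skel <- thin_skeleton(m)
  d_bg <- dist_to_zero(m)
  d_med <- dist_to_zero(1 - skel)
  denom <- d_bg + d_med
  w <- ifelse(denom > 0, d_bg / denom, 1)
  w[!m] <- 0
  w
}

#' Refine a vessel probability map for graph extraction
#'
#' Post-processing between the segmentation model and Morse-skeleton
#' extraction: (1) binarize the map at `p >= 0.5`; (2) remove connected
#' components that are blob-like (circularity `4*pi*A/P^2 > 0.8`) or whose
#' 1-px skeleton has no junction; (3) apply the surviving mask to the
#' probabilities; (4) multiply by the medial-axis weights
#' `d_bg / (d_bg + d_medial)` so that bright ridges coincide with vessel
#' centerlines, which the ridge extractor assumes. The output never exceeds
#' the input pixelwise.
#'
#' @param prob a [probability_map()] (or matrix in `[0, 1]`).
#' @param circ_max circularity cutoff (default 0.8).
#' @param threshold binarization level (default 0.5).
#' @return A `probability_map` with provenance preserved.
#' @export
refine_probability_map <- function(prob, circ_max = 0.8, threshold = 0.5) {
  provenance <- attr(prob, "provenance")
  if (is.null(provenance)) provenance <- "model"
  img <- unclass(prob)
  attributes(img) <- list(dim = dim(prob))
  assert_image(img)
  mask <- img >= threshold
  if (!any(mask)) {
    return(probability_map(img * 0, provenance))
  }
  mask <- filter_components_circularity(mask, circ_max)
  mask <- filter_components_junctionless(mask)
  if (!any(mask)) {
    return(probability_map(img * 0, provenance))
  }
  w <- medial_axis_weights(mask)
  probability_map(img * mask * w, provenance)
}
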