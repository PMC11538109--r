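# Seeded, ground-truthed synthetic fixtures for every pipeline stage:
# well projections with known coverage, invasion Z-stacks with a known
# deepest in-focus plane, and rendered vessel trees with exact branch
# lengths. Ground truths are exact by construction, never estimated.

#' Synthetic well-projection fixture
#'
#' Renders a plate-well projection: a disk- (or superellipse-) shaped well on
#' dark plastic, with a requested fraction of the well interior covered by
#' bright foreground (cells) and the rest by dim background (hydrogel). The
#' foreground region is a smooth random field thresholded at the exact
#' quantile, so the realized fraction matches the request to within one
#' pixel's worth of area. Foreground and background intensities follow the
#' separability rule `|mu_fg - mu_bg| > 3 * sigma`.
#'
#' @param fraction requested coverage fraction in `[0, 1]`.
#' @param size image side in px (default 512).
#' @param well_shape `"circle"` or `"superellipse"`.
#' @param well_radius_frac well semi-axis as a fraction of `size / 2`.
#' @param exponent superellipse exponent when `well_shape = "superellipse"`.
#' @param fg_mean,fg_sd,bg_mean,bg_sd,plastic_mean,plastic_sd intensity
#'   distributions (arbitrary units).
#' @param blob_scale smoothing scale (px) of the random foreground field;
#'   larger values give larger contiguous cell patches.
#' @param seed integer seed; output is bit-reproducible.
#' @return A list: `image`, `true_fraction` (realized), `boundary`
#'   (a [well_boundary()]).
#' @export
make_well_fixture <- function(fraction, size = 512, well_shape = "circle",
                              well_radius_frac = 0.84, exponent = 4,
                              fg_mean = 180, fg_sd = 12,
                              bg_mean = 25, bg_sd = 5,
                              plastic_mean = 5, plastic_sd = 2,
                              blob_scale = 12, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1, size >= 64)
  if (abs(fg_mean - bg_mean) <= 3 * max(fg_sd, bg_sd)) {
    stop("spec error: foreground and background must satisfy ",
         "|mu_fg - mu_bg| > 3 * sigma", call. = FALSE)
  }
  r <- well_radius_frac * size / 2
  boundary <- well_boundary(
    kind = if (well_shape == "circle") "circle" else "superellipse",
    center = c((size + 1) / 2, (size + 1) / 2),
    a = r, b = r, n = if (well_shape == "circle") 2 else exponent,
    dim = c(size, size))
  withr_seed(seed, {
    img <- matrix(rnorm(size * size, plastic_mean, plastic_sd), size, size)
    well <- boundary$mask
    nw <- sum(well)
    img[well] <- rnorm(nw, bg_mean, bg_sd)
    n_fg <- round(fraction * nw)
    if (n_fg > 0) {
      field <- gauss_blur(matrix(rnorm(size * size), size, size), blob_scale)
      fv <- field[well]
      cut <- sort(fv, decreasing = TRUE)[n_fg]
      fg_sel <- well & field >= cut
      # exact count despite threshold ties
      extra <- sum(fg_sel) - n_fg
      if (extra > 0) {
        idx <- which(fg_sel)
        fg_sel[idx[seq_len(extra)]] <- FALSE
      }
      img[fg_sel] <- rnorm(sum(fg_sel), fg_mean, fg_sd)
      n_fg <- sum(fg_sel)
    }
    img <- pmax(img, 0)
    list(image = img, true_fraction = n_fg / nw, boundary = boundary)
  })
}

#' Synthetic invasion Z-stack fixture
#'
#' Emulates the defocus structure of invasion stacks: planes at or above the
#' deepest invaded index carry sharp cell speckle, deeper planes carry only
#' the heavily blurred glow of cells above plus sensor noise. The true depth
#' is `deepest_invaded_index * z_step_um`, exact by construction.
#'
#' @param deepest_invaded_index 0-based index of the deepest invaded plane
#'   (top plane = 0), or `NA` for a stack with no invasion.
#' @param n_planes plane count (default 10).
#' @param z_step_um Z step (default 10).
#' @param size plane side in px (default 64).
#' @param density speckle density of invaded planes.
#' @param blur_sigma defocus blur applied to non-invaded planes (px).
#' @param noise_sd additive sensor noise.
#' @param seed integer seed.
#' @return A list: `stack` (a [zstack()]), `true_depth_um`,
#'   `true_deepest_index`, `labels` (logical per plane, top-first).
#' @export
make_invasion_fixture <- function(deepest_invaded_index, n_planes = 10,
                                  z_step_um = 10, size = 64,
                                  density = 0.06, blur_sigma = 4,
                                  noise_sd = 0.02, seed = 1L) {
  stopifnot(n_planes >= 1)
  di <- deepest_invaded_index
  if (!is.na(di)) stopifnot(di >= 0, di < n_planes)
  withr_seed(seed, {
    planes <- vector("list", n_planes)
    labels <- logical(n_planes)
    for (i in seq_len(n_planes)) {
      idx0 <- i - 1L
      speck <- matrix(as.numeric(runif(size * size) < density), size, size)
      base <- gauss_blur(speck, 0.7)
      invaded <- !is.na(di) && idx0 <= di
      p <- if (invaded) base else gauss_blur(base, blur_sigma)
      planes[[i]] <- pmax(p + matrix(rnorm(size * size, 0, noise_sd),
                                     size, size), 0)
      labels[i] <- invaded
    }
    list(stack = zstack(planes, z_step_um = z_step_um, pixel_size_um = 1),
         true_depth_um = if (is.na(di)) 0 else di * z_step_um,
         true_deepest_index = di,
         labels = labels)
  })
}

# --- random embedded trees + tube rendering ---------------------------------

point_segment_dist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  l2 <- dx * dx + dy * dy
  if (l2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- pmin(pmax(((px - x1) * dx + (py - y1) * dy) / l2, 0), 1)
  sqrt((px - x1 - t * dx)^2 + (py - y1 - t * dy)^2)
}

# minimum distance between two segments, sampled finely
segment_separation <- function(s1, s2, n = 25) {
  t <- seq(0, 1, length.out = n)
  xs <- s1[1] + t * (s1[3] - s1[1])
  ys <- s1[2] + t * (s1[4] - s1[2])
  min(point_segment_dist(xs, ys, s2[1], s2[2], s2[3], s2[4]))
}

# segments that meet at a tree node are adjacent: bounded branching angles
# (siblings >= 0.8 rad apart, children never double back) keep them locally
# separated, so the clearance check only applies to non-adjacent pairs
segments_share_endpoint <- function(s1, s2, tol = 1e-6) {
  ends1 <- rbind(s1[1:2], s1[3:4])
  ends2 <- rbind(s2[1:2], s2[3:4])
  for (i in 1:2) for (j in 1:2) {
    if (max(abs(ends1[i, ] - ends2[j, ])) < tol) return(TRUE)
  }
  FALSE
}

grow_random_tree <- function(n_branches, len_range_px, size, margin,
                             min_sep_px) {
  # trunk plus pairs of children: odd branch counts realize exactly
  n_target <- if (n_branches %% 2 == 0) n_branches - 1L else n_branches
  root <- c(runif(1, size * 0.35, size * 0.65),
            runif(1, size * 0.35, size * 0.65))
  segs <- NULL       # rows: x1, y1, x2, y2, parent segment index
  nodes <- list()
  add_segment <- function(from_xy, dir, parent_idx) {
    for (try in 1:25) {
      len <- runif(1, len_range_px[1], len_range_px[2])
      d <- dir + runif(1, -0.5, 0.5)
      to <- from_xy + len * c(cos(d), sin(d))
      if (any(to < margin) || any(to > size - margin)) next
      seg <- c(from_xy, to)
      ok <- TRUE
      if (!is.null(segs)) {
        for (j in seq_len(nrow(segs))) {
          if (segments_share_endpoint(seg, segs[j, 1:4])) next
          if (segment_separation(seg, segs[j, 1:4]) < min_sep_px) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) return(list(seg = seg, dir = d))
    }
    NULL
  }
  trunk <- add_segment(root, runif(1, 0, 2 * pi), NA)
  if (is.null(trunk)) return(NULL)
  segs <- matrix(c(trunk$seg, NA), 1)
  queue <- list(list(tip = trunk$seg[3:4], dir = trunk$dir, idx = 1L))
  while (nrow(segs) < n_target && length(queue) > 0) {
    cur <- queue[[1]]
    queue <- queue[-1]
    if (nrow(segs) + 2 > n_target) break
    spread <- runif(1, 0.4, 0.9)
    for (s in c(-spread, spread)) {
      ch <- add_segment(cur$tip, cur$dir + s, cur$idx)
      if (is.null(ch)) next
      segs <- rbind(segs, c(ch$seg, cur$idx))
      queue[[length(queue) + 1]] <- list(tip = ch$seg[3:4], dir = ch$dir,
                                         idx = nrow(segs))
    }
  }
  segs
}

segments_to_graph <- function(segs, pixel_size_um) {
  if (is.null(segs) || nrow(segs) == 0) {
    return(empty_embedded_graph(pixel_size_um))
  }
  pts <- rbind(segs[, 1:2, drop = FALSE], segs[, 3:4, drop = FALSE])
  key <- paste(round(pts[, 1], 6), round(pts[, 2], 6))
  uk <- unique(key)
  vid <- match(key, uk)
  nseg <- nrow(segs)
  vt <- tibble::tibble(id = seq_along(uk),
                       x = pts[match(uk, key), 1],
                       y = pts[match(uk, key), 2])
  edges <- tibble::tibble(
    v1 = vid[seq_len(nseg)],
    v2 = vid[nseg + seq_len(nseg)],
    geom = purrr::map(seq_len(nseg), function(i) {
      rbind(segs[i, 1:2], segs[i, 3:4])
    }))
  # contract degree-2 nodes (failed child placements) so edges are the true
  # branch decomposition, matching what any extractor can observe
  assemble_chains(vt, edges, pixel_size_um)
}

render_tubes <- function(segs, size, sigma_px, amplitude = 1) {
  dist <- matrix(Inf, size, size)
  if (!is.null(segs)) {
    reach <- 4 * sigma_px
    for (i in seq_len(nrow(segs))) {
      s <- segs[i, 1:4]
      r0 <- max(1, floor(min(s[2], s[4]) - reach))
      r1 <- min(size, ceiling(max(s[2], s[4]) + reach))
      c0 <- max(1, floor(min(s[1], s[3]) - reach))
      c1 <- min(size, ceiling(max(s[1], s[3]) + reach))
      rows <- r0:r1; cols <- c0:c1
      py <- matrix(rep(rows, length(cols)), length(rows))
      px <- matrix(rep(cols, each = length(rows)), length(rows))
      d <- point_segment_dist(as.vector(px), as.vector(py),
                              s[1], s[2], s[3], s[4])
      dist[rows, cols] <- pmin(dist[rows, cols],
                               matrix(d, length(rows), length(cols)))
    }
  }
  amplitude * exp(-dist^2 / (2 * sigma_px^2))
}

#' Synthetic microvessel-network fixture
#'
#' Grows a random embedded tree (trunk plus pairs of children, with angle
#' jitter and rejection resampling so branches never approach each other
#' closer than a clearance distance), then renders each branch as a tube
#' with Gaussian cross-section plus additive Gaussian noise. The returned
#' `true_graph` carries the exact branch polylines and lengths. Rendering is
#' either a single 2D projection or a Z-stack in which each branch lives on
#' an assigned plane.
#'
#' @param n_branches requested branch count (odd counts realize exactly; even
#'   requests use `n - 1`; crowded geometry may realize fewer, and the truth
#'   reflects what was rendered).
#' @param size image side in px (default 256).
#' @param pixel_size_um microns per pixel (default 2).
#' @param length_range_um branch length range (default 30-300 um).
#' @param tube_width_px full tube width in px (Gaussian FWHM; default 6).
#' @param snr amplitude-to-noise-sd ratio; `Inf` for noise-free.
#' @param mode `"projection"` (2D image) or `"zstack"`.
#' @param n_planes,z_step_um Z geometry for `mode = "zstack"`.
#' @param seed integer seed.
#' @return A list: `image` (matrix) or `stack` (a [zstack()]), `true_graph`
#'   (an [embedded_graph()]), `true_mask` (tube support), `segments`.
#' @export
make_vessel_fixture <- function(n_branches = 7, size = 256,
                                pixel_size_um = 2,
                                length_range_um = c(30, 300),
                                tube_width_px = 6, snr = 5,
                                mode = c("projection", "zstack"),
                                n_planes = 8, z_step_um = 10, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_branches >= 0, size >= 64)
  sigma_px <- tube_width_px / 2.355
  withr_seed(seed, {
    if (n_branches == 0) {
      img <- matrix(0, size, size)
      if (is.finite(snr)) {
        img <- img + matrix(rnorm(size * size, 0, 1 / snr), size, size)
      }
      return(list(image = img, true_graph = empty_embedded_graph(pixel_size_um),
                  true_mask = matrix(FALSE, size, size), segments = NULL))
    }
    len_px <- pmax(length_range_um / pixel_size_um, 4)
    if (len_px[1] > size * 0.7) {
      stop("spec error: branch lengths do not fit the image size",
           call. = FALSE)
    }
    segs <- NULL
    for (attempt in 1:10) {
      segs <- grow_random_tree(n_branches, len_px, size,
                               margin = 10 + 3 * sigma_px,
                               min_sep_px = 2 * tube_width_px)
      if (!is.null(segs) && nrow(segs) >= 1) break
    }
    if (is.null(segs) || nrow(segs) == 0) {
      stop("could not place a tree for this spec; try another seed",
           call. = FALSE)
    }
    graph <- segments_to_graph(segs, pixel_size_um)
    noise <- function() {
      if (!is.finite(snr)) matrix(0, size, size)
      else matrix(rnorm(size * size, 0, 1 / snr), size, size)
    }
    clean <- render_tubes(segs, size, sigma_px)
    true_mask <- clean >= exp(-(tube_width_px / 2)^2 / (2 * sigma_px^2))
    if (mode == "projection") {
      list(image = pmax(clean + noise(), 0), true_graph = graph,
           true_mask = true_mask, segments = segs)
    } else {
      plane_of <- sample.int(n_planes, nrow(segs), replace = TRUE)
      planes <- lapply(seq_len(n_planes), function(p) {
        sel <- segs[plane_of == p, , drop = FALSE]
        img <- if (nrow(sel) > 0) render_tubes(sel, size, sigma_px)
        else matrix(0, size, size)
        pmax(img + noise(), 0)
      })
      list(stack = zstack(planes, z_step_um = z_step_um,
                          pixel_size_um = pixel_size_um),
           true_graph = graph, true_mask = true_mask,
           segments = segs, plane_of = plane_of)
    }
  })
}
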