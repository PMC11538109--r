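# Internal image helpers. Convention throughout the package: a grayscale
# image is a plain numeric matrix indexed [row, col]; row 1 is the top of the
# image, y = row, x = col. EBImage primitives are used behind thin wrappers
# so the rest of the code never depends on EBImage's x/y layout.

assert_image <- function(img, arg = "image") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (any(!is.finite(img))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  invisible(img)
}

as_matrix_img <- function(x) {
  m <- EBImage::imageData(x)
  if (length(dim(m)) > 2) m <- m[, , 1]
  m <- as.matrix(m)
  dimnames(m) <- NULL
  m
}

#' @noRd
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  as_matrix_img(EBImage::gblur(EBImage::Image(img), sigma = sigma,
                               boundary = "replicate"))
}

conv2_replicate <- function(img, kernel) {
  as_matrix_img(EBImage::filter2(EBImage::Image(img), filter = kernel,
                                 boundary = "replicate"))
}

sobel_gradients <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE) / 8
  # kx responds to change across columns (x); ky across rows (y)
  gx <- conv2_replicate(img, t(kx))
  gy <- conv2_replicate(img, kx)
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

laplacian_filter <- function(img) {
  k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  conv2_replicate(img, k)
}

box_filter <- function(img, size) {
  k <- matrix(1 / (size * size), size, size)
  conv2_replicate(img, k)
}

local_variance <- function(img, size) {
  mu <- box_filter(img, size)
  mu2 <- box_filter(img * img, size)
  pmax(mu2 - mu * mu, 0)
}

rescale01 <- function(img) {
  rng <- range(img)
  if (rng[2] <= rng[1]) return(img * 0)
  (img - rng[1]) / (rng[2] - rng[1])
}

#' @noRd
resize_image <- function(img, nrow_out, ncol_out) {
  if (nrow(img) == nrow_out && ncol(img) == ncol_out) return(img)
  as_matrix_img(EBImage::resize(EBImage::Image(img), w = nrow_out,
                                h = ncol_out))
}

# Reflection-pad an image to at least (nr, nc)
pad_reflect <- function(img, nr, nc) {
  r <- nrow(img); c <- ncol(img)
  if (r >= nr && c >= nc) return(img)
  idx_reflect <- function(n, n_out) {
    i <- seq_len(n_out)
    # reflect indices 1..n outward (abba style)
    period <- max(2L * n - 2L, 1L)
    j <- (i - 1L) %% period
    ifelse(j < n, j + 1L, period - j + 1L)
  }
  img[idx_reflect(r, max(r, nr)), idx_reflect(c, max(c, nc)), drop = FALSE]
}

# shift with edge replication: for finite differences near the frame
shift_rep <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  rs <- pmin(pmax(seq_len(nr) - dr, 1), nr)
  cs <- pmin(pmax(seq_len(nc) - dc, 1), nc)
  m[rs, cs, drop = FALSE]
}

shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  ok_r <- rs >= 1 & rs <= nr
  ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

neighbor_offsets8 <- cbind(
  dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
  dc = c(-1, 0, 1, -1, 1, -1, 0, 1)
)

#' Otsu threshold of a numeric vector/matrix (256-bin histogram)
#' @noRd
otsu_threshold <- function(x) {
  v <- as.numeric(x)
  rng <- range(v)
  if (rng[2] <= rng[1]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(findInterval(v, breaks, all.inside = TRUE), nbins = 256)
  w <- cumsum(h)
  mids <- (breaks[-1] + breaks[-257]) / 2
  mu <- cumsum(h * mids)
  tot <- w[256]; mu_t <- mu[256]
  w1 <- w[-256]; w2 <- tot - w1
  valid <- w1 > 0 & w2 > 0
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_t * w1[valid] - mu[-256][valid])^2 /
    (w1[valid] * w2[valid])
  mids[which.max(sigma_b)]
}

# Morphological thinning (Zhang-Suen) of a binary matrix; returns 0/1 matrix.
thin_skeleton <- function(mask) {
  m <- (mask > 0) * 1L
  repeat {
    changed <- FALSE
    for (step in 0:1) {
      p2 <- shift_mat(m, -1, 0); p3 <- shift_mat(m, -1, 1)
      p4 <- shift_mat(m, 0, 1);  p5 <- shift_mat(m, 1, 1)
      p6 <- shift_mat(m, 1, 0);  p7 <- shift_mat(m, 1, -1)
      p8 <- shift_mat(m, 0, -1); p9 <- shift_mat(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- cbind(as.vector(p2), as.vector(p3), as.vector(p4),
                    as.vector(p5), as.vector(p6), as.vector(p7),
                    as.vector(p8), as.vector(p9))
      a <- rowSums(seqs[, c(1:8)] == 0 & seqs[, c(2:8, 1)] == 1)
      a <- matrix(a, nrow(m), ncol(m))
      if (step == 0) {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Count of 8-connected skeleton neighbors for each pixel of a binary matrix.
neighbor_count8 <- function(mask) {
  m <- (mask > 0) * 1L
  out <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(nrow(neighbor_offsets8))) {
    out <- out + shift_mat(m, neighbor_offsets8[i, 1], neighbor_offsets8[i, 2])
  }
  out
}

# Perimeter of a binary region by marching squares at the 0.5 iso-level.
# Crossing points sit at pixel-edge midpoints, so staircase corners are cut
# at 45 degrees. The polygon still overestimates smooth digital curves by a
# few percent (octagonal metric), so the total is calibrated by 0.98: an
# ideal rasterized disk then measures close to 2*pi*r while axis-aligned
# rectangles stay near their exact perimeter.
ms_perimeter <- function(mask) {
  m <- (mask > 0) * 1L
  m <- rbind(0L, cbind(0L, m, 0L), 0L)
  a <- m[-nrow(m), -ncol(m)]  # top-left
  b <- m[-nrow(m), -1]        # top-right
  d <- m[-1, -ncol(m)]        # bottom-left
  e <- m[-1, -1]              # bottom-right
  case <- a + 2L * b + 4L * d + 8L * e
  s <- sqrt(0.5)
  # segment length contributed by each of the 16 cases
  len <- c(0, s, s, 1, s, 1, 2 * s, s, s, 2 * s, 1, s, 1, s, s, 0)
  0.98 * sum(len[case + 1L])
}

#' Circularity (4*pi*area / perimeter^2) of a binary region
#'
#' Computes the isoperimetric circularity of the foreground of a binary
#' image, with the perimeter measured as the marching-squares contour length
#' at the 0.5 level so that an ideal disk scores close to 1.
#'
#' @param mask logical or 0/1 numeric matrix with a single foreground region.
#' @return A single number; 1 for an ideal disk, smaller for elongated shapes.
#' @examples
#' rect <- matrix(0, 20, 120)
#' rect[9:12, 11:110] <- 1
#' circularity(rect)
#' @export
circularity <- function(mask) {
  area <- sum(mask > 0)
  if (area == 0) return(0)
  p <- ms_perimeter(mask)
  if (p <= 0) return(1)
  4 * pi * area / p^2
}

label_components <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image((mask > 0) * 1))
  lab <- as_matrix_img(lab)
  storage.mode(lab) <- "integer"
  lab
}

dist_to_zero <- function(mask) {
  # Euclidean distance from each pixel to the nearest zero pixel
  as_matrix_img(EBImage::distmap(EBImage::Image((mask > 0) * 1)))
}
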