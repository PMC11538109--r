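#' Z-stack container
#'
#' A Z-stack is an ordered set of 2D grayscale planes acquired at increasing
#' focal depth through a 3D hydrogel construct, together with the physical
#' Z step between planes and the pixel size. Plane 1 is the *top* plane
#' (where cancer cells are seeded); depth increases with plane index.
#' Physical metadata is always user-supplied: acquisition files rarely agree
#' on stack depth, so nothing is inferred from headers.
#'
#' @param planes list of numeric matrices of identical dimensions.
#' @param z_step_um positive Z step between consecutive planes, in microns.
#' @param pixel_size_um positive pixel size, in microns per pixel.
#' @param channel_label optional channel name (e.g. "GFP", "TexasRed").
#' @return An object of class `zstack`.
#' @examples
#' zs <- zstack(list(matrix(0, 8, 8), matrix(1, 8, 8)), z_step_um = 4.25,
#'              pixel_size_um = 3.25)
#' n_planes(zs)
#' @export
zstack <- function(planes, z_step_um, pixel_size_um, channel_label = "") {
  if (!is.list(planes) || length(planes) == 0) {
    stop("`planes` must be a non-empty list of matrices (empty input)",
         call. = FALSE)
  }
  purrr::walk(planes, assert_image, arg = "planes[[i]]")
  dims <- vapply(planes, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("shape mismatch: all planes must have identical dimensions",
         call. = FALSE)
  }
  stopifnot(is.numeric(z_step_um), z_step_um > 0,
            is.numeric(pixel_size_um), pixel_size_um > 0)
  structure(
    list(planes = planes, z_step_um = z_step_um,
         pixel_size_um = pixel_size_um, channel_label = channel_label),
    class = "zstack"
  )
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$planes[[1]])
  cat(sprintf(
    "<zstack> %d plane(s) of %d x %d px | z step %.3g um | %.3g um/px%s\n",
    length(x$planes), d[1], d[2], x$z_step_um, x$pixel_size_um,
    if (nzchar(x$channel_label)) paste0(" | ", x$channel_label) else ""))
  invisible(x)
}

#' @rdname zstack
#' @param x a `zstack`.
#' @export
n_planes <- function(x) length(x$planes)

#' Read a Z-stack from TIFF files
#'
#' Reads an ordered list of single- or multi-page grayscale TIFF files into a
#' [zstack()]. The supplied file order defines the plane order, top plane
#' first; filename conventions vary between instruments, so ordering is the
#' caller's responsibility (see [parse_filenames()] for regex-driven
#' ordering in batch runs).
#'
#' @param paths character vector of TIFF paths, top plane first.
#' @inheritParams zstack
#' @return A [zstack()].
#' @export
read_zstack <- function(paths, z_step_um, pixel_size_um, channel_label = "") {
  if (length(paths) == 0) {
    stop("empty input: no files supplied", call. = FALSE)
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  planes <- purrr::map(paths, function(p) {
    pages <- tiff::readTIFF(p, all = TRUE, as.is = FALSE)
    purrr::map(pages, function(pg) {
      if (length(dim(pg)) == 3) pg <- pg[, , 1]
      m <- as.matrix(pg)
      dimnames(m) <- NULL
      m
    })
  })
  planes <- purrr::flatten(planes)
  zstack(planes, z_step_um = z_step_um, pixel_size_um = pixel_size_um,
         channel_label = channel_label)
}

#' Write a projection (or any image) as 16-bit TIFF
#'
#' Intensities are rescaled to `[0, 1]` before writing unless already within
#' range.
#'
#' @param img numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(img, path) {
  assert_image(img)
  if (min(img) < 0 || max(img) > 1) img <- rescale01(img)
  tiff::writeTIFF(img, path, bits.per.sample = 16L)
  invisible(path)
}

PROJECTION_METHODS <- c("focus_stack", "min", "max", "median", "mean")

#' Project a Z-stack to a single 2D image
#'
#' Reduces a Z-stack to one 2D image by one of five established projection
#' methods: per-pixel minimum, maximum, median, or mean intensity, or focus
#' stacking. Focus stacking selects, for every pixel, the value from the
#' plane that is locally sharpest there (largest local variance of the
#' Laplacian in a square window), producing an all-in-focus composite that
#' matches what plate readers report.
#'
#' @param stack a [zstack()].
#' @param method one of `"focus_stack"`, `"min"`, `"max"`, `"median"`,
#'   `"mean"`.
#' @param focus_window odd window size (pixels) of the local sharpness
#'   measure used by focus stacking. Default 11, mirroring the 11 px maximum
#'   filter used by the manual plate-reader workflow.
#' @return An object of class `projection`: the projected matrix with
#'   attributes `method` and `n_planes`.
#' @examples
#' zs <- zstack(list(matrix(3, 4, 4), matrix(5, 4, 4)), 10, 1)
#' project_zstack(zs, "max")[1, 1]
#' @export
project_zstack <- function(stack, method = c("focus_stack", "min", "max",
                                             "median", "mean"),
                           focus_window = 11) {
  stopifnot(inherits(stack, "zstack"))
  if (length(method) != 1 || !method %in% PROJECTION_METHODS) {
    method <- tryCatch(match.arg(method),
                       error = function(e) {
                         stop("unknown projection method: ",
                              paste(method, collapse = "/"), call. = FALSE)
                       })
  }
  planes <- stack$planes
  k <- length(planes)
  d <- dim(planes[[1]])
  img <- switch(
    method,
    min = Reduce(pmin, planes),
    max = Reduce(pmax, planes),
    mean = Reduce(`+`, planes) / k,
    median = {
      flat <- matrix(unlist(planes), ncol = k)
      matrix(apply(flat, 1, median), d[1], d[2])
    },
    focus_stack = {
      if (focus_window %% 2 == 0 || focus_window < 3) {
        stop("`focus_window` must be an odd integer >= 3", call. = FALSE)
      }
      sharp <- vapply(planes, function(p) {
        local_variance(laplacian_filter(p), focus_window)
      }, matrix(0, nrow(planes[[1]]), ncol(planes[[1]])))
      best <- apply(sharp, c(1, 2), which.max)
      sel <- matrix(0, nrow(best), ncol(best))
      for (i in seq_len(k)) {
        pick <- best == i
        sel[pick] <- planes[[i]][pick]
      }
      sel
    }
  )
  structure(img, method = method, n_planes = k, class = c("projection",
                                                          "matrix", "array"))
}
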