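test_that("read_zstack assembles ordered planes and validates input", {
  dir <- withr::local_tempdir()
  paths <- character(21)
  for (i in 1:21) {
    paths[i] <- file.path(dir, sprintf("z%02d.tif", i))
    tiff::writeTIFF(matrix(i / 21, 16, 16), paths[i], bits.per.sample = 16L)
  }
  zs <- read_zstack(paths, z_step_um = 85 / 20, pixel_size_um = 3.25)
  expect_equal(n_planes(zs), 21)
  expect_equal(zs$planes[[1]][1, 1], 1 / 21, tolerance = 1e-3)
  expect_equal(zs$planes[[21]][1, 1], 1, tolerance = 1e-3)

  one <- read_zstack(paths[3], 1, 1)
  expect_equal(n_planes(one), 1)
  pr <- project_zstack(one, "max")
  expect_equal(unclass(pr)[seq_len(16), ], one$planes[[1]], tolerance = 1e-7,
               ignore_attr = TRUE)

  bad <- file.path(dir, "bad.tif")
  tiff::writeTIFF(matrix(0.5, 8, 8), bad)
  expect_error(read_zstack(c(paths[1], bad), 1, 1), "shape mismatch")
  expect_error(read_zstack(character(), 1, 1), "empty input")
})

test_that("pixelwise projections follow their reductions", {
  zs <- zstack(list(matrix(3, 6, 6), matrix(5, 6, 6)), 10, 1)
  expect_true(all(project_zstack(zs, "max") == 5))
  expect_true(all(project_zstack(zs, "min") == 3))
  expect_true(all(project_zstack(zs, "mean") == 4))
  expect_true(all(project_zstack(zs, "median") == 4))
  expect_error(project_zstack(zs, "sharpest"), "unknown projection method")

  # min <= median <= max pixelwise on random stacks
  set.seed(11)
  for (rep in 1:3) {
    planes <- lapply(1:5, function(i) matrix(runif(400), 20, 20))
    zs <- zstack(planes, 1, 1)
    lo <- project_zstack(zs, "min")
    md <- project_zstack(zs, "median")
    hi <- project_zstack(zs, "max")
    expect_true(all(lo <= md & md <= hi))
  }

  # mean of identical planes is exact
  p <- matrix(runif(100), 10, 10)
  zs_id <- zstack(list(p, p, p), 1, 1)
  expect_equal(unclass(project_zstack(zs_id, "mean")), p,
               ignore_attr = TRUE)
})

test_that("focus stacking selects the locally sharpest plane per pixel", {
  set.seed(21)
  sharp_l <- matrix(0, 60, 60)
  sharp_l[, 1:30] <- matrix(as.numeric(runif(60 * 30) > 0.5), 60)
  sharp_r <- matrix(0, 60, 60)
  sharp_r[, 31:60] <- matrix(as.numeric(runif(60 * 30) > 0.5), 60)
  blur <- function(m) mpmimage:::gauss_blur(m, 3)
  zs <- zstack(list(sharp_l + blur(sharp_r), blur(sharp_l) + sharp_r), 1, 1)
  fs <- project_zstack(zs, "focus_stack")
  # away from the seam, the output equals the in-focus plane
  expect_true(all(fs[, 5:26] == zs$planes[[1]][, 5:26]))
  expect_true(all(fs[, 35:56] == zs$planes[[2]][, 35:56]))
  # selection property: every output pixel comes from some plane
  from_some <- fs == zs$planes[[1]] | fs == zs$planes[[2]]
  expect_true(all(from_some))
})

test_that("well boundary fits a disk and a superellipse and falls back", {
  img <- matrix(0, 512, 512)
  img[(row(img) - 256.5)^2 + (col(img) - 256.5)^2 <= 200^2] <- 1
  b <- detect_well_boundary(img)
  expect_lt(abs(sum(b$mask) - pi * 200^2) / (pi * 200^2), 0.05)
  # mask fully contained in frame by construction
  expect_equal(dim(b$mask), dim(img))

  xs <- matrix(rep(1:512, each = 512), 512)
  ys <- matrix(rep(1:512, 512), 512)
  inside <- (abs((xs - 256.5) / 200))^4 + (abs((ys - 256.5) / 200))^4 <= 1
  img2 <- matrix(0, 512, 512)
  img2[inside] <- 1
  b2 <- detect_well_boundary(img2)
  expect_equal(b2$kind, "superellipse")
  expect_lt(abs(b2$n - 4), 1)
  expect_lt(abs(sum(b2$mask) - sum(inside)) / sum(inside), 0.05)

  b3 <- detect_well_boundary(matrix(0, 128, 128))
  expect_equal(b3$kind, "circle")
  expect_equal(b3$a, 0.95 * 128 / 2)
  expect_error(detect_well_boundary(matrix(0, 32, 32)), "64 x 64")
})
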