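test_that("training schedule follows the floor(1500/batch) rule", {
  cfg <- seg_model_config(batch_size = 4)
  sched <- training_schedule(cfg)
  expect_equal(sched$train_steps, 375)
  expect_equal(sched$val_steps, 125)
  expect_equal(training_schedule(seg_model_config(batch_size = 7))$train_steps,
               floor(1500 / 7))
})

test_that("augmentation is deterministic, binary-safe, and sized correctly", {
  set.seed(5)
  img <- matrix(runif(600 * 600), 600)
  msk <- matrix(as.numeric(runif(600 * 600) > 0.9), 600)
  a1 <- augment_sample(img, msk, seed = 4)
  a2 <- augment_sample(img, msk, seed = 4)
  expect_identical(a1, a2)
  expect_equal(dim(a1$image), c(320, 320))
  expect_type(a1$mask, "logical")

  # degenerate policy: only the crop + resample remain
  pol0 <- augmentation_policy(rotate = 0, crop = 1, hflip = 0, vflip = 0,
                              brightness_contrast = 0, noise = 0,
                              elastic = 0)
  a3 <- augment_sample(img, msk, pol0, seed = 9)
  expect_equal(dim(a3$image), c(320, 320))
  # with all transforms off, the output is a resampled crop of the input
  expect_true(min(a3$image) >= min(img) - 1e-9)
  expect_true(max(a3$image) <= max(img) + 1e-9)
  expect_error(augment_sample(img, msk[1:10, 1:10]), "congruent")
})

test_that("geometric transforms keep image and mask congruent", {
  fx <- make_vessel_fixture(n_branches = 1, size = 600, snr = Inf,
                            tube_width_px = 8,
                            length_range_um = c(300, 300),
                            pixel_size_um = 1, seed = 6)
  pol <- augmentation_policy(rotate = 1, crop = 1, hflip = 1, vflip = 1,
                             brightness_contrast = 0, noise = 0, elastic = 1)
  a <- augment_sample(fx$image, fx$true_mask, pol, seed = 11)
  expect_true(any(a$mask))
  # the transformed tube's bright pixels stay inside the transformed mask
  expect_gt(mean(a$image[a$mask]), 3 * mean(a$image[!a$mask]))
})

test_that("segmentation training reaches Dice >= 0.8 on tube fixtures", {
  tr <- make_seg_split(30, 3000)
  va <- make_seg_split(10, 5000)
  cfg <- seg_model_config(filters = c(8, 16, 32, 64), learning_rate = 0.01,
                          epochs = 5, batch_size = 4, input_size = 96)
  mod <- train_segmentation_model(
    lapply(tr, `[[`, "img"), lapply(tr, `[[`, "mask"),
    lapply(va, `[[`, "img"), lapply(va, `[[`, "mask"), cfg, seed = 1)
  d <- sapply(va, function(s) dice_coefficient(predict_map(mod, s$img),
                                               s$mask))
  expect_gte(mean(d), 0.8)
  expect_error(
    train_segmentation_model(list(tr[[1]]$img), list(tr[[1]]$img * 0.3),
                             list(va[[1]]$img), list(va[[1]]$mask), cfg),
    "label error")
})

test_that("grid search returns the argmax candidate (trivially for one)", {
  tr <- make_seg_split(6, 3000)
  va <- make_seg_split(3, 5000)
  cfg <- seg_model_config(filters = c(8, 16), epochs = 2, batch_size = 2,
                          input_size = 96)
  gs <- grid_search_segmentation(
    lapply(tr, `[[`, "img"), lapply(tr, `[[`, "mask"),
    lapply(va, `[[`, "img"), lapply(va, `[[`, "mask"),
    learning_rates = 0.01, filter_sets = list(c(8, 16)),
    base_config = cfg, seed = 1)
  expect_equal(nrow(gs$results), 1)
  expect_equal(gs$best_config$learning_rate, 0.01)
  expect_equal(gs$best_config$filters, c(8, 16))
})

test_that("tiled prediction blends overlaps by averaging", {
  # constant stub: output constant everywhere
  stub <- function(img) matrix(0.4, nrow(img), ncol(img))
  img <- matrix(runif(300 * 300), 300)
  pt <- predict_tiled(stub, img, patch_size = 128, stride = 64)
  expect_true(all(abs(pt - 0.4) < 1e-12))
  expect_equal(dim(pt), dim(img))

  # two tiles predicting 0.4 and 0.6: the overlap averages to 0.5
  img2 <- matrix(0, 64, 96)
  img2[1, 1] <- 0.4
  img2[1, 33] <- 0.6
  corner_stub <- function(im) matrix(im[1, 1], nrow(im), ncol(im))
  pt2 <- predict_tiled(corner_stub, img2, patch_size = 64, stride = 32)
  expect_equal(pt2[30, 10], 0.4)          # left-only region
  expect_equal(pt2[30, 50], 0.5)          # overlap of both tiles
  expect_equal(pt2[30, 90], 0.6)          # right-only region

  # trivial tiling equals direct prediction
  img3 <- matrix(runif(64 * 64), 64)
  ident <- function(im) pmin(pmax(im, 0), 1)
  pt3 <- predict_tiled(ident, img3, patch_size = 64, stride = 63)
  expect_equal(unclass(pt3), predict_map(ident, img3), ignore_attr = TRUE)

  # image smaller than a tile: reflection padding, output matches input
  img4 <- matrix(runif(40 * 50), 40)
  pt4 <- predict_tiled(stub, img4, patch_size = 64, stride = 32)
  expect_equal(dim(pt4), c(40, 50))
})

test_that("refinement removes blobs and weights centerlines", {
  # an ideal disk has circularity near 1 and is removed
  pm <- matrix(0, 80, 80)
  pm[(row(pm) - 25)^2 + (col(pm) - 25)^2 <= 100] <- 0.9
  expect_true(all(refine_probability_map(probability_map(pm, "model")) == 0))

  # an elongated component with a junction is kept, never amplified
  pm2 <- matrix(0, 80, 80)
  pm2[40:43, 10:70] <- 0.9
  pm2[20:39, 38:41] <- 0.9
  r2 <- refine_probability_map(probability_map(pm2, "model"))
  expect_true(any(r2 > 0))
  expect_true(all(r2 <= pm2 + 1e-12))

  # a bare segment (no junction) is removed by the junction rule
  pm3 <- matrix(0, 80, 80)
  pm3[40:43, 10:70] <- 0.9
  expect_true(all(refine_probability_map(probability_map(pm3, "model")) == 0))
})

test_that("circularity and medial-axis weights match their formulas", {
  disk <- matrix(0, 64, 64)
  disk[(row(disk) - 32.5)^2 + (col(disk) - 32.5)^2 <= 20^2] <- 1
  expect_gt(circularity(disk), 0.9)
  expect_lt(circularity(disk), 1.05)

  rect <- matrix(0, 40, 140)
  rect[19:22, 21:120] <- 1
  expect_lt(abs(circularity(rect) - 4 * pi * 400 / 208^2), 0.03)

  w <- medial_axis_weights(rect)
  sk <- mpmimage:::thin_skeleton(rect)
  expect_equal(max(w[sk == 1]), 1)            # 1 on the medial axis
  expect_equal(w[10, 70], 0)                  # 0 outside the component
  border <- rect == 1 & mpmimage:::dist_to_zero(rect) <= 1
  expect_true(all(w[border] <= 0.5 + 1e-9))   # low at the border
})

test_that("sato path produces a masked 2D vesselness from a stack", {
  blank <- zstack(replicate(3, matrix(0, 64, 64), simplify = FALSE), 10, 1)
  expect_true(all(sato_vesselness_2d(blank) == 0))

  # one tube at a single plane of 8: recovered within 10% downstream. The
  # tube is long relative to the tube width so the measurement reflects path
  # recovery rather than the +/- few px localization of the two free ends.
  fx <- make_vessel_fixture(n_branches = 1, size = 300, snr = 8,
                            tube_width_px = 5,
                            length_range_um = c(200, 200),
                            pixel_size_um = 1, mode = "zstack",
                            n_planes = 8, seed = 31)
  vm <- sato_vesselness_2d(fx$stack, scales = c(1, 2))
  va <- analyze_vessels(vm, morse_params(remove_disconnected = TRUE),
                        pixel_size_um = 1)
  expect_equal(n_branches(va$graph), 1)
  expect_lt(abs(total_length_um(va$graph) - 200) / 200, 0.1)

  # tubes spread over different planes are all preserved in the 2D output
  fx2 <- make_vessel_fixture(n_branches = 3, size = 224, snr = 8,
                             tube_width_px = 5, mode = "zstack",
                             n_planes = 8, pixel_size_um = 2, seed = 33)
  expect_gte(length(unique(fx2$plane_of)), 2)
  vm2 <- sato_vesselness_2d(fx2$stack, scales = c(1, 2))
  va2 <- analyze_vessels(vm2, morse_params(remove_disconnected = FALSE),
                         pixel_size_um = 2)
  expect_lte(abs(n_branches(va2$graph) - n_branches(fx2$true_graph)), 1)
  # every true segment midline is covered by the extracted graph
  pts <- do.call(rbind, va2$graph$edges$geom)
  for (i in seq_len(nrow(fx2$segments))) {
    s <- fx2$segments[i, 1:4]
    tt <- seq(0.1, 0.9, length.out = 20)
    sx <- s[1] + tt * (s[3] - s[1])
    sy <- s[2] + tt * (s[4] - s[2])
    cov <- mean(vapply(seq_along(sx), function(k) {
      min(sqrt((pts[, 1] - sx[k])^2 + (pts[, 2] - sy[k])^2)) < 4
    }, logical(1)))
    expect_gte(cov, 0.7)
  }
})
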