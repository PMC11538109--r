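test_that("all generators are bit-reproducible under a fixed seed", {
  expect_identical(make_well_fixture(0.3, size = 128, seed = 9),
                   make_well_fixture(0.3, size = 128, seed = 9))
  expect_identical(make_invasion_fixture(4, seed = 9),
                   make_invasion_fixture(4, seed = 9))
  expect_identical(make_vessel_fixture(5, size = 128, seed = 9),
                   make_vessel_fixture(5, size = 128, seed = 9))
})

test_that("well fixtures realize the requested fraction", {
  for (f in c(0, 0.25, 0.6, 1)) {
    fx <- make_well_fixture(f, size = 128, seed = 3)
    expect_lt(abs(fx$true_fraction - f), 0.01)
  }
  fx0 <- make_well_fixture(0, size = 128, seed = 3)
  # pure background in the well: nothing near the foreground level
  expect_lt(max(fx0$image[fx0$boundary$mask]), 100)
  expect_error(make_well_fixture(0.5, fg_mean = 30, bg_mean = 25),
               "spec error")
})

test_that("invasion fixtures carry exact depth ground truth", {
  fx <- make_invasion_fixture(7, n_planes = 10, z_step_um = 10, seed = 2)
  expect_equal(fx$true_depth_um, 70)
  expect_equal(sum(fx$labels), 8)  # planes 0..7 invaded
  expect_true(all(fx$labels[1:8]))

  fx0 <- make_invasion_fixture(0, seed = 2)
  expect_equal(fx0$true_depth_um, 0)
  expect_true(fx0$labels[1])

  fx1 <- make_invasion_fixture(0, n_planes = 1, seed = 2)
  expect_equal(n_planes(fx1$stack), 1)
  expect_equal(fx1$true_depth_um, 0)
})

test_that("vessel fixtures carry exact graphs, masks, and empty specs", {
  fx <- make_vessel_fixture(7, size = 256, snr = 5, seed = 12)
  expect_s3_class(fx$true_graph, "embedded_graph")
  expect_gte(n_branches(fx$true_graph), 1)
  # branch lengths are exact euclidean segment sums in um
  lens <- fx$true_graph$edges$length_um
  expect_true(all(lens > 0))
  # the rendered tube support covers the true polylines
  pts <- do.call(rbind, fx$true_graph$edges$geom)
  on_mask <- fx$true_mask[cbind(pmin(pmax(round(pts[, 2]), 1), 256),
                                pmin(pmax(round(pts[, 1]), 1), 256))]
  expect_gte(mean(on_mask), 0.99)

  empty <- make_vessel_fixture(0, size = 64, snr = Inf, seed = 1)
  expect_equal(n_branches(empty$true_graph), 0)
  expect_true(all(empty$image == 0))

  zfx <- make_vessel_fixture(5, size = 128, mode = "zstack", n_planes = 6,
                             seed = 8)
  expect_s3_class(zfx$stack, "zstack")
  expect_equal(n_planes(zfx$stack), 6)
  expect_equal(length(zfx$plane_of), nrow(zfx$segments))
})

test_that("rendered branches keep a clearance distance", {
  fx <- make_vessel_fixture(9, size = 256, tube_width_px = 6, seed = 21)
  segs <- fx$segments
  if (nrow(segs) > 2) {
    for (i in seq_len(nrow(segs) - 1)) {
      for (j in seq((i + 1), nrow(segs))) {
        if (mpmimage:::segments_share_endpoint(segs[i, 1:4], segs[j, 1:4])) {
          next
        }
        expect_gte(mpmimage:::segment_separation(segs[i, 1:4], segs[j, 1:4]),
                   12)
      }
    }
  }
})
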