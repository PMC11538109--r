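test_that("constant images yield an empty skeleton", {
  g <- extract_morse_skeleton(matrix(3, 40, 40), morse_params())
  expect_equal(n_branches(g), 0)
  expect_equal(total_length_um(g), 0)
})

test_that("a noise-free tube is recovered as one branch within 5%", {
  fx <- make_vessel_fixture(n_branches = 1, size = 320, snr = Inf,
                            tube_width_px = 6,
                            length_range_um = c(200, 200),
                            pixel_size_um = 1, seed = 5)
  expect_equal(total_length_um(fx$true_graph), 200, tolerance = 1e-6)
  va <- analyze_vessels(fx$image, morse_params(remove_disconnected = TRUE),
                        pixel_size_um = 1, presmooth_sigma = 0)
  expect_equal(n_branches(va$graph), 1)
  expect_lt(abs(total_length_um(va$graph) - 200) / 200, 0.05)
})

test_that("skeleton length agrees with a morphological-thinning oracle", {
  # same pruning/smoothing applied to both routes: the comparison isolates
  # ridge extraction (Morse) versus morphological thinning of the true mask
  fx <- make_vessel_fixture(n_branches = 1, size = 320, snr = Inf,
                            tube_width_px = 6,
                            length_range_um = c(200, 200),
                            pixel_size_um = 1, seed = 5)
  va <- analyze_vessels(fx$image, morse_params(remove_disconnected = TRUE),
                        pixel_size_um = 1, presmooth_sigma = 0)
  tg <- thinning_skeleton_graph(fx$true_mask)
  tg <- smooth_branches(prune_and_filter(tg, morse_params()), 5)
  thin_len <- total_length_um(tg)
  expect_lt(abs(total_length_um(va$graph) - thin_len) / thin_len, 0.05)
})

test_that("two crossing tubes give a junction and four leaf branches", {
  img <- matrix(0, 128, 128)
  for (t in seq(0, 1, length.out = 400)) {
    p1 <- c(20, 20) + t * c(88, 88)
    p2 <- c(108, 20) + t * c(-88, 88)
    img[round(p1[2]), round(p1[1])] <- 1
    img[round(p2[2]), round(p2[1])] <- 1
  }
  img <- mpmimage:::gauss_blur(img, 2.2)
  va <- analyze_vessels(img, morse_params(remove_disconnected = TRUE), 1,
                        presmooth_sigma = 0)
  deg <- mpmimage:::graph_degrees(va$graph)
  expect_gte(sum(deg >= 3), 1)
  leaf_edges <- with(va$graph$edges,
                     deg[as.character(v1)] == 1 | deg[as.character(v2)] == 1)
  expect_equal(sum(leaf_edges), 4)
})

test_that("pruning removes short leaf branches and iterates to stability", {
  # Y with one 8 um leaf, one 12 um leaf, 30 um trunk
  coords <- rbind(c(0, 0), c(30, 0), c(30 + 8 / sqrt(2), 8 / sqrt(2)),
                  c(30 + 12 / sqrt(2), -12 / sqrt(2)))
  g <- line_graph(coords, rbind(c(1, 2), c(2, 3), c(2, 4)))
  p <- prune_and_filter(g, morse_params(min_branch_um = 10))
  expect_equal(n_branches(p), 1)  # 8 um leaf removed, chain re-merged
  expect_equal(total_length_um(p), 42, tolerance = 1e-9)

  # a network whose every branch is short collapses to nothing
  tiny <- line_graph(rbind(c(0, 0), c(4, 0), c(4, 3)),
                     rbind(c(1, 2), c(2, 3)))
  expect_equal(n_branches(prune_and_filter(tiny,
                                           morse_params(min_branch_um = 10))),
               0)

  # disconnected components: only the longest survives when requested
  two <- line_graph(rbind(c(0, 0), c(500, 0), c(0, 50), c(40, 50)),
                    rbind(c(1, 2), c(3, 4)))
  kept <- prune_and_filter(two, morse_params(min_branch_um = 10,
                                             remove_disconnected = TRUE))
  expect_equal(total_length_um(kept), 500)
})

test_that("pruning never increases total length", {
  for (s in 1:5) {
    fx <- make_vessel_fixture(n_branches = 7, size = 256, snr = 10,
                              pixel_size_um = 2, seed = 100 + s)
    g <- extract_morse_skeleton(fx$image, morse_params(), 2)
    p <- prune_and_filter(g, morse_params())
    expect_lte(total_length_um(p), total_length_um(g) + 1e-9)
  }
})

test_that("branch smoothing fixes endpoints and shortens staircases", {
  # straight-line branch is unchanged
  straight <- line_graph(rbind(c(0, 0), c(20, 0)), cbind(1, 2))
  straight$edges$geom[[1]] <- cbind(seq(0, 20), 0)
  sm <- smooth_branches(embedded_graph(straight$vertices,
                                       straight$edges[, c("v1", "v2", "geom")],
                                       1), 5)
  expect_equal(total_length_um(sm), 20, tolerance = 1e-9)

  # unit staircase from (0,0) to (10,10): raw 20, smoothed in [10*sqrt(2), 20)
  stair <- cbind(rep(0:10, each = 2)[1:21], c(0, rep(1:10, each = 2)))
  vt <- tibble::tibble(id = 1:2, x = c(0, 10), y = c(0, 10))
  ed <- tibble::tibble(v1 = 1L, v2 = 2L, geom = list(stair))
  g <- embedded_graph(vt, ed, 1)
  expect_equal(total_length_um(g), 20, tolerance = 1e-9)
  smg <- smooth_branches(g, 5)
  expect_gte(total_length_um(smg), 10 * sqrt(2))
  expect_lt(total_length_um(smg), 20)
  # endpoints fixed
  gsm <- smg$edges$geom[[1]]
  expect_equal(gsm[1, ], c(0, 0))
  expect_equal(gsm[nrow(gsm), ], c(10, 10))
  # smoothed length >= euclidean distance between endpoints
  expect_gte(total_length_um(smg),
             sqrt(sum((gsm[1, ] - gsm[nrow(gsm), ])^2)) - 1e-9)

  # smoothing never changes the branch count
  fx <- make_vessel_fixture(n_branches = 5, size = 192, snr = Inf,
                            pixel_size_um = 2, seed = 44)
  ge <- prune_and_filter(extract_morse_skeleton(fx$image, morse_params(), 2),
                         morse_params())
  expect_equal(n_branches(smooth_branches(ge, 5)), n_branches(ge))
})

test_that("junction coordinates are identical before and after smoothing", {
  fx <- make_vessel_fixture(n_branches = 5, size = 192, snr = Inf,
                            pixel_size_um = 2, seed = 44)
  g <- prune_and_filter(extract_morse_skeleton(fx$image, morse_params(), 2),
                        morse_params())
  sm <- smooth_branches(g, 7)
  expect_equal(sm$vertices, g$vertices)
})
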