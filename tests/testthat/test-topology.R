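test_that("choose_root selects the graph center with deterministic ties", {
  # unit path v1-v2-v3-v4: center is v2 (tie with v3 broken to lower id)
  path4 <- line_graph(rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0)),
                      rbind(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(choose_root(path4), 2)

  # star: the hub minimizes eccentricity
  star <- line_graph(rbind(c(0, 0), c(10, 0), c(0, 6), c(-4, 0)),
                     rbind(c(1, 2), c(1, 3), c(1, 4)))
  expect_equal(choose_root(star), 1)

  # cycle of equal edges: all eccentricities equal, lowest id wins
  k <- 6
  ang <- 2 * pi * (0:(k - 1)) / k
  cyc <- line_graph(cbind(10 * cos(ang), 10 * sin(ang)),
                    cbind(1:k, c(2:k, 1)))
  expect_equal(choose_root(cyc), 1)

  expect_error(choose_root(mpmimage:::empty_embedded_graph()), "empty")
})

test_that("shortest-path tree is geodesic with deterministic predecessors", {
  # a tree input is returned as itself
  star <- line_graph(rbind(c(0, 0), c(10, 0), c(0, 6), c(-4, 0)),
                     rbind(c(1, 2), c(1, 3), c(1, 4)))
  tr <- shortest_path_tree(star, 1)
  expect_equal(sort(tr$dist), sort(c(`1` = 0, `2` = 10, `3` = 6, `4` = 4)))
  expect_true(all(tr$parent[c("2", "3", "4")] == 1))

  # unit triangle rooted at v1: edge v2-v3 is dropped
  tri <- line_graph(rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)),
                    rbind(c(1, 2), c(1, 3), c(2, 3)))
  trt <- shortest_path_tree(tri, 1)
  expect_equal(trt$parent[["2"]], 1)
  expect_equal(trt$parent[["3"]], 1)

  # 8-vertex unit cycle rooted at v1: 7 tree edges, total length 7
  k <- 8
  ang <- 2 * pi * (0:(k - 1)) / k
  r <- 0.5 / sin(pi / k)  # unit chord
  cyc <- line_graph(cbind(r * cos(ang), r * sin(ang)),
                    cbind(1:k, c(2:k, 1)))
  trc <- shortest_path_tree(cyc, 1)
  expect_equal(sum(trc$edge_weight, na.rm = TRUE), 7, tolerance = 1e-9)
  expect_equal(sum(!is.na(trc$parent)), 7)
})

test_that("barcodes match hand-computed path, star, and T examples", {
  # path of length 10 rooted at one end: one bar [-10, 0]
  p <- line_graph(rbind(c(0, 0), c(10, 0)), cbind(1, 2))
  bc <- compute_barcode(shortest_path_tree(p, 1))
  expect_equal(nrow(bc), 1)
  expect_equal(bc$birth, -10)
  expect_equal(bc$death, 0)

  # star with arms 10 / 6 / 4 rooted at the hub: persistences {10, 6, 4}
  star <- line_graph(rbind(c(0, 0), c(10, 0), c(0, 6), c(-4, 0)),
                     rbind(c(1, 2), c(1, 3), c(1, 4)))
  bs <- compute_barcode(shortest_path_tree(star, 1))
  expect_equal(sort(bs$persistence), c(4, 6, 10))

  # T: root at the end of a 5 um stem, arms 10 and 3 um from the junction
  tg <- line_graph(rbind(c(0, 0), c(0, 5), c(10, 5), c(0, 8)),
                   rbind(c(1, 2), c(2, 3), c(2, 4)))
  bt <- compute_barcode(shortest_path_tree(tg, 1))
  expect_equal(bt$birth, c(-15, -8))
  expect_equal(bt$death, c(0, -5))
  expect_equal(sum(bt$persistence), 18)  # equals total tree length
})

test_that("persistences sum to tree length on 100 random trees", {
  for (s in 1:100) {
    g <- random_tree_graph(sample(4:25, 1), seed = 1700 + s)
    root <- choose_root(g)
    tr <- shortest_path_tree(g, root)
    bc <- compute_barcode(tr)
    expect_equal(sum(bc$persistence), sum(tr$edge_weight, na.rm = TRUE),
                 tolerance = 1e-9)
    # one bar per leaf of the tree
    leaves <- sum(!(as.integer(names(tr$dist)) %in%
                      tr$parent[!is.na(tr$parent)]) &
                    as.integer(names(tr$dist)) != root)
    expect_equal(nrow(bc), leaves)
  }
})

test_that("barcode matches a brute-force oracle on small trees", {
  for (s in 1:20) {
    g <- random_tree_graph(sample(4:12, 1), seed = 2300 + s)
    tr <- shortest_path_tree(g, choose_root(g))
    bc <- compute_barcode(tr)
    oracle <- brute_force_barcode(tr)
    expect_equal(bc$leaf, oracle$leaf)
    expect_equal(bc$birth, oracle$birth, tolerance = 1e-12)
    expect_equal(bc$death, oracle$death, tolerance = 1e-12)
  }
})

test_that("for cyclic graphs, persistence sum is tree length <= graph length", {
  k <- 8
  ang <- 2 * pi * (0:(k - 1)) / k
  r <- 0.5 / sin(pi / k)
  cyc <- line_graph(cbind(r * cos(ang), r * sin(ang)),
                    cbind(1:k, c(2:k, 1)))
  tr <- shortest_path_tree(cyc, 1)
  bc <- compute_barcode(tr)
  expect_equal(sum(bc$persistence), 7, tolerance = 1e-9)
  expect_lt(sum(bc$persistence), total_length_um(cyc))
})

test_that("the barcode is invariant under rigid motions", {
  g <- random_tree_graph(12, seed = 77)
  th <- 0.7
  rot <- function(m) {
    cbind(cos(th) * m[, 1] - sin(th) * m[, 2] + 40,
          sin(th) * m[, 1] + cos(th) * m[, 2] - 15)
  }
  vt <- g$vertices
  moved_coords <- rot(cbind(vt$x, vt$y))
  moved <- embedded_graph(
    tibble::tibble(id = vt$id, x = moved_coords[, 1], y = moved_coords[, 2]),
    tibble::tibble(v1 = g$edges$v1, v2 = g$edges$v2,
                   geom = lapply(g$edges$geom, rot)),
    g$pixel_size_um)
  b1 <- compute_barcode(shortest_path_tree(g, choose_root(g)))
  b2 <- compute_barcode(shortest_path_tree(moved, choose_root(moved)))
  expect_equal(b1$birth, b2$birth, tolerance = 1e-9)
  expect_equal(b1$death, b2$death, tolerance = 1e-9)
})

test_that("network statistics summarize the barcode and graph", {
  tg <- line_graph(rbind(c(0, 0), c(0, 5), c(10, 5), c(0, 8)),
                   rbind(c(1, 2), c(2, 3), c(2, 4)))
  bc <- compute_barcode(shortest_path_tree(tg, 1))
  st <- summarize_network(bc, tg)
  expect_equal(st$branch_count, 2)
  expect_equal(st$tree_length_um, 18)
  expect_equal(st$total_length_um, 18)
  expect_equal(st$mean_branch_length_um, 9)

  empty <- analyze_topology(mpmimage:::empty_embedded_graph())
  expect_equal(empty$stats$branch_count, 0)
  expect_equal(empty$stats$total_length_um, 0)
  expect_equal(empty$stats$mean_branch_length_um, 0)
})
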