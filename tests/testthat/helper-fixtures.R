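# Shared builders and independent oracles used across the test files.

# Straight-line embedded graph from a vertex table and an edge list; geometry
# is the straight segment between endpoint coordinates.
line_graph <- function(coords, edges, pixel_size_um = 1) {
  vt <- tibble::tibble(id = seq_len(nrow(coords)),
                       x = coords[, 1], y = coords[, 2])
  ed <- tibble::tibble(
    v1 = edges[, 1], v2 = edges[, 2],
    geom = lapply(seq_len(nrow(edges)), function(i) {
      rbind(coords[edges[i, 1], ], coords[edges[i, 2], ])
    }))
  embedded_graph(vt, ed, pixel_size_um)
}

# Random abstract tree as an embedded graph: vertices at random coordinates,
# each new vertex attached to a uniformly chosen existing vertex.
random_tree_graph <- function(n_vertices, seed) {
  set.seed(seed)
  coords <- matrix(runif(n_vertices * 2, 0, 100), ncol = 2)
  edges <- cbind(sapply(seq(2, n_vertices), function(i) {
    sample.int(i - 1, 1)
  }), seq(2, n_vertices))
  line_graph(coords, edges)
}

# Independent brute-force barcode oracle for trees: for each leaf, walk its
# path to the root; the bar dies at the first path vertex also used by a
# strictly elder leaf (deeper, ties by smaller id), or at the root.
brute_force_barcode <- function(tree) {
  dist <- tree$dist
  parent <- tree$parent
  ids <- as.integer(names(dist))
  root <- tree$root
  path_of <- function(v) {
    p <- v
    while (!is.na(parent[[as.character(v)]])) {
      v <- parent[[as.character(v)]]
      p <- c(p, v)
    }
    p
  }
  leaves <- ids[!(ids %in% parent[!is.na(parent)]) & ids != root]
  paths <- lapply(leaves, path_of)
  names(paths) <- leaves
  elder <- function(a, b) {
    # TRUE if leaf a is elder than leaf b
    da <- dist[[as.character(a)]]; db <- dist[[as.character(b)]]
    da > db || (da == db && a < b)
  }
  bars <- lapply(leaves, function(l) {
    path <- paths[[as.character(l)]]
    rivals <- leaves[vapply(leaves, function(r) {
      r != l && elder(r, l)
    }, logical(1))]
    death <- 0
    for (v in path) {
      hit <- any(vapply(rivals, function(r) {
        v %in% paths[[as.character(r)]]
      }, logical(1)))
      if (hit) {
        death <- -dist[[as.character(v)]]
        break
      }
    }
    c(leaf = l, birth = -dist[[as.character(l)]], death = death)
  })
  df <- as.data.frame(do.call(rbind, bars))
  df$persistence <- df$death - df$birth
  df[order(-df$persistence, df$leaf), ]
}

# Length of a thinned 1-px skeleton, as the minimum-spanning-tree length of
# its 8-connected pixel graph (weights 1 / sqrt(2)). Raw link counting would
# double-count the triangle shortcuts thinning leaves on staircases; the MST
# is the minimal connected length through all skeleton pixels. Independent
# oracle for total skeleton length of noise-free renderable shapes.
skeleton_length <- function(mask) {
  sk <- mpmimage:::thin_skeleton(mask)
  idx <- which(sk == 1)
  nr <- nrow(sk)
  from <- integer(); to <- integer(); w <- numeric()
  off <- list(c(0, 1), c(1, -1), c(1, 0), c(1, 1))  # forward half
  for (o in off) {
    r <- (idx - 1) %% nr + 1
    c <- (idx - 1) %/% nr + 1
    r2 <- r + o[1]; c2 <- c + o[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncol(sk)
    nb <- (c2[ok] - 1) * nr + r2[ok]
    hit <- sk[nb] == 1
    from <- c(from, idx[ok][hit])
    to <- c(to, nb[hit])
    w <- c(w, rep(if (all(o != 0)) sqrt(2) else 1, sum(hit)))
  }
  ids <- sort(unique(c(from, to)))
  g <- igraph::graph_from_edgelist(
    cbind(match(from, ids), match(to, ids)), directed = FALSE)
  igraph::E(g)$weight <- w
  sum(igraph::E(igraph::mst(g))$weight)
}

# Embedded graph of the thinning skeleton of a binary mask: MST of the
# skeleton pixel graph (drops the triangle shortcuts thinning leaves on
# staircases), assembled into branches.
thinning_skeleton_graph <- function(mask, pixel_size_um = 1) {
  sk <- mpmimage:::thin_skeleton(mask)
  idx <- which(sk == 1)
  nr <- nrow(sk)
  from <- integer(); to <- integer(); w <- numeric()
  for (o in list(c(0, 1), c(1, -1), c(1, 0), c(1, 1))) {
    r <- (idx - 1) %% nr + 1
    c <- (idx - 1) %/% nr + 1
    r2 <- r + o[1]; c2 <- c + o[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncol(sk)
    nb <- (c2[ok] - 1) * nr + r2[ok]
    hit <- sk[nb] == 1
    from <- c(from, idx[ok][hit])
    to <- c(to, nb[hit])
    w <- c(w, rep(if (all(o != 0)) sqrt(2) else 1, sum(hit)))
  }
  ids <- sort(unique(c(from, to)))
  g <- igraph::graph_from_edgelist(
    cbind(match(from, ids), match(to, ids)), directed = FALSE)
  igraph::E(g)$weight <- w
  mst <- igraph::mst(g)
  el <- igraph::as_edgelist(mst)
  em <- cbind(ids[as.integer(el[, 1])], ids[as.integer(el[, 2])])
  mpmimage:::pixel_graph_to_embedded(em, nr, pixel_size_um)
}

# Small labeled plane set for invasion-classifier tests.
make_invasion_training_set <- function(n_stacks = 20, seed0 = 400) {
  imgs <- list()
  labs <- logical()
  for (i in seq_len(n_stacks)) {
    di <- (i * 7) %% 10
    fx <- make_invasion_fixture(di, seed = seed0 + i)
    imgs <- c(imgs, fx$stack$planes)
    labs <- c(labs, fx$labels)
  }
  list(images = imgs, labels = labs)
}

# Tube image/mask pairs for segmentation-model tests.
make_seg_split <- function(n, seed0) {
  lapply(seq_len(n), function(i) {
    fx <- make_vessel_fixture(n_branches = 3, size = 96, snr = 6,
                              tube_width_px = 5,
                              length_range_um = c(30, 120),
                              pixel_size_um = 2, seed = seed0 + i)
    list(img = fx$image, mask = fx$true_mask * 1)
  })
}
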