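#' Embedded vessel-network graph
#'
#' A planar geometric multigraph representing a microvessel network: vertices
#' carry pixel coordinates `(x, y)` (x = column, y = row, y increasing
#' downward), and every edge carries the full polyline geometry of the
#' vessel centerline it traces. Edges are the *branches* of the network:
#' maximal paths between junction or leaf vertices, so interior polyline
#' points always have degree 2.
#'
#' @param vertices tibble with columns `id`, `x`, `y`.
#' @param edges tibble with columns `v1`, `v2`, `geom` (list of n x 2
#'   matrices whose first/last rows coincide with the endpoint vertex
#'   coordinates).
#' @param pixel_size_um physical pixel size, microns per pixel.
#' @return An object of class `embedded_graph`.
#' @export
embedded_graph <- function(vertices, edges, pixel_size_um = 1) {
  stopifnot(is.data.frame(vertices), is.data.frame(edges),
            pixel_size_um > 0)
  vertices <- tibble::as_tibble(vertices)
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) > 0) {
    len_px <- vapply(edges$geom, polyline_length, numeric(1))
    edges$length_px <- len_px
    edges$length_um <- len_px * pixel_size_um
    edges$edge_id <- seq_len(nrow(edges))
    coords <- setNames(split(as.matrix(vertices[, c("x", "y")]),
                             seq_len(nrow(vertices))), vertices$id)
    for (i in seq_len(nrow(edges))) {
      g <- edges$geom[[i]]
      a <- coords[[as.character(edges$v1[i])]]
      b <- coords[[as.character(edges$v2[i])]]
      if (max(abs(g[1, ] - a)) > 1e-6 ||
          max(abs(g[nrow(g), ] - b)) > 1e-6) {
        stop("edge polyline endpoints must coincide with vertex coordinates",
             call. = FALSE)
      }
    }
  } else {
    edges <- tibble::tibble(v1 = integer(), v2 = integer(), geom = list(),
                            length_px = numeric(), length_um = numeric(),
                            edge_id = integer())
  }
  structure(list(vertices = vertices, edges = edges,
                 pixel_size_um = pixel_size_um),
            class = "embedded_graph")
}

empty_embedded_graph <- function(pixel_size_um = 1) {
  embedded_graph(tibble::tibble(id = integer(), x = numeric(), y = numeric()),
                 tibble::tibble(v1 = integer(), v2 = integer(), geom = list()),
                 pixel_size_um)
}

polyline_length <- function(g) {
  if (nrow(g) < 2) return(0)
  sum(sqrt(rowSums((g[-1, , drop = FALSE] - g[-nrow(g), , drop = FALSE])^2)))
}

#' @export
print.embedded_graph <- function(x, ...) {
  cat(sprintf(
    "<embedded_graph> %d vertices, %d branch(es), total length %.1f um (%.3g um/px)\n",
    nrow(x$vertices), nrow(x$edges), total_length_um(x), x$pixel_size_um))
  invisible(x)
}

#' @rdname embedded_graph
#' @param graph an `embedded_graph`.
#' @export
n_branches <- function(graph) nrow(graph$edges)

#' @rdname embedded_graph
#' @export
total_length_um <- function(graph) {
  if (nrow(graph$edges) == 0) return(0)
  sum(graph$edges$length_um)
}

#' Vertex degrees of an embedded graph (self-loops count twice)
#' @noRd
graph_degrees <- function(graph) {
  ids <- graph$vertices$id
  d <- setNames(integer(length(ids)), ids)
  if (nrow(graph$edges) > 0) {
    tab <- table(c(graph$edges$v1, graph$edges$v2))
    d[names(tab)] <- as.integer(tab)
  }
  d
}

#' Tidy the branches of an embedded graph
#'
#' @param x an [embedded_graph()].
#' @param ... unused.
#' @return A tibble with one row per branch: `edge_id`, `v1`, `v2`,
#'   `length_px`, `length_um`, `n_points`.
#' @export
tidy.embedded_graph <- function(x, ...) {
  e <- x$edges
  tibble::tibble(
    edge_id = e$edge_id, v1 = e$v1, v2 = e$v2,
    length_px = e$length_px, length_um = e$length_um,
    n_points = vapply(e$geom, nrow, integer(1))
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' Convert an embedded graph to an igraph object
#'
#' Vertices keep their coordinates as attributes; edges carry `length_um`
#' weights, so igraph's weighted algorithms operate on geodesic branch
#' lengths.
#'
#' @param graph an [embedded_graph()].
#' @return An `igraph` graph.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "embedded_graph"))
  v <- graph$vertices
  g <- igraph::make_empty_graph(n = nrow(v), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(v$id))
  g <- igraph::set_vertex_attr(g, "x", value = v$x)
  g <- igraph::set_vertex_attr(g, "y", value = v$y)
  if (nrow(graph$edges) > 0) {
    el <- rbind(match(graph$edges$v1, v$id), match(graph$edges$v2, v$id))
    g <- igraph::add_edges(g, as.vector(el),
                           attr = list(weight = graph$edges$length_um,
                                       edge_id = graph$edges$edge_id))
  }
  g
}

# --- chain assembly ---------------------------------------------------------

# Merge an abstract multigraph of geometric edges into maximal chains between
# anchor nodes (degree != 2, or nodes carrying self-loops; pure cycles get
# their smallest node as anchor). Input: nodes tibble(id, x, y) and edges
# tibble(v1, v2, geom). Output: an embedded_graph whose edges are branches.
assemble_chains <- function(nodes, edges, pixel_size_um = 1) {
  if (nrow(edges) == 0) return(empty_embedded_graph(pixel_size_um))
  ids <- nodes$id
  idx <- setNames(seq_along(ids), ids)
  m <- nrow(edges)
  a <- idx[as.character(edges$v1)]
  b <- idx[as.character(edges$v2)]
  deg <- tabulate(c(a, b), nbins = length(ids))
  selfloop <- a == b
  anchor <- deg != 2
  anchor[a[selfloop]] <- TRUE
  # incidence lists
  inc <- vector("list", length(ids))
  for (e in seq_len(m)) {
    inc[[a[e]]] <- c(inc[[a[e]]], e)
    if (!selfloop[e]) inc[[b[e]]] <- c(inc[[b[e]]], e)
  }
  used <- logical(m)
  out_v1 <- integer(); out_v2 <- integer(); out_geom <- list()

  orient_geom <- function(e, from) {
    g <- edges$geom[[e]]
    if (a[e] == from) g else g[rev(seq_len(nrow(g))), , drop = FALSE]
  }
  other_end <- function(e, from) if (a[e] == from) b[e] else a[e]

  walk <- function(start, e0) {
    geoms <- list(orient_geom(e0, start))
    used[e0] <<- TRUE
    cur <- other_end(e0, start)
    while (!anchor[cur]) {
      nxt_e <- inc[[cur]][!used[inc[[cur]]]]
      if (length(nxt_e) == 0) break  # closed a cycle back into the chain
      nxt_e <- nxt_e[1]
      used[nxt_e] <<- TRUE
      geoms[[length(geoms) + 1]] <- orient_geom(nxt_e, cur)
      cur <- other_end(nxt_e, cur)
    }
    full <- do.call(rbind, lapply(seq_along(geoms), function(i) {
      g <- geoms[[i]]
      if (i == 1) g else g[-1, , drop = FALSE]
    }))
    list(v1 = ids[start], v2 = ids[cur], geom = full)
  }

  for (v in which(anchor)) {
    repeat {
      avail <- inc[[v]][!used[inc[[v]]]]
      if (length(avail) == 0) break
      ch <- walk(v, avail[1])
      out_v1 <- c(out_v1, ch$v1)
      out_v2 <- c(out_v2, ch$v2)
      out_geom[[length(out_geom) + 1]] <- ch$geom
    }
  }
  # pure cycles: every node degree 2, no anchors touched
  while (any(!used)) {
    e0 <- which(!used)[1]
    start <- min(a[e0], b[e0])
    anchor[start] <- TRUE
    ch <- walk(start, e0)
    out_v1 <- c(out_v1, ch$v1)
    out_v2 <- c(out_v2, ch$v2)
    out_geom[[length(out_geom) + 1]] <- ch$geom
  }

  used_ids <- sort(unique(c(out_v1, out_v2)))
  vt <- nodes[match(used_ids, nodes$id), ]
  embedded_graph(vt,
                 tibble::tibble(v1 = out_v1, v2 = out_v2, geom = out_geom),
                 pixel_size_um)
}

# Build an embedded graph from unit pixel edges (2-column matrix of linear
# pixel indices, column-major in an nr-row image).
pixel_graph_to_embedded <- function(edge_mat, nr, pixel_size_um = 1) {
  if (is.null(edge_mat) || nrow(edge_mat) == 0) {
    return(empty_embedded_graph(pixel_size_um))
  }
  # canonical orientation + dedupe
  lo <- pmin(edge_mat[, 1], edge_mat[, 2])
  hi <- pmax(edge_mat[, 1], edge_mat[, 2])
  keep <- lo != hi
  key <- paste(lo[keep], hi[keep])
  u <- !duplicated(key)
  lo <- lo[keep][u]; hi <- hi[keep][u]
  px <- sort(unique(c(lo, hi)))
  xy <- cbind(x = (px - 1) %/% nr + 1, y = (px - 1) %% nr + 1)
  nodes <- tibble::tibble(id = px, x = xy[, 1], y = xy[, 2])
  geom <- purrr::map2(lo, hi, function(p, q) {
    rbind(c((p - 1) %/% nr + 1, (p - 1) %% nr + 1),
          c((q - 1) %/% nr + 1, (q - 1) %% nr + 1))
  })
  assemble_chains(nodes, tibble::tibble(v1 = lo, v2 = hi, geom = geom),
                  pixel_size_um)
}
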