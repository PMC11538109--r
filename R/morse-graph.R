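#' Parameters of Morse-skeleton extraction and simplification
#'
#' @param persistence_cutoff peak-cancellation threshold, in intensity units
#'   of the vesselness image. Peaks whose persistence (peak height minus the
#'   saddle where they merge into an elder peak) falls below the cutoff are
#'   cancelled together with their saddle, which removes noise spurs while
#'   keeping ridge geometry. `NULL` (default) selects
#'   `max(2 * mad(image), 1e-3 * range(image))` per image: twice the robust
#'   noise scale, with a small floor that cancels the zero-persistence
#'   plateau artifacts of exactly-valued synthetic backgrounds.
#' @param min_branch_um minimum branch length; leaf branches shorter than
#'   this are pruned (default 10 um — shorter branches are usually noise).
#' @param smoothing_window odd moving-average window (polyline points) used
#'   by [smooth_branches()]; default 5.
#' @param remove_disconnected drop all connected components except the one
#'   with the largest total length.
#' @param value_floor_frac peaks whose height exceeds
#'   `min + value_floor_frac * range` are significant regardless of
#'   persistence and are never cancelled. Peaks along a ridge of roughly
#'   constant height have low persistence but high value; this second cut
#'   (persistence *or* height) keeps ridge ends while cancellation removes
#'   low-lying noise peaks.
#' @param keep_loops trace ridge arcs for saddles that close a cycle of the
#'   network. Off by default: on noisy bands every ring-split saddle would
#'   add a spurious cycle that no leaf pruning can remove; without loop arcs
#'   a true cycle is still recovered except for a short gap at its dimmest
#'   saddle.
#' @return A list of class `morse_params`.
#' @export
morse_params <- function(persistence_cutoff = NULL, min_branch_um = 10,
                         smoothing_window = 5, remove_disconnected = FALSE,
                         value_floor_frac = 0.25, keep_loops = FALSE) {
  stopifnot(is.null(persistence_cutoff) || persistence_cutoff >= 0,
            min_branch_um >= 0,
            smoothing_window >= 3, smoothing_window %% 2 == 1,
            value_floor_frac >= 0, value_floor_frac <= 1)
  structure(list(persistence_cutoff = persistence_cutoff,
                 min_branch_um = min_branch_um,
                 smoothing_window = smoothing_window,
                 remove_disconnected = remove_disconnected,
                 value_floor_frac = value_floor_frac,
                 keep_loops = keep_loops),
            class = "morse_params")
}

#' Extract the Morse skeleton of a vesselness image
#'
#' Treats the grayscale image as a terrain and extracts its mountain-ridge
#' network as an embedded graph. The construction is discrete Morse theory
#' on the 8-connected pixel grid: pixels are swept in descending intensity
#' order under a union-find, which identifies local maxima, the saddles where
#' superlevel components merge, and each younger peak's persistence. Ridge
#' arcs are traced from every saddle by steepest ascent to the maxima on
#' either side; (peak, saddle) pairs with persistence below the cutoff are
#' cancelled, which iteratively removes noise spurs from the arc network
#' while concatenating ridge geometry through cancelled peaks. The surviving
#' arcs form a subgraph of the pixel grid (edges horizontal, vertical, or
#' 45 degrees); its maximal paths between junctions and leaves become the
#' branches of the returned [embedded_graph()]. Saddles that close a loop of
#' the network are detected separately and retained when they stand clear of
#' the background level, so cyclic networks keep their cycles.
#'
#' Ridges connect peaks across dim gaps, which is what makes this extractor
#' suited to microvessel images of non-uniform brightness; background
#' suppression (see [refine_probability_map()] / [sato_vesselness_2d()])
#' should precede extraction so that only vessel ridges remain.
#'
#' @param vesselness 2D numeric matrix (any intensity scale).
#' @param params a [morse_params()].
#' @param pixel_size_um physical pixel size attached to the output graph.
#' @return An [embedded_graph()]; empty for a constant image.
#' @export
extract_morse_skeleton <- function(vesselness, params = morse_params(),
                                   pixel_size_um = 1) {
  assert_image(vesselness)
  rng <- range(vesselness)
  if (rng[2] <= rng[1]) return(empty_embedded_graph(pixel_size_um))
  delta <- params$persistence_cutoff
  if (is.null(delta)) {
    delta <- max(2 * mad(vesselness), 1e-3 * (rng[2] - rng[1]))
  }
  loop_min <- if (isTRUE(params$keep_loops)) median(vesselness) + delta
  else Inf
  res <- .morse_sweep(vesselness, loop_min)
  ev <- res$events
  if (nrow(ev) == 0) return(empty_embedded_graph(pixel_size_um))

  # ridges may bridge dim gaps, but saddles lying in the exact
  # global-minimum plateau are masked-out background: never bridge there
  floor_val <- rng[1] + 1e-9 * (rng[2] - rng[1])
  bridge_ok <- vesselness[ev[, 1]] > floor_val
  ev <- ev[bridge_ok, , drop = FALSE]
  res$is_loop <- res$is_loop[bridge_ok]
  res$arcs <- res$arcs[bridge_ok]
  if (nrow(ev) == 0) return(empty_embedded_graph(pixel_size_um))

  value_floor <- rng[1] + params$value_floor_frac * (rng[2] - rng[1])
  kept_peaks <- res$peaks[res$peak_persistence >= delta |
                            vesselness[res$peaks] >= value_floor]
  loop_ends <- unique(c(ev[res$is_loop, 2], ev[res$is_loop, 3]))
  protected <- as.character(unique(c(kept_peaks, loop_ends)))

  verts <- as.character(sort(unique(c(ev[, 2], ev[, 3]))))
  g <- igraph::make_empty_graph(n = length(verts), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = verts)
  el <- rbind(match(as.character(ev[, 2]), verts),
              match(as.character(ev[, 3]), verts))
  g <- igraph::add_edges(g, as.vector(el),
                         attr = list(eid = seq_len(nrow(ev))))
  # persistence cancellation: iteratively remove sub-cutoff leaf peaks
  # together with their pairing saddle's arc
  repeat {
    d <- igraph::degree(g, loops = TRUE)
    nm <- igraph::V(g)$name
    drop <- which(d <= 1 & !(nm %in% protected))
    if (length(drop) == 0) break
    g <- igraph::delete_vertices(g, drop)
  }
  eids <- igraph::E(g)$eid
  if (length(eids) == 0) return(empty_embedded_graph(pixel_size_um))

  # union of surviving ridge arcs as unit pixel edges
  steps <- purrr::map(res$arcs[eids], function(path) {
    if (length(path) < 2) return(NULL)
    cbind(path[-length(path)], path[-1])
  })
  edge_mat <- do.call(rbind, steps)
  pixel_graph_to_embedded(edge_mat, nrow(vesselness), pixel_size_um)
}

#' Prune short leaf branches and drop disconnected components
#'
#' Removes leaf branches (branches with a degree-1 endpoint) whose geodesic
#' length is below `min_branch_um`, re-merges the degree-2 chains this
#' exposes, and repeats until stable; such branches are usually rasterization
#' or segmentation noise. When `remove_disconnected` is set, all connected
#' components except the one with the largest total length are removed.
#'
#' @param graph an [embedded_graph()].
#' @param params a [morse_params()]; `min_branch_um` and
#'   `remove_disconnected` are used.
#' @return A pruned [embedded_graph()].
#' @export
prune_and_filter <- function(graph, params = morse_params()) {
  stopifnot(inherits(graph, "embedded_graph"))
  min_um <- params$min_branch_um
  repeat {
    if (nrow(graph$edges) == 0) break
    deg <- graph_degrees(graph)
    e <- graph$edges
    is_leaf <- deg[as.character(e$v1)] == 1 | deg[as.character(e$v2)] == 1
    short <- is_leaf & e$length_um < min_um & e$v1 != e$v2
    if (!any(short)) break
    keep <- e[!short, c("v1", "v2", "geom")]
    used <- unique(c(keep$v1, keep$v2))
    vt <- graph$vertices[graph$vertices$id %in% used, ]
    graph <- assemble_chains(vt, keep, graph$pixel_size_um)
  }
  if (params$remove_disconnected && nrow(graph$edges) > 0) {
    ig <- as_igraph(graph)
    comp <- igraph::components(ig)$membership
    len_by_comp <- tapply(graph$edges$length_um,
                          comp[as.character(graph$edges$v1)], sum)
    best <- names(len_by_comp)[which.max(len_by_comp)]
    keep_v <- names(comp)[comp == as.integer(best)]
    e <- graph$edges
    sel <- as.character(e$v1) %in% keep_v
    vt <- graph$vertices[as.character(graph$vertices$id) %in% keep_v, ]
    graph <- assemble_chains(vt, e[sel, c("v1", "v2", "geom")],
                             graph$pixel_size_um)
  }
  graph
}

#' Moving-average smoothing of branch polylines
#'
#' The Morse skeleton is a subgraph of the pixel grid, so its polylines are
#' staircases of horizontal, vertical, and 45-degree steps that overestimate
#' the length of oblique vessels. Each branch polyline's interior points are
#' replaced by a centered moving average of the coordinates (window truncated
#' near the ends); branch endpoints — junctions and leaves — are kept fixed,
#' so topology is unchanged and smoothing never increases length.
#'
#' @param graph an [embedded_graph()].
#' @param window odd window size (polyline points), at least 3.
#' @return An [embedded_graph()] with smoothed geometry.
#' @export
smooth_branches <- function(graph, window = 5) {
  stopifnot(inherits(graph, "embedded_graph"),
            window >= 3, window %% 2 == 1)
  if (nrow(graph$edges) == 0) return(graph)
  h <- (window - 1) / 2
  sm <- function(g) {
    n <- nrow(g)
    if (n <= 2) return(g)
    out <- g
    cs <- rbind(0, apply(g, 2, cumsum))
    i <- 2:(n - 1)
    lo <- pmax(i - h, 1)
    hi <- pmin(i + h, n)
    out[i, ] <- (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) /
      (hi - lo + 1)
    out[1, ] <- g[1, ]
    out[n, ] <- g[n, ]
    out
  }
  e <- graph$edges
  e$geom <- purrr::map(e$geom, sm)
  embedded_graph(graph$vertices, e[, c("v1", "v2", "geom")],
                 graph$pixel_size_um)
}
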