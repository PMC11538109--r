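#' Choose the root of the network: the graph center
#'
#' The barcode filtration needs a root "at the center of the network". This
#' is operationalized as the vertex of minimum eccentricity (smallest maximal
#' geodesic distance to any other vertex) within the connected component of
#' largest total length, with ties broken by smallest vertex id.
#'
#' @param graph an [embedded_graph()].
#' @return The root vertex id (integer).
#' @export
choose_root <- function(graph) {
  stopifnot(inherits(graph, "embedded_graph"))
  if (nrow(graph$vertices) == 0) {
    stop("empty graph: no root to choose", call. = FALSE)
  }
  if (nrow(graph$edges) == 0) return(min(graph$vertices$id))
  ig <- as_igraph(graph)
  comp <- igraph::components(ig)$membership
  len_by_comp <- tapply(graph$edges$length_um,
                        comp[as.character(graph$edges$v1)], sum)
  best <- as.integer(names(len_by_comp)[which.max(len_by_comp)])
  vnames <- names(comp)[comp == best]
  sub <- igraph::induced_subgraph(ig, vnames)
  d <- igraph::distances(sub, weights = igraph::E(sub)$weight)
  ecc <- apply(d, 1, max)
  ids <- as.integer(igraph::V(sub)$name)
  # float tolerance so symmetric layouts tie exactly, then smallest id
  cand <- ids[ecc <= min(ecc) * (1 + 1e-9) + 1e-12]
  min(cand)
}

#' Geodesic shortest-path tree from a root
#'
#' Computes the length-weighted shortest-path tree of the root's connected
#' component. Each non-root vertex keeps one predecessor edge; when several
#' predecessors give the same geodesic distance, the smallest predecessor id
#' wins, which makes the tree deterministic.
#'
#' @param graph an [embedded_graph()].
#' @param root vertex id present in `graph`.
#' @return A list of class `sp_tree`: `root`, `dist` (named geodesic
#'   distances in um), `parent` (named vector, `NA` for the root), and
#'   `edge_weight` (length of each vertex's predecessor edge).
#' @export
shortest_path_tree <- function(graph, root) {
  stopifnot(inherits(graph, "embedded_graph"))
  if (!root %in% graph$vertices$id) {
    stop("root is not a vertex of the graph", call. = FALSE)
  }
  ig <- as_igraph(graph)
  rname <- as.character(root)
  d <- igraph::distances(ig, v = rname, weights = igraph::E(ig)$weight)[1, ]
  reach <- names(d)[is.finite(d)]
  ids <- as.integer(reach)
  dist <- setNames(d[reach], reach)
  parent <- setNames(rep(NA_integer_, length(ids)), reach)
  wgt <- setNames(rep(NA_real_, length(ids)), reach)
  e <- graph$edges
  if (nrow(e) > 0) {
    # candidate predecessor relations from both edge orientations
    cand <- rbind(
      data.frame(child = e$v2, par = e$v1, w = e$length_um),
      data.frame(child = e$v1, par = e$v2, w = e$length_um)
    )
    cand <- cand[cand$child != root, ]
    cand <- cand[as.character(cand$child) %in% reach &
                   as.character(cand$par) %in% reach, ]
    ok <- abs(dist[as.character(cand$par)] + cand$w -
                dist[as.character(cand$child)]) < 1e-9
    cand <- cand[ok, ]
    cand <- cand[order(cand$child, cand$par), ]
    first <- !duplicated(cand$child)
    sel <- cand[first, ]
    parent[as.character(sel$child)] <- sel$par
    wgt[as.character(sel$child)] <- sel$w
  }
  structure(list(root = root, dist = dist, parent = parent,
                 edge_weight = wgt),
            class = "sp_tree")
}

#' @export
print.sp_tree <- function(x, ...) {
  cat(sprintf("<sp_tree> root %d | %d vertices | total length %.2f um\n",
              x$root, length(x$dist), sum(x$edge_weight, na.rm = TRUE)))
  invisible(x)
}

#' Persistence barcode of the shortest-path-tree filtration
#'
#' The filtration function on the network is `f(x) = -dist(x, root)`: as the
#' threshold `t` increases from the deepest leaf toward 0, the tree grows
#' from its leaves toward the root. Every leaf spawns a bar at its birth
#' value `b = -dist(leaf, root)`; when two growing branches merge, the
#' younger bar (the shorter-reaching leaf) dies at the merge vertex (elder
#' rule; ties between equidistant leaves broken by smaller leaf id). The
#' globally deepest leaf's bar dies at 0, the root. Each bar's persistence
#' `d - b` is the length of one branch, so persistences sum exactly to the
#' total tree length.
#'
#' @param tree an [shortest_path_tree()] result.
#' @return A tibble of class `barcode`: `leaf`, `birth`, `death`,
#'   `persistence` (um), sorted by decreasing persistence, with the root id
#'   as attribute `"root"`.
#' @export
compute_barcode <- function(tree) {
  stopifnot(inherits(tree, "sp_tree"))
  ids <- as.integer(names(tree$dist))
  n <- length(ids)
  if (n == 1) {
    out <- tibble::tibble(leaf = integer(), birth = numeric(),
                          death = numeric(), persistence = numeric())
    attr(out, "root") <- tree$root
    class(out) <- c("barcode", class(out))
    return(out)
  }
  parent <- tree$parent
  dist <- tree$dist
  has_child <- unique(parent[!is.na(parent)])
  leaves <- ids[!(ids %in% has_child) & ids != tree$root]
  # representative (deepest descendant leaf) propagation from leaves to root;
  # process vertices in decreasing distance so children resolve first
  ord <- names(sort(dist, decreasing = TRUE))
  rep_leaf <- setNames(rep(NA_integer_, n), names(dist))
  rep_leaf[as.character(leaves)] <- leaves
  bars_leaf <- integer(); bars_birth <- numeric(); bars_death <- numeric()
  children <- split(ids[!is.na(parent)], parent[!is.na(parent)])
  for (v in ord) {
    vid <- as.integer(v)
    ch <- children[[v]]
    cand <- rep_leaf[as.character(ch)]
    cand <- cand[!is.na(cand)]
    if (vid %in% leaves) cand <- c(cand, vid)
    if (length(cand) == 0) next
    # elder rule: the deepest candidate survives; ties -> smaller leaf id
    cd <- dist[as.character(cand)]
    winner <- cand[order(-cd, cand)][1]
    losers <- setdiff(cand, winner)
    for (l in losers) {
      bars_leaf <- c(bars_leaf, l)
      bars_birth <- c(bars_birth, -dist[[as.character(l)]])
      bars_death <- c(bars_death, -dist[[v]])
    }
    rep_leaf[v] <- winner
  }
  w <- rep_leaf[[as.character(tree$root)]]
  bars_leaf <- c(bars_leaf, w)
  bars_birth <- c(bars_birth, -dist[[as.character(w)]])
  bars_death <- c(bars_death, 0)
  out <- tibble::tibble(leaf = bars_leaf, birth = bars_birth,
                        death = bars_death,
                        persistence = bars_death - bars_birth)
  out <- out[order(-out$persistence, out$leaf), ]
  attr(out, "root") <- tree$root
  class(out) <- c("barcode", class(out))
  out
}

#' Branch statistics of a microvessel network
#'
#' Summarizes the persistent-homology branch decomposition: the number of
#' branches is the number of bars, the mean branch length is the mean bar
#' persistence, and lengths are reported both for the full graph (all edge
#' polylines) and for the shortest-path tree (sum of persistences; equal to
#' the graph length when the network is a tree).
#'
#' @param barcode a [compute_barcode()] result.
#' @param graph the [embedded_graph()] the barcode was computed from.
#' @return A one-row tibble: `branch_count`, `total_length_um` (graph),
#'   `tree_length_um` (sum of persistences), `mean_branch_length_um`.
#' @export
summarize_network <- function(barcode, graph) {
  stopifnot(inherits(barcode, "barcode"), inherits(graph, "embedded_graph"))
  n <- nrow(barcode)
  tibble::tibble(
    branch_count = n,
    total_length_um = total_length_um(graph),
    tree_length_um = if (n > 0) sum(barcode$persistence) else 0,
    mean_branch_length_um = if (n > 0) mean(barcode$persistence) else 0
  )
}

#' Full topological analysis of an embedded graph
#'
#' Convenience wrapper: chooses the root, builds the shortest-path tree,
#' computes the barcode, and returns network statistics. Statistics describe
#' the largest component (the barcode is defined on the root's component);
#' apply [prune_and_filter()] with `remove_disconnected` upstream when other
#' components should be excluded explicitly.
#'
#' @param graph an [embedded_graph()].
#' @return A list: `root`, `tree`, `barcode`, `stats`.
#' @export
analyze_topology <- function(graph) {
  stopifnot(inherits(graph, "embedded_graph"))
  if (nrow(graph$edges) == 0) {
    bc <- tibble::tibble(leaf = integer(), birth = numeric(),
                         death = numeric(), persistence = numeric())
    class(bc) <- c("barcode", class(bc))
    return(list(root = NA_integer_, tree = NULL, barcode = bc,
                stats = tibble::tibble(branch_count = 0L,
                                       total_length_um = 0,
                                       tree_length_um = 0,
                                       mean_branch_length_um = 0)))
  }
  root <- choose_root(graph)
  tree <- shortest_path_tree(graph, root)
  bc <- compute_barcode(tree)
  list(root = root, tree = tree, barcode = bc,
       stats = summarize_network(bc, graph))
}
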