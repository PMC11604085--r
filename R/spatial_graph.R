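#' Build a pruned Delaunay spatial graph for one ROI
#'
#' Cells are triangulated (Delaunay, via `deldir`) and long cell-cell
#' links are removed at the `prune_percentile`-th percentile of the
#' ROI's edge lengths. Pruning is per-ROI because cell densities (and
#' hence typical link lengths) differ between ROIs.
#'
#' Fewer than 3 cells, or fully collinear cells, fall back to the
#' complete graph (still subject to pruning at < 100th percentile only
#' when at least two edges exist). Duplicate coordinates are jittered by
#' at most 1e-6 um with a warning.
#'
#' @param cells data frame with `cell_id`, `x_um`, `y_um` (one ROI).
#' @param prune_percentile percentile in (0, 100\]; default 99.
#' @param roi_id optional ROI identifier stored on the graph.
#' @return A `spatial_graph`: list with `cell_id`, `x`, `y`, `edges`
#'   (data frame `i`, `j`, `length_um`; 1-based indices, i < j),
#'   `prune_threshold_um`, `adj` (adjacency list) and `roi_id`.
#' @export
build_spatial_graph <- function(cells, prune_percentile = 99, roi_id = NULL) {
  stopifnot(all(c("cell_id", "x_um", "y_um") %in% names(cells)))
  n <- nrow(cells)
  x <- cells$x_um; y <- cells$y_um
  if (anyDuplicated(cbind(x, y))) {
    warnf("build_spatial_graph: duplicate coordinates jittered by <= 1e-6 um")
    dup <- duplicated(cbind(x, y))
    x[dup] <- x[dup] + stats::runif(sum(dup), -1e-6, 1e-6)
    y[dup] <- y[dup] + stats::runif(sum(dup), -1e-6, 1e-6)
  }
  edges <- if (n <= 2) {
    if (n == 2) data.frame(i = 1L, j = 2L) else data.frame(i = integer(), j = integer())
  } else {
    tri <- tryCatch(
      suppressMessages(deldir::deldir(x, y, suppressMsge = TRUE)),
      error = function(e) NULL)
    if (is.null(tri)) {                       # degenerate (e.g. collinear): complete graph
      idx <- t(utils::combn(n, 2))
      data.frame(i = idx[, 1], j = idx[, 2])
    } else {
      data.frame(i = pmin(tri$delsgs$ind1, tri$delsgs$ind2),
                 j = pmax(tri$delsgs$ind1, tri$delsgs$ind2))
    }
  }
  edges$length_um <- sqrt((x[edges$i] - x[edges$j])^2 + (y[edges$i] - y[edges$j])^2)
  # empirical order-statistic quantile: with few edges the threshold is an
  # observed length, so small graphs (e.g. a triangle) are not over-pruned
  thr <- if (nrow(edges))
    stats::quantile(edges$length_um, prune_percentile / 100, type = 1,
                    names = FALSE) else Inf
  edges <- edges[edges$length_um <= thr, , drop = FALSE]
  rownames(edges) <- NULL
  adj <- vector("list", n)
  for (k in seq_len(n)) adj[[k]] <- integer()
  if (nrow(edges)) {
    adj <- split(c(edges$j, edges$i), factor(c(edges$i, edges$j), levels = seq_len(n)))
    adj <- lapply(adj, as.integer)
  }
  structure(list(cell_id = as.character(cells$cell_id), x = x, y = y,
                 edges = edges, prune_threshold_um = thr, adj = adj,
                 roi_id = roi_id %||% (cells$roi_id[1] %||% NA_character_)),
            class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("<spatial_graph> %s: %d cells, %d edges (pruned at %.1f um)\n",
              x$roi_id, length(x$cell_id), nrow(x$edges), x$prune_threshold_um))
  invisible(x)
}

#' l-step neighbourhood of a cell
#'
#' All cells within `l` edges of the target cell on the pruned spatial
#' graph, inclusive of the target (a breadth-first expansion).
#'
#' @param graph a `spatial_graph`.
#' @param cell a `cell_id` present in the graph, or a 1-based vertex
#'   index.
#' @param l number of steps (default 3).
#' @return Character vector of member `cell_id`s.
#' @export
l_step_neighbourhood <- function(graph, cell, l = 3) {
  v <- if (is.character(cell)) match(cell, graph$cell_id) else as.integer(cell)
  if (is.na(v) || v < 1 || v > length(graph$cell_id))
    stopf("cell not in graph")
  graph$cell_id[l_step_indices(graph$adj, v, l)]
}

# BFS returning 1-based vertex indices within l steps (target included).
l_step_indices <- function(adj, v, l) {
  seen <- v
  frontier <- v
  for (step in seq_len(l)) {
    if (!length(frontier)) break
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  sort(seen)
}
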