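#' Per-cell Delaunay spatial measurements
#'
#' Triangulates nuclear centroids and derives, for every cell, neighbourhood
#' statistics over the incident Delaunay edges and triangles, plus
#' graph-cluster measurements: edges longer than `cluster_threshold_um` are
#' pruned and the connected components of the remaining Delaunay graph define
#' clusters (size and distance from the cell to its cluster centroid).
#'
#' Degenerate inputs (fewer than 3 points, or all collinear) yield `NA`
#' sentinel values for all nine columns, with a logged message.
#'
#' @param centroids A data frame (or matrix) whose first two columns are x/y
#'   centroid coordinates in micrometres.
#' @param cluster_threshold_um Maximum edge length retained when forming
#'   Delaunay clusters. Default 50.
#' @return A tibble with one row per input cell and the nine Delaunay schema
#'   columns.
#' @export
#' @examples
#' delaunay_features(data.frame(x = c(0, 3, 0), y = c(0, 0, 4)))
delaunay_features <- function(centroids, cluster_threshold_um = 50) {
  xy <- as.matrix(centroids[, 1:2])
  storage.mode(xy) <- "double"
  n <- nrow(xy)
  out <- matrix(NA_real_, n, length(rp_delaunay_names))
  colnames(out) <- rp_delaunay_names
  tmat <- if (n >= 3) {
    tryCatch({
      tm <- interp::triangles(interp::tri.mesh(xy[, 1], xy[, 2]))
      tm[, c("node1", "node2", "node3"), drop = FALSE]
    }, error = function(e) NULL)
  }
  if (is.null(tmat) || nrow(tmat) == 0) {
    rp_log("Delaunay triangulation degenerate (n = ", n, "); sentinel values used")
    return(tibble::as_tibble(out))
  }
  # triangle areas (shoelace)
  ax <- xy[tmat[, 1], 1]; ay <- xy[tmat[, 1], 2]
  bx <- xy[tmat[, 2], 1]; by <- xy[tmat[, 2], 2]
  cx <- xy[tmat[, 3], 1]; cy <- xy[tmat[, 3], 2]
  area <- abs((bx - ax) * (cy - ay) - (cx - ax) * (by - ay)) / 2
  # unique edges with lengths
  e <- rbind(tmat[, c(1, 2)], tmat[, c(2, 3)], tmat[, c(1, 3)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  elen <- sqrt(rowSums((xy[e[, 1], , drop = FALSE] - xy[e[, 2], , drop = FALSE])^2))
  # per-cell edge statistics
  cell_of <- c(e[, 1], e[, 2])
  len_of <- c(elen, elen)
  sp <- split(len_of, cell_of)
  ids <- as.integer(names(sp))
  out[ids, "Delaunay: Num neighbors"] <- lengths(sp)
  out[ids, "Delaunay: Mean distance"] <- vapply(sp, mean, numeric(1))
  out[ids, "Delaunay: Median distance"] <- vapply(sp, median, numeric(1))
  out[ids, "Delaunay: Min distance"] <- vapply(sp, min, numeric(1))
  out[ids, "Delaunay: Max distance"] <- vapply(sp, max, numeric(1))
  # per-cell triangle statistics
  tcell <- c(tmat[, 1], tmat[, 2], tmat[, 3])
  ta <- rep(area, 3)
  spa <- split(ta, tcell)
  ids2 <- as.integer(names(spa))
  out[ids2, "Delaunay: Mean triangle area"] <- vapply(spa, mean, numeric(1))
  out[ids2, "Delaunay: Max triangle area"] <- vapply(spa, max, numeric(1))
  # clusters on the pruned Delaunay graph
  keep <- elen <= cluster_threshold_um
  g <- igraph::graph_from_edgelist(e[keep, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  out[, "Delaunay: Cluster size"] <- comp$csize[comp$membership]
  ccx <- tapply(xy[, 1], comp$membership, mean)
  ccy <- tapply(xy[, 2], comp$membership, mean)
  out[, "Delaunay: Distance to cluster centroid"] <-
    sqrt((xy[, 1] - ccx[comp$membership])^2 + (xy[, 2] - ccy[comp$membership])^2)
  tibble::as_tibble(out)
}
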