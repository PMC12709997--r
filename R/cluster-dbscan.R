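#' Density-based spatial clustering (DBSCAN) on a 2-D point set
#'
#' Classic DBSCAN: a point with at least `min_samples` neighbours (itself
#' included) within `eps` is a core point; clusters are the connected
#' components of core points under the `eps` relation, plus border points
#' attached to a neighbouring core point. Points in no cluster are noise
#' (label 0). Border points with several core neighbours are attached to
#' the lowest-indexed one, making the labelling deterministic.
#'
#' @param xy Numeric matrix or data frame with two columns (x, y).
#' @param eps Neighbourhood radius.
#' @param min_samples Minimum neighbourhood size (self included) for a core
#'   point.
#' @return Integer vector of cluster labels (0 = noise), numbered 1, 2, ...
#'   in order of first appearance.
#' @export
dbscan_points <- function(xy, eps = 5, min_samples = 10) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n == 0L) return(integer(0))
  adj <- .radius_neighbours(xy, eps)
  core <- lengths(adj) >= min_samples
  labels <- integer(n)
  if (any(core)) {
    edges <- purrr::map(which(core), function(i) {
      js <- adj[[i]]
      js <- js[core[js] & js > i]
      if (length(js)) rbind(i, js) else NULL
    })
    edges <- do.call(cbind, edges)
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (!is.null(edges)) g <- igraph::add_edges(g, as.vector(edges))
    comp <- igraph::components(g)$membership
    labels[core] <- comp[core]
    # border points: lowest-indexed core neighbour decides
    for (i in which(!core)) {
      cores_near <- adj[[i]][core[adj[[i]]]]
      if (length(cores_near)) labels[i] <- labels[min(cores_near)]
    }
  }
  .renumber_labels(labels)
}

# renumber positive labels 1..k in order of first appearance, keep 0 = noise
.renumber_labels <- function(labels) {
  pos <- labels > 0L
  if (!any(pos)) return(labels)
  first <- unique(labels[pos])
  labels[pos] <- match(labels[pos], first)
  labels
}
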