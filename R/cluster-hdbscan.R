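#' Hierarchical density-based clustering (HDBSCAN) on a 2-D point set
#'
#' Implements the HDBSCAN* pipeline: core distances (distance to the
#' `min_samples`-th nearest neighbour, self included), the mutual
#' reachability graph, its minimum spanning tree (Prim, linear memory),
#' the single-linkage hierarchy, condensation with `min_cluster_size`, and
#' excess-of-mass cluster selection. Points not in any selected cluster are
#' noise (label 0). The root of the condensed tree is never selected
#' (no single-cluster solutions), matching common practice.
#'
#' @param xy Numeric matrix or data frame with two columns (x, y).
#' @param min_cluster_size Smallest cluster size retained in the condensed
#'   tree.
#' @param min_samples Core-distance smoothing; defaults to
#'   `min_cluster_size`.
#' @return Integer vector of cluster labels (0 = noise).
#' @export
hdbscan_points <- function(xy, min_cluster_size = 10,
                           min_samples = min_cluster_size) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n == 0L) return(integer(0))
  if (n < 2L * min_cluster_size) {
    # no split into two minimum-size clusters is possible and the root is
    # not selectable: everything is noise
    return(integer(n))
  }
  core <- .kth_nn_dist(xy, min_samples)
  mst <- .mutual_reachability_mst(xy, core)
  tree <- .single_linkage_tree(mst, n)
  cond <- .condense_tree(tree, n, min_cluster_size)
  chosen <- .excess_of_mass(cond)
  labels <- integer(n)
  for (k in seq_along(chosen)) {
    labels[cond$points[[chosen[k]]]] <- k
  }
  .renumber_labels(labels)
}

# Prim's MST over the implicit mutual-reachability graph; O(n^2) time,
# O(n) memory. Returns a data.frame(from, to, w) of n-1 edges.
.mutual_reachability_mst <- function(xy, core) {
  n <- nrow(xy)
  in_tree <- logical(n)
  best_w <- rep(Inf, n)
  best_from <- integer(n)
  in_tree[1L] <- TRUE
  cur <- 1L
  from <- integer(n - 1L)
  to <- integer(n - 1L)
  w <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    d <- sqrt((xy[, 1] - xy[cur, 1])^2 + (xy[, 2] - xy[cur, 2])^2)
    mr <- pmax(d, core, core[cur])
    upd <- !in_tree & mr < best_w
    best_w[upd] <- mr[upd]
    best_from[upd] <- cur
    cand <- which(!in_tree)
    nxt <- cand[which.min(best_w[cand])]
    from[step] <- best_from[nxt]
    to[step] <- nxt
    w[step] <- best_w[nxt]
    in_tree[nxt] <- TRUE
    cur <- nxt
  }
  data.frame(from = from, to = to, w = w)
}

# Union-find single linkage over sorted MST edges. Internal nodes are
# numbered n+1 .. 2n-1; returns children and merge heights.
.single_linkage_tree <- function(mst, n) {
  o <- order(mst$w)
  parent <- seq_len(2L * n - 1L)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  node_of <- seq_len(n) # current tree node representing each set root
  left <- integer(n - 1L)
  right <- integer(n - 1L)
  height <- numeric(n - 1L)
  size <- c(rep(1L, n), integer(n - 1L))
  for (step in seq_len(n - 1L)) {
    e <- o[step]
    a <- find(mst$from[e])
    b <- find(mst$to[e])
    new_node <- n + step
    left[step] <- node_of[a]
    right[step] <- node_of[b]
    height[step] <- mst$w[e]
    size[new_node] <- size[node_of[a]] + size[node_of[b]]
    parent[a] <- b
    node_of[b] <- new_node
  }
  list(left = left, right = right, height = height, size = size, n = n)
}

.leaves_under <- function(tree, node) {
  n <- tree$n
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v <= n) {
      out <- c(out, v)
    } else {
      k <- v - n
      stack <- c(stack, tree$left[k], tree$right[k])
    }
  }
  out
}

# Condense the single-linkage tree: clusters persist while both children of
# a split have >= min_cluster_size leaves; smaller children "fall out" as
# individual points. Returns per-condensed-cluster birth lambda, stability,
# parent, and full point sets (the leaves under the cluster's birth node).
.condense_tree <- function(tree, n, min_cluster_size) {
  root <- 2L * n - 1L
  id <- 0L
  cl_parent <- integer(0)
  cl_birth <- numeric(0)
  cl_stab <- numeric(0)
  cl_points <- list()
  new_cluster <- function(parent, birth, node) {
    id <<- id + 1L
    cl_parent[id] <<- parent
    cl_birth[id] <<- birth
    cl_stab[id] <<- 0
    cl_points[[id]] <<- .leaves_under(tree, node)
    id
  }
  root_id <- new_cluster(0L, 0, root)
  stack <- list(list(node = root, cluster = root_id))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    node <- top$node
    cl <- top$cluster
    while (node > n) {
      k <- node - n
      lam <- if (tree$height[k] > 0) 1 / tree$height[k] else Inf
      l <- tree$left[k]
      r <- tree$right[k]
      sl <- tree$size[l]
      sr <- tree$size[r]
      if (sl >= min_cluster_size && sr >= min_cluster_size) {
        # true split: cluster cl ends here, its remaining mass leaves now
        cl_stab[cl] <- cl_stab[cl] + (sl + sr) * (lam - cl_birth[cl])
        cl_l <- new_cluster(cl, lam, l)
        cl_r <- new_cluster(cl, lam, r)
        stack[[length(stack) + 1L]] <- list(node = l, cluster = cl_l)
        node <- r
        cl <- cl_r
      } else if (sl < min_cluster_size && sr < min_cluster_size) {
        # cluster dissolves: all remaining points fall out
        cl_stab[cl] <- cl_stab[cl] + (sl + sr) * (lam - cl_birth[cl])
        node <- 0L
        break
      } else {
        small <- if (sl < min_cluster_size) l else r
        big <- if (sl < min_cluster_size) r else l
        cl_stab[cl] <- cl_stab[cl] + tree$size[small] * (lam - cl_birth[cl])
        node <- big
      }
    }
    if (node != 0L && node <= n) {
      # singleton leaf remaining in cl: it left at the lambda of the edge
      # that isolated it, already accounted where its sibling split; nothing
      # further to add (size-1 leaves reached directly carry no extra mass)
      next
    }
  }
  list(
    parent = cl_parent[seq_len(id)], birth = cl_birth[seq_len(id)],
    stability = cl_stab[seq_len(id)], points = cl_points[seq_len(id)]
  )
}

# Excess-of-mass selection over the condensed tree; root excluded.
.excess_of_mass <- function(cond) {
  m <- length(cond$parent)
  if (m <= 1L) return(integer(0))
  children <- split(seq_len(m), factor(cond$parent, levels = 0:m))
  subtree_val <- numeric(m)
  selected <- logical(m)
  # children always have larger ids than parents: process in reverse order
  for (i in rev(seq_len(m))) {
    kids <- children[[as.character(i)]]
    if (is.null(kids) || !length(kids)) {
      subtree_val[i] <- cond$stability[i]
      selected[i] <- TRUE
    } else {
      kid_sum <- sum(subtree_val[kids])
      if (cond$stability[i] >= kid_sum && cond$parent[i] != 0L) {
        subtree_val[i] <- cond$stability[i]
        selected[i] <- TRUE
        # deselect all descendants
        desc <- kids
        while (length(desc)) {
          selected[desc] <- FALSE
          desc <- unlist(children[as.character(desc)], use.names = FALSE)
        }
      } else {
        subtree_val[i] <- kid_sum
      }
    }
  }
  selected[1L] <- FALSE # root
  which(selected)
}
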