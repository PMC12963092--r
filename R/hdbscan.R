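# Hierarchical density-based clustering of 2-D point positions, in the
# HDBSCAN family: mutual-reachability distances, a single-linkage
# hierarchy over them, condensation by minimum cluster size, and
# excess-of-mass cluster extraction with an explicit noise label. The
# cluster count is data-driven, which is what the detector needs — the
# number of fragments in view is unknown a priori.
#
# Conventions (documented, deliberate):
#   * core distance of a point = distance to its min_samples-th
#     nearest neighbour counting the point itself;
#   * the hierarchy root is selectable, so a single coherent blob
#     yields one cluster rather than all-noise;
#   * fewer than min_cluster_size points in total -> all noise.

#' Cluster 2-D positions by hierarchical density
#'
#' Clustering depends only on the point positions (Euclidean metric),
#' never on velocities, and is deterministic for a fixed input order.
#'
#' @param points K x 2 numeric matrix of (x, y) positions.
#' @param config a [cluster_config()].
#' @return Integer vector of labels, one per point: clusters are
#'   numbered 0, 1, ... in order of first appearance and noise is -1.
#' @export
cluster_positions <- function(points, config = cluster_config()) {
  points <- as.matrix(points)
  if (nrow(points) == 0) return(integer(0))
  if (ncol(points) != 2 || !is.numeric(points)) {
    ft_input_error("points must be a K x 2 numeric matrix")
  }
  .hdbscan_labels(points, config$min_cluster_size, config$min_samples)
}

#' Count clusters in a label vector
#'
#' @param labels labels from [cluster_positions()] (-1 = noise).
#' @return Number of distinct non-noise labels.
#' @export
cluster_count <- function(labels) {
  length(unique(labels[labels >= 0]))
}

.hdbscan_labels <- function(xy, min_cluster_size, min_samples) {
  n <- nrow(xy)
  if (n < min_cluster_size || min_samples > n) {
    return(rep(-1L, n))
  }
  d <- as.matrix(dist(xy))
  # core distance: min_samples-th nearest neighbour, self included
  core <- apply(d, 1, function(r) sort(r, partial = min_samples)[min_samples])
  mreach <- pmax(d, outer(core, core, pmax))
  hc <- hclust(stats::as.dist(mreach), method = "single")
  tree <- .condense_tree(hc, n, min_cluster_size)
  chosen <- .excess_of_mass(tree)
  .assign_labels(tree, chosen, n)
}

# Walk the single-linkage dendrogram top-down, building the condensed
# cluster tree: a true split needs both sides >= mcs; smaller sides
# fall out of the current cluster at the split's lambda = 1/height.
# Stability(C) = sum over points p of (lambda_leave(p) - lambda_birth).
.condense_tree <- function(hc, n, mcs) {
  merge <- hc$merge; height <- hc$height
  n_int <- nrow(merge)
  # subtree sizes and point lists per internal node
  sizes <- integer(n_int)
  for (i in seq_len(n_int)) {
    a <- merge[i, 1]; b <- merge[i, 2]
    sizes[i] <- (if (a < 0) 1L else sizes[a]) + (if (b < 0) 1L else sizes[b])
  }
  node_size <- function(v) if (v < 0) 1L else sizes[v]
  lam <- 1 / pmax(height, .Machine$double.xmin)

  env <- new.env(parent = emptyenv())
  env$parent <- integer(0)      # condensed-cluster parent ids (0 = none)
  env$birth <- numeric(0)
  env$stability <- numeric(0)
  env$fall_cluster <- integer(n)  # per point: cluster it fell out of

  new_cluster <- function(parent, birth) {
    id <- length(env$parent) + 1L
    env$parent[id] <- parent
    env$birth[id] <- birth
    env$stability[id] <- 0
    id
  }

  leaves_of <- function(v) {
    # iterative subtree leaf collection
    out <- integer(0); stack <- v
    while (length(stack)) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (u < 0) out <- c(out, -u)
      else stack <- c(stack, merge[u, 1], merge[u, 2])
    }
    out
  }

  root <- new_cluster(0L, 0)
  # explicit stack of (node, cluster) to avoid deep recursion
  stack <- list(list(node = n_int, cluster = root))
  while (length(stack)) {
    fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    v <- fr$node; cl <- fr$cluster
    a <- merge[v, 1]; b <- merge[v, 2]
    sa <- node_size(a); sb <- node_size(b)
    l <- lam[v]
    if (sa >= mcs && sb >= mcs) {
      # true split: every current point leaves cl here
      env$stability[cl] <- env$stability[cl] + (l - env$birth[cl]) * (sa + sb)
      for (side in c(a, b)) {
        child <- new_cluster(cl, l)
        if (side < 0) {
          # cannot happen (size >= mcs >= 2) but keep the walk total
          env$fall_cluster[-side] <- child
        } else {
          stack[[length(stack) + 1L]] <- list(node = side, cluster = child)
        }
      }
    } else if (sa >= mcs || sb >= mcs) {
      big <- if (sa >= mcs) a else b
      small <- if (sa >= mcs) b else a
      ns <- node_size(small)
      env$stability[cl] <- env$stability[cl] + (l - env$birth[cl]) * ns
      env$fall_cluster[leaves_of(small)] <- cl
      if (big < 0) {
        env$fall_cluster[-big] <- cl   # unreachable for mcs >= 2
      } else {
        stack[[length(stack) + 1L]] <- list(node = big, cluster = cl)
      }
    } else {
      # both sides below mcs: the cluster dies here
      env$stability[cl] <- env$stability[cl] + (l - env$birth[cl]) * (sa + sb)
      env$fall_cluster[leaves_of(v)] <- cl
    }
  }
  list(parent = env$parent, stability = env$stability,
       fall_cluster = env$fall_cluster)
}

# Excess-of-mass selection: a cluster is kept when its own stability
# exceeds the summed stability of its selected descendants; the root
# is allowed to win (single coherent blob -> one cluster).
.excess_of_mass <- function(tree) {
  m <- length(tree$parent)
  children <- vector("list", m)
  for (i in seq_len(m)) {
    p <- tree$parent[i]
    if (p > 0) children[[p]] <- c(children[[p]], i)
  }
  subtree_stab <- numeric(m)
  sel <- logical(m)
  for (i in rev(seq_len(m))) {      # children are created after parents
    ch <- children[[i]]
    if (is.null(ch)) {
      subtree_stab[i] <- tree$stability[i]
      sel[i] <- TRUE
    } else {
      s_ch <- sum(subtree_stab[ch])
      if (tree$stability[i] >= s_ch) {
        subtree_stab[i] <- tree$stability[i]
        sel[i] <- TRUE
      } else {
        subtree_stab[i] <- s_ch
        sel[i] <- FALSE
      }
    }
  }
  # drop selections shadowed by a selected ancestor
  chosen <- logical(m)
  for (i in seq_len(m)) {
    if (!sel[i]) next
    p <- tree$parent[i]
    shadowed <- FALSE
    while (p > 0) {
      if (sel[p]) { shadowed <- TRUE; break }
      p <- tree$parent[p]
    }
    chosen[i] <- !shadowed
  }
  chosen
}

.assign_labels <- function(tree, chosen, n) {
  labels <- rep(-1L, n)
  # map each point's fall-out cluster up to the nearest chosen ancestor
  cl_label <- rep(NA_integer_, length(tree$parent))
  next_label <- 0L
  for (p in seq_len(n)) {
    c0 <- tree$fall_cluster[p]
    cl <- c0
    while (cl > 0 && !chosen[cl]) cl <- tree$parent[cl]
    if (cl > 0) {
      if (is.na(cl_label[cl])) {
        cl_label[cl] <- next_label
        next_label <- next_label + 1L
      }
      labels[p] <- cl_label[cl]
    }
  }
  labels
}
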