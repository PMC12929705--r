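# Hierarchical density-based clustering (HDBSCAN) used by the gating stage.
#
# Pipeline: per-point core distances (k-NN density proxy), minimum spanning
# tree of the mutual-reachability graph, single-linkage merge tree, condensed
# cluster tree at `min_cluster_size`, and excess-of-mass cluster selection.
# The compiled kernels in src/ do the O(n^2) distance work; the tree logic
# lives here. Labels follow the usual convention: positive integers for
# clusters, -1 for noise.

#' Density-based hierarchical cluster labels
#'
#' @param x numeric matrix (observations x dimensions), already on a scale
#'   where Euclidean distance is meaningful (the gating stage passes
#'   log10(x+1)-transformed channels).
#' @param min_cluster_size smallest group treated as a cluster.
#' @param min_samples neighbourhood size of the core-distance estimate;
#'   larger values give smoother density and more points declared noise.
#' @return integer vector of labels, one per row of `x`; -1 marks noise.
#' @export
hdbscan_labels <- function(x, min_cluster_size, min_samples = 10L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (min_cluster_size < 2) stopf("min_cluster_size must be >= 2")
  if (n <= min_cluster_size) return(rep(1L, n))
  k <- max(1L, as.integer(min_samples) - 1L)
  core <- .core_distances(x, k)
  edges <- .mreach_mst(x, core)
  ord <- order(edges[, 3])
  edges <- edges[ord, , drop = FALSE]

  ## single-linkage merge tree --------------------------------------------
  # leaves 1..n; internal nodes n+1..2n-1 in merge order
  parent_uf <- seq_len(n)         # union-find over points
  find <- function(i) {
    while (parent_uf[i] != i) {
      parent_uf[i] <<- parent_uf[parent_uf[i]]
      i <- parent_uf[i]
    }
    i
  }
  comp_node <- seq_len(n)         # tree node currently representing each root
  n_nodes <- 2L * n - 1L
  left <- integer(n_nodes); right <- integer(n_nodes)
  height <- numeric(n_nodes); count <- integer(n_nodes)
  count[seq_len(n)] <- 1L
  for (e in seq_len(n - 1L)) {
    ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
    node <- n + e
    left[node] <- comp_node[ra]; right[node] <- comp_node[rb]
    height[node] <- edges[e, 3]
    count[node] <- count[left[node]] + count[right[node]]
    parent_uf[ra] <- rb
    comp_node[rb] <- node
  }
  root <- n_nodes

  # duplicates give zero merge heights; cap lambda at a large finite value
  pos <- height[(n + 1L):n_nodes]
  min_pos <- if (any(pos > 0)) min(pos[pos > 0]) else 1
  lam_of <- function(h) if (h <= 0) 2 / min_pos else 1 / h

  leaves_under <- function(node) {
    out <- integer(0); stack <- node
    while (length(stack)) {
      nd <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (nd <= n) out <- c(out, nd)
      else stack <- c(stack, left[nd], right[nd])
    }
    out
  }

  ## condensed tree --------------------------------------------------------
  max_clusters <- n
  cl_parent <- integer(0); cl_birth <- numeric(0)
  cl_stability <- numeric(0); cl_children <- list()
  new_cluster <- function(parent, birth) {
    cl_parent[length(cl_parent) + 1L] <<- parent
    cl_birth[length(cl_birth) + 1L] <<- birth
    cl_stability[length(cl_stability) + 1L] <<- 0
    cl_children[[length(cl_children) + 1L]] <<- integer(0)
    id <- length(cl_parent)
    if (parent > 0) cl_children[[parent]] <<- c(cl_children[[parent]], id)
    id
  }
  point_cluster <- integer(n)

  root_cl <- new_cluster(0L, 0)
  stack_nodes <- root; stack_cl <- root_cl
  while (length(stack_nodes)) {
    node <- stack_nodes[length(stack_nodes)]
    cl <- stack_cl[length(stack_cl)]
    stack_nodes <- stack_nodes[-length(stack_nodes)]
    stack_cl <- stack_cl[-length(stack_cl)]
    # walk down through merges until this cluster splits or bottoms out
    repeat {
      if (node <= n) { # singleton remainder of the cluster
        point_cluster[node] <- cl
        cl_stability[cl] <- cl_stability[cl] + (lam_of(0) - cl_birth[cl])
        break
      }
      lam <- lam_of(height[node])
      l <- left[node]; r <- right[node]
      big_l <- count[l] >= min_cluster_size
      big_r <- count[r] >= min_cluster_size
      if (big_l && big_r) { # true split: two child clusters are born
        cl_stability[cl] <- cl_stability[cl] +
          (lam - cl_birth[cl]) * (count[l] + count[r])
        for (child in c(l, r)) {
          ccl <- new_cluster(cl, lam)
          stack_nodes <- c(stack_nodes, child)
          stack_cl <- c(stack_cl, ccl)
        }
        break
      }
      if (!big_l && !big_r) { # cluster bottoms out; all points leave here
        pts <- leaves_under(node)
        point_cluster[pts] <- cl
        cl_stability[cl] <- cl_stability[cl] +
          length(pts) * (lam - cl_birth[cl])
        break
      }
      small <- if (big_l) r else l
      pts <- leaves_under(small)
      point_cluster[pts] <- cl
      cl_stability[cl] <- cl_stability[cl] +
        length(pts) * (lam - cl_birth[cl])
      node <- if (big_l) l else r
    }
  }

  ## excess-of-mass selection ----------------------------------------------
  n_cl <- length(cl_parent)
  selected <- rep(FALSE, n_cl)
  subtree_stab <- cl_stability
  for (cl in rev(seq_len(n_cl))) {
    kids <- cl_children[[cl]]
    if (length(kids) == 0) {
      selected[cl] <- TRUE
      next
    }
    child_sum <- sum(subtree_stab[kids])
    if (cl_stability[cl] > child_sum) {
      selected[cl] <- TRUE
      # deselect descendants
      stack <- kids
      while (length(stack)) {
        c2 <- stack[length(stack)]; stack <- stack[-length(stack)]
        selected[c2] <- FALSE
        stack <- c(stack, cl_children[[c2]])
      }
    } else {
      subtree_stab[cl] <- child_sum
    }
  }

  ## labelling --------------------------------------------------------------
  sel_ids <- which(selected)
  label_of_cluster <- integer(n_cl)
  # nearest selected ancestor (including the cluster itself); 0 = none
  for (cl in seq_len(n_cl)) {
    cur <- cl
    while (cur > 0 && !selected[cur]) cur <- cl_parent[cur]
    label_of_cluster[cl] <- if (cur > 0) match(cur, sel_ids) else 0L
  }
  labels <- label_of_cluster[point_cluster]
  labels[labels == 0L] <- -1L
  labels
}
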