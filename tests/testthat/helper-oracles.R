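# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals: flood fill is breadth-first in
# plain R, max-min path strength comes from exhaustive simple-path
# enumeration (tiny grids) and from the maximum-spanning-tree bottleneck
# theorem via igraph (3x3x3 grids).

neighbour_offsets_r <- function(connectivity) {
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  l1 <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  keep <- switch(as.character(connectivity),
                 "6" = l1 == 1, "18" = l1 >= 1 & l1 <= 2, "26" = l1 >= 1)
  as.matrix(off[keep, ])
}

# Breadth-first flood-fill connected-component labelling.
r_label_components <- function(mask, connectivity) {
  d <- dim(mask)
  off <- neighbour_offsets_r(connectivity)
  lab <- array(0L, dim = d)
  current <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    current <- current + 1L
    queue <- start
    lab[start] <- current
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      vc <- arrayInd(v, d)
      for (k in seq_len(nrow(off))) {
        p <- vc + off[k, ]
        if (any(p < 1) || any(p > d)) next
        w <- p[1] + (p[2] - 1L) * d[1] + (p[3] - 1L) * d[1] * d[2]
        if (mask[w] && lab[w] == 0L) {
          lab[w] <- current
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

gaussian_affinity <- function(a, b, mu, sigma) {
  exp(-(((a + b) / 2 - mu)^2) / (2 * sigma^2))
}

# Adjacency list (linear indices) of in-region voxels.
region_adjacency <- function(region, connectivity) {
  d <- dim(region)
  off <- neighbour_offsets_r(connectivity)
  adj <- vector("list", prod(d))
  for (v in which(region)) {
    vc <- arrayInd(v, d)
    nb <- integer()
    for (k in seq_len(nrow(off))) {
      p <- vc + off[k, ]
      if (any(p < 1) || any(p > d)) next
      w <- p[1] + (p[2] - 1L) * d[1] + (p[3] - 1L) * d[1] * d[2]
      if (region[w]) nb <- c(nb, w)
    }
    adj[[v]] <- nb
  }
  adj
}

# Exhaustive enumeration of all simple paths from every seed, tracking the
# best (max over paths of min per-step affinity) strength per voxel.
# Feasible only for very small regions.
r_fuzzy_conn_enumerate <- function(img, region, seeds, mu, sigma, connectivity) {
  d <- dim(img)
  adj <- region_adjacency(region, connectivity)
  best <- array(0, dim = d)
  visited <- array(FALSE, dim = d)
  recurse <- function(v, strength) {
    if (strength > best[v]) best[v] <<- strength
    for (w in adj[[v]]) {
      if (visited[w]) next
      visited[w] <<- TRUE
      recurse(w, min(strength, gaussian_affinity(img[v], img[w], mu, sigma)))
      visited[w] <<- FALSE
    }
  }
  for (s in seeds) {
    visited[] <- FALSE
    visited[s] <- TRUE
    recurse(s, 1)
  }
  best[!region] <- 0
  best
}

# Max-min path strength via the maximum-spanning-tree bottleneck theorem:
# the strongest-bottleneck path between two nodes runs along the maximum
# spanning tree, so the strength is the minimum edge weight on the unique
# tree path. Multi-seed strength is the max over seeds.
r_fuzzy_conn_mst <- function(img, region, seeds, mu, sigma, connectivity) {
  d <- dim(img)
  idx <- which(region)
  node_of <- integer(prod(d))
  node_of[idx] <- seq_along(idx)
  adj <- region_adjacency(region, connectivity)
  edges <- list()
  w <- numeric()
  for (v in idx) {
    for (u in adj[[v]]) {
      if (u > v) {
        edges[[length(edges) + 1L]] <- c(node_of[v], node_of[u])
        w <- c(w, gaussian_affinity(img[v], img[u], mu, sigma))
      }
    }
  }
  best <- array(0, dim = d)
  best[seeds] <- 1
  if (length(edges) == 0) return(best)
  g <- igraph::make_graph(t(do.call(rbind, edges)), n = length(idx),
                          directed = FALSE)
  igraph::E(g)$aff <- w
  tree <- igraph::mst(g, weights = -w)
  for (s in seeds) {
    sn <- node_of[s]
    paths <- igraph::shortest_paths(tree, from = sn,
                                    to = seq_along(idx), output = "epath")
    for (j in seq_along(idx)) {
      v <- idx[j]
      if (v == s) next
      ep <- paths$epath[[j]]
      if (length(ep) == 0) next  # disconnected from this seed
      strength <- min(igraph::E(tree)$aff[ep])
      if (strength > best[v]) best[v] <- strength
    }
  }
  best[!region] <- 0
  best
}

random_mask_array <- function(d, p = 0.3) {
  array(stats::runif(prod(d)) < p, dim = d)
}

# Binary erosion with the 6-neighbourhood structuring element.
r_erode6 <- function(m) {
  d <- dim(m)
  out <- m
  shift <- function(arr, axis, by) {
    idx <- rep(list(quote(expr = )), 3)
    n <- d[axis]
    src <- pmin(pmax(seq_len(n) + by, 1), n)
    pad <- seq_len(n) + by < 1 | seq_len(n) + by > n
    idx[[axis]] <- src
    res <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
    idx2 <- rep(list(quote(expr = )), 3)
    idx2[[axis]] <- which(pad)
    if (any(pad)) res <- do.call(`[<-`, c(list(res), idx2, list(value = FALSE)))
    res
  }
  for (axis in 1:3) {
    out <- out & shift(m, axis, 1) & shift(m, axis, -1)
  }
  out
}
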