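#' Decompose an axon into arbors by spectral clustering
#'
#' The axonal nodes (optionally resampled for uniform spacing) are
#' clustered on an affinity of exponentiated negative pairwise
#' distances (normalised by their median); labels are then repaired to
#' connected subtrees: nodes on the tree path between two same-label
#' components are reassigned so that every arbor is internally
#' connected. Basal and apical dendrites are returned whole as
#' additional arbors.
#'
#' @param tree a [neuron_tree()].
#' @param k number of axonal arbors.
#' @param seed RNG seed.
#' @param spacing resampling spacing before clustering, um (default
#'   20; NULL skips resampling).
#' @return list of arbors; each has `node_ids` (of the resampled
#'   tree returned as `$tree`), `kind` ("axonal", "basal", "apical").
#' @export
decompose_arbors <- function(tree, k, seed = 1, spacing = 20) {
  if (!is.null(spacing)) tree <- resample_tree(tree, spacing)
  nd <- tree$nodes
  ax <- which(nd$structure == 2L)
  if (length(ax) < k) stop("k exceeds the number of axonal nodes")
  out <- list()
  for (s in c(basal = 3L, apical = 4L)) {
    idx <- which(nd$structure == s)
    if (length(idx)) {
      out[[length(out) + 1L]] <- list(
        node_ids = nd$id[idx],
        kind = c(`3` = "basal", `4` = "apical")[as.character(s)])
    }
  }
  xyz <- node_xyz(tree)[ax, , drop = FALSE]
  if (k == 1) {
    lab <- rep(1L, length(ax))
  } else {
    W <- local_scaled_affinity(xyz)
    lab <- spectral_embed_kmeans(W, k, seed)
    lab <- repair_connectivity(tree, nd$id[ax], lab)
  }
  for (g in sort(unique(lab))) {
    out[[length(out) + 1L]] <- list(node_ids = nd$id[ax][lab == g],
                                    kind = "axonal")
  }
  attr(out, "tree") <- tree
  out
}

#' reassign labels so each label set is connected within the tree;
#' nodes on a path between two same-label fragments adopt that label
#' @noRd
repair_connectivity <- function(tree, ids, lab) {
  nd <- tree$nodes
  idx <- match(nd$parent, nd$id)
  labs_all <- rep(NA_integer_, nrow(nd))
  labs_all[match(ids, nd$id)] <- lab
  ord <- topo_order(tree)
  # walk leaves->root; if a node and its grandparent side share a label
  # but the parent differs, relabel the parent (majority of the path)
  repeat {
    changed <- FALSE
    for (i in rev(ord)) {
      p <- idx[i]
      if (is.na(p) || is.na(labs_all[i]) || is.na(labs_all[p])) next
      if (labs_all[i] == labs_all[p]) next
      # does any ancestor carry the child label?
      a <- p
      hop <- 0L
      while (!is.na(a) && hop < 1000L) {
        if (!is.na(labs_all[a]) && labs_all[a] == labs_all[i]) break
        a <- idx[a]
        hop <- hop + 1L
      }
      if (!is.na(a) && !is.na(labs_all[a]) &&
          labs_all[a] == labs_all[i]) {
        # relabel the intermediate path to the child's label
        b <- p
        while (b != a) {
          if (!is.na(labs_all[b]) && labs_all[b] != labs_all[i]) {
            labs_all[b] <- labs_all[i]
            changed <- TRUE
          }
          b <- idx[b]
        }
      }
    }
    if (!changed) break
  }
  labs_all[match(ids, nd$id)]
}

#' distance affinity with per-point local scaling: the bandwidth of
#' each point is its distance to the `nn`-th nearest neighbour, so
#' dense tufts separate from the sparse wires connecting them
#' @noRd
local_scaled_affinity <- function(xyz, nn = 7) {
  d <- as.matrix(stats::dist(xyz))
  n <- nrow(d)
  nn <- min(nn, n - 1)
  sig <- apply(d, 1, function(r) sort(r)[nn + 1])
  sig <- pmax(sig, .Machine$double.eps)
  exp(-d^2 / (sig %o% sig))
}

#' Automatic arbor count by the eigengap heuristic
#'
#' Since arbors are densely packed subtrees, the spectrum is evaluated
#' on the high-density axonal nodes only (local density at least
#' `density_frac` of the maximum within `density_radius`), which
#' removes the sparse tract wires connecting arbors; the eigengap of
#' the locally scaled affinity of the remaining nodes gives k.
#'
#' @param tree a [neuron_tree()] with an axon.
#' @param k_range candidate range (default 1:4).
#' @param spacing resampling spacing, um.
#' @param density_radius local density sphere, um (default 50).
#' @param density_frac density cutoff as a fraction of the maximum
#'   (default 0.3).
#' @param sigma Gaussian affinity bandwidth, um (default 100: between
#'   the diameter of an arbor and the separation of distinct arbors,
#'   so one arbor looks like one block).
#' @return integer k.
#' @export
auto_arbor_k <- function(tree, k_range = 1:4, spacing = 20,
                         density_radius = 50, density_frac = 0.3,
                         sigma = 100) {
  tree <- resample_tree(tree, spacing)
  nd <- tree$nodes
  ax <- which(nd$structure == 2L)
  if (length(ax) < 3) return(1L)
  xyz <- node_xyz(tree)[ax, , drop = FALSE]
  d <- as.matrix(stats::dist(xyz))
  dens <- rowSums(d <= density_radius)
  keep <- dens >= density_frac * max(dens)
  if (sum(keep) < 3) return(1L)
  W <- exp(-(d[keep, keep, drop = FALSE]^2) / (2 * sigma^2))
  eg <- eigengap(W, k_max = max(k_range))
  min(max(eg$k_best, min(k_range)), max(k_range))
}

#' Dominant arbor count of a region by majority vote
#'
#' @param trees neurons of one region.
#' @param ... passed to [auto_arbor_k()].
#' @return integer k (ties resolved toward the smaller k).
#' @export
region_arbor_count <- function(trees, ...) {
  votes <- vapply(trees, auto_arbor_k, 1L, ...)
  tab <- table(votes)
  as.integer(names(tab)[which.max(tab)])  # ties: first = smaller k
}

#' Arbor morphometry
#'
#' Computes, for an arbor of a (resampled) tree: the branch count of
#' the arbor subtree, the volume of the PCA-rotated 3-D bounding box
#' (um^3), the maximal spatial density (largest number of arbor nodes
#' within `density_radius` of any arbor node), the Euclidean distance
#' from the maximal-density node to the soma, and the proximal/distal
#' type (distal when that distance exceeds `distal_threshold`).
#'
#' @param arbor one element of [decompose_arbors()] output.
#' @param tree the decomposed tree (attribute `tree` of the same
#'   output).
#' @param density_radius sphere radius for the density feature, um
#'   (default 20).
#' @param distal_threshold proximal/distal cut, um (default 750;
#'   strictly above is distal).
#' @return named list: n_branch, volume, max_density, dist2soma, type.
#' @export
arbor_features <- function(arbor, tree, density_radius = 20,
                           distal_threshold = 750) {
  nd <- tree$nodes
  rows <- match(arbor$node_ids, nd$id)
  xyz <- node_xyz(tree)[rows, , drop = FALSE]
  # branch count of the induced subtree: every tip ends a branch and
  # every internal branch point adds one
  inset <- nd$id %in% arbor$node_ids
  par_in <- inset & nd$parent %in% nd$id[inset]
  kids_in <- tabulate(match(nd$parent[par_in], nd$id), nbins = nrow(nd))
  tips_in <- sum(kids_in[rows] == 0)
  bifs_in <- sum(kids_in[rows] >= 2)
  n_branch <- tips_in + bifs_in
  cc <- sweep(xyz, 2, colMeans(xyz))
  vol <- 0
  if (nrow(xyz) >= 3) {
    sv <- svd(cc, nu = 0)
    rot <- cc %*% sv$v
    ext <- apply(rot, 2, function(c) diff(range(c)))
    vol <- prod(ext)
  }
  d <- as.matrix(stats::dist(xyz))
  dens <- rowSums(d <= density_radius)
  imax <- which.max(dens)
  root_xyz <- as.numeric(nd[nd$parent == -1L, c("x", "y", "z")])
  d2s <- sqrt(sum((xyz[imax, ] - root_xyz)^2))
  list(n_branch = n_branch, volume = vol,
       max_density = max(dens), dist2soma = d2s,
       type = if (d2s > distal_threshold) "distal" else "proximal")
}

#' Detect structural hubs across a neuron population
#'
#' Axons are resampled to `spacing` um, node density is the number of
#' population nodes within a `sphere_radius` um ball, and nodes whose
#' density exceeds `min_neighbors` are written into a voxel image at
#' `voxel_size` um which is dilated by a cubic kernel; the connected
#' components of the result are the hubs.
#'
#' @param trees list of [neuron_tree()] in a shared frame.
#' @param spacing resampling spacing, um (default 80).
#' @param sphere_radius density sphere, um (default 500).
#' @param min_neighbors density threshold (default 70; strictly above
#'   is a high-density node).
#' @param voxel_size um per voxel of the hub image (default 25).
#' @param dilate cubic dilation kernel size in voxels (default 10).
#' @return list: `labels` (3-D array, 0 = background), `origin` (um),
#'   `hubs` (per-hub voxel counts), `n_high` (high-density node
#'   count).
#' @export
detect_hubs <- function(trees, spacing = 80, sphere_radius = 500,
                        min_neighbors = 70, voxel_size = 25,
                        dilate = 10) {
  pts <- do.call(rbind, lapply(trees, function(tr) {
    rt <- resample_tree(tr, spacing)
    nd <- rt$nodes
    as.matrix(nd[nd$structure == 2L, c("x", "y", "z")])
  }))
  if (is.null(pts) || !nrow(pts)) {
    return(list(labels = array(0L, c(1, 1, 1)), origin = c(0, 0, 0),
                hubs = integer(0), n_high = 0L))
  }
  d <- as.matrix(stats::dist(pts))
  dens <- rowSums(d <= sphere_radius) - 1L
  high <- pts[dens > min_neighbors, , drop = FALSE]
  if (!nrow(high)) {
    return(list(labels = array(0L, c(1, 1, 1)), origin = c(0, 0, 0),
                hubs = integer(0), n_high = 0L))
  }
  origin <- apply(pts, 2, min) - dilate * voxel_size
  dims <- ceiling((apply(pts, 2, max) - origin) / voxel_size) +
    dilate + 1
  img <- array(FALSE, dims)
  v <- floor(sweep(high, 2, origin) / voxel_size) + 1
  img[cbind(v[, 1], v[, 2], v[, 3])] <- TRUE
  # cubic dilation, half-width on each side
  r <- floor(dilate / 2)
  dil <- img
  for (ax in 1:3) {
    acc <- dil
    for (o in seq_len(r)) {
      acc <- acc | shift_array(dil, ax, o) | shift_array(dil, ax, -o)
    }
    dil <- acc
  }
  lab <- label_components_3d(dil)
  list(labels = lab, origin = origin,
       hubs = tabulate(lab[lab > 0]),
       n_high = nrow(high))
}

#' connected components (26-connectivity) of a logical 3-D array
#' @noRd
label_components_3d <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  out <- array(0L, dim(mask))
  if (!nrow(w)) return(out)
  key <- function(m) (m[, 1] - 1) + dim(mask)[1] *
    ((m[, 2] - 1) + dim(mask)[2] * (m[, 3] - 1))
  k0 <- key(w)
  lookup <- stats::setNames(seq_len(nrow(w)), k0)
  edges <- NULL
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0 & offs %*% c(1, 3, 9) > 0, ,
               drop = FALSE]
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(w, 2, -offs[o, ])
    ok <- nb[, 1] >= 1 & nb[, 1] <= dim(mask)[1] &
      nb[, 2] >= 1 & nb[, 2] <= dim(mask)[2] &
      nb[, 3] >= 1 & nb[, 3] <= dim(mask)[3]
    kn <- key(nb[ok, , drop = FALSE])
    hit <- !is.na(lookup[as.character(kn)])
    if (any(hit)) {
      edges <- rbind(edges, cbind(which(ok)[hit],
                                  lookup[as.character(kn[hit])]))
    }
  }
  g <- igraph::graph_from_edgelist(
    rbind(edges, cbind(seq_len(nrow(w)), seq_len(nrow(w)))),
    directed = FALSE)
  comp <- igraph::components(g)$membership
  out[w] <- comp
  out
}

#' Primary axonal tract of a neuron
#'
#' Starts from the longest root-to-tip axonal path; while the terminal
#' branch of the current longest path is shorter than the
#' second-longest axonal branch of the tree, that terminal branch is
#' removed and the path re-evaluated. The surviving path, directed
#' soma to terminal, is the primary tract.
#'
#' @param tree a [neuron_tree()] with axonal nodes (structure 2).
#' @return list: `node_ids` (ordered soma -> terminal), `xyz` (path
#'   coordinates), `length` (um), `terminal` (tip coordinate).
#' @export
primary_tract <- function(tree) {
  nd <- tree$nodes
  if (!any(nd$structure == 2L)) stop("no axon in tree")
  sub <- subset_tree(tree, nd$id[nd$structure %in% c(1L, 2L)])
  brs <- branch_decompose(sub, structures = 2L)
  if (!length(brs)) stop("no axon in tree")
  lens <- vapply(brs, function(b) b$path_length, 1)
  l2 <- if (length(lens) >= 2) sort(lens, decreasing = TRUE)[2] else 0
  # branch graph: parent of branch b is the branch ending at b's start
  end_ids <- vapply(brs, function(b) b$end_id, 1)
  start_ids <- vapply(brs, function(b) b$start_id, 1)
  par_b <- match(start_ids, end_ids)           # NA for root branches
  cum <- numeric(length(brs))
  for (b in order(!is.na(par_b))) cum[b] <- lens[b]  # roots first
  # accumulate in topological order of the branch graph
  remaining <- rep(TRUE, length(brs))
  done <- is.na(par_b)
  cum[done] <- lens[done]
  while (!all(done)) {
    ready <- which(!done & done[ifelse(is.na(par_b), 1L, par_b)])
    if (!length(ready)) break
    cum[ready] <- lens[ready] + cum[par_b[ready]]
    done[ready] <- TRUE
  }
  n_child <- tabulate(par_b[!is.na(par_b)], nbins = length(brs))
  repeat {
    tips_b <- which(remaining & n_child == 0)
    best <- tips_b[which.max(cum[tips_b])]
    if (lens[best] < l2 && sum(remaining) > 1) {
      remaining[best] <- FALSE
      if (!is.na(par_b[best])) {
        n_child[par_b[best]] <- n_child[par_b[best]] - 1L
      }
    } else break
  }
  # materialise the node path root -> best tip
  chain <- best
  while (!is.na(par_b[chain[1]])) chain <- c(par_b[chain[1]], chain)
  ids <- brs[[chain[1]]]$node_ids
  for (b in chain[-1]) ids <- c(ids, brs[[b]]$node_ids[-1])
  rows <- match(ids, sub$nodes$id)
  xyz <- node_xyz(sub)[rows, , drop = FALSE]
  list(node_ids = ids, xyz = xyz, length = cum[best],
       terminal = xyz[nrow(xyz), ])
}

#' resample a polyline to n points uniformly spaced by arc length
#' @noRd
resample_polyline <- function(xyz, n = 200) {
  seg <- sqrt(rowSums((xyz[-1, , drop = FALSE] -
                       xyz[-nrow(xyz), , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  tgt <- seq(0, arc[length(arc)], length.out = n)
  t(vapply(tgt, function(t) {
    k <- min(max(findInterval(t, arc), 1), nrow(xyz) - 1)
    f <- if (seg[k] > 0) (t - arc[k]) / seg[k] else 0
    xyz[k, ] + f * (xyz[k + 1, ] - xyz[k, ])
  }, numeric(3)))
}

#' Radius profile and pattern of a tract group
#'
#' Each tract is resampled to `n_points` arc-uniform points; at every
#' percentile the member points are projected onto their first two
#' principal components and the 75th percentile of the distances to
#' the centre is the group radius there. The pattern compares the mean
#' radius over the terminal tenth of the arc with the soma tenth:
#' ratios below `conv_ratio` are convergent, above `div_ratio`
#' divergent, otherwise parallel.
#'
#' @param tracts list of [primary_tract()] results (>= 3).
#' @param n_points resampling count (default 200).
#' @param radius_quantile percentile of centre distances (default
#'   0.75).
#' @param conv_ratio,div_ratio pattern thresholds (defaults 0.8,
#'   1.25).
#' @return list: `radii` (length `n_points`), `pattern`, `ratio`.
#' @export
tract_group_profile <- function(tracts, n_points = 200,
                                radius_quantile = 0.75,
                                conv_ratio = 0.8, div_ratio = 1.25) {
  if (length(tracts) < 3) stop("need at least 3 tracts")
  rs <- lapply(tracts, function(t) resample_polyline(t$xyz, n_points))
  radii <- vapply(seq_len(n_points), function(i) {
    pts <- t(vapply(rs, function(m) m[i, ], numeric(3)))
    cc <- sweep(pts, 2, colMeans(pts))
    sv <- svd(cc, nu = 0)
    p2 <- cc %*% sv$v[, 1:2, drop = FALSE]
    stats::quantile(sqrt(rowSums(p2^2)), radius_quantile)
  }, 1)
  tenth <- max(1, round(n_points / 10))
  r_soma <- mean(radii[seq_len(tenth)])
  r_term <- mean(radii[(n_points - tenth + 1):n_points])
  ratio <- if (r_soma > 0) r_term / r_soma else Inf
  pattern <- if (ratio < conv_ratio) "convergent"
  else if (ratio > div_ratio) "divergent" else "parallel"
  list(radii = radii, pattern = pattern, ratio = ratio)
}

#' K-means clustering of tract terminals
#'
#' @param tracts list of [primary_tract()] results.
#' @param k cluster count (<= number of tracts).
#' @param seed RNG seed.
#' @return list: `labels`, `profiles` (per-cluster
#'   [tract_group_profile()] where the cluster has >= 3 members).
#' @export
terminal_clusters <- function(tracts, k, seed = 1) {
  stopifnot(k <= length(tracts))
  term <- t(vapply(tracts, function(t) t$terminal, numeric(3)))
  set.seed(seed)
  cl <- stats::kmeans(term, centers = k, nstart = 10)$cluster
  profiles <- lapply(seq_len(k), function(g) {
    mem <- which(cl == g)
    if (length(mem) >= 3) tract_group_profile(tracts[mem]) else NULL
  })
  list(labels = cl, profiles = profiles)
}

#' Regional projection vector of an axon
#'
#' Accumulates axonal edge lengths into the atlas region of each
#' edge's midpoint; background (region 0) is excluded. Lengths are
#' reported in millimetres.
#'
#' @param tree a [neuron_tree()] in atlas space (um).
#' @param atlas a [make_toy_atlas()].
#' @return named numeric vector over atlas regions (mm).
#' @export
projection_vector <- function(tree, atlas) {
  nd <- tree$nodes
  idx <- match(nd$parent, nd$id)
  sel <- which(!is.na(idx) & nd$structure == 2L)
  regions <- atlas$region_table$region_id
  out <- stats::setNames(numeric(length(regions)), regions)
  if (!length(sel)) return(out)
  xyz <- node_xyz(tree)
  mid <- (xyz[sel, , drop = FALSE] + xyz[idx[sel], , drop = FALSE]) / 2
  len <- sqrt(rowSums((xyz[sel, , drop = FALSE] -
                       xyz[idx[sel], , drop = FALSE])^2))
  reg <- atlas_lookup(atlas, mid)
  for (r in regions) out[as.character(r)] <- sum(len[reg == r]) / 1000
  out
}

#' Agglomerative clustering of arbor features plus projections
#'
#' Combines z-scored arbor summary features (mean and sd of n_branch,
#' volume, max_density, dist2soma over a neuron's axonal arbors) with
#' the L1-normalised projection vector, and cuts an average-linkage
#' dendrogram at `k`.
#'
#' @param arbor_stats neurons x 8 matrix of arbor feature summaries.
#' @param projections neurons x regions projection matrix.
#' @param k cluster count.
#' @return integer labels.
#' @export
thalamic_style_clustering <- function(arbor_stats, projections, k) {
  z <- scale(arbor_stats)
  z[is.na(z)] <- 0
  p <- projections / pmax(rowSums(abs(projections)),
                          .Machine$double.eps)
  x <- cbind(z, p)
  hc <- stats::hclust(stats::dist(x), method = "average")
  stats::cutree(hc, k = k)
}
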