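#' Exclude somas in crowded neighbourhoods
#'
#' Somas with more than `max_neighbors` other somas within `radius`
#' micrometres are eliminated before local tracing (highly interweaved
#' neurons cannot be traced reliably). Exactly `max_neighbors`
#' neighbours is still acceptable.
#'
#' @param somas n x 3 matrix of soma positions (um).
#' @param radius neighbourhood radius, um (default 128).
#' @param max_neighbors maximum tolerated neighbour count (default 5).
#' @return logical vector: TRUE for somas kept.
#' @export
soma_neighborhood_filter <- function(somas, radius = 128,
                                     max_neighbors = 5) {
  stopifnot(radius > 0)
  somas <- as.matrix(somas)
  n <- nrow(somas)
  if (n == 0) return(logical(0))
  d <- as.matrix(stats::dist(somas))
  nb <- rowSums(d <= radius) - 1L
  nb <= max_neighbors
}

#' Consensus merge of two tracer outputs
#'
#' Nodes of the primary reconstruction that have no node of the
#' reference reconstruction within `tol` are pruned together with all
#' their descendants; the result stays connected from the root.
#'
#' @param primary,reference [neuron_tree()]s in the same space.
#' @param tol correspondence tolerance (same units as coordinates,
#'   default 5 voxels-worth).
#' @return pruned [neuron_tree()] (unchanged if the roots are farther
#'   apart than `tol`, with a warning).
#' @export
consensus_merge <- function(primary, reference, tol = 5) {
  p <- node_xyz(primary)
  r <- node_xyz(reference)
  proot <- p[primary$nodes$parent == -1L, ]
  rroot <- r[reference$nodes$parent == -1L, ]
  if (nrow(r) == 0 || sqrt(sum((proot - rroot)^2)) > tol) {
    if (nrow(r) > 0) warning("roots farther apart than tol; no merge")
  }
  if (nrow(r) == 0) {
    keep <- primary$nodes$parent == -1L
  } else {
    keep <- vapply(seq_len(nrow(p)), function(i) {
      min(sqrt(colSums((t(r) - p[i, ])^2))) <= tol
    }, TRUE)
  }
  subset_tree(primary, primary$nodes$id[keep])
}

#' direction vector of a branch: start -> end (remote)
#' @noRd
branch_dir <- function(tree, b) {
  xyz <- node_xyz(tree)
  i1 <- match(b$start_id, tree$nodes$id)
  i2 <- match(b$end_id, tree$nodes$id)
  xyz[i2, ] - xyz[i1, ]
}

#' angle between a parent branch and a child branch, in the convention
#' where 180 degrees means straight continuation: angle between
#' (parent end -> start) and (child start -> end)
#' @noRd
parent_child_angle <- function(tree, parent_b, child_b) {
  angle_deg(-branch_dir(tree, parent_b), branch_dir(tree, child_b))
}

#' mean node radius of a branch (excluding the shared start node)
#' @noRd
branch_mean_radius <- function(tree, b) {
  mean(tree$nodes$radius[match(b$node_ids[-1], tree$nodes$id)])
}

#' Prune branches with aberrant geometry
#'
#' Removes (with all descendants) every branch that turns back on its
#' parent branch — parent-child angle below `min_angle` degrees, where
#' 180 means straight continuation — or whose mean radius exceeds
#' `radius_ratio` times the parent branch's mean radius.
#'
#' @param tree a [neuron_tree()] with radii.
#' @param min_angle angle cutoff in degrees (default 80; strictly
#'   below is pruned).
#' @param radius_ratio radius inflation cutoff (default 1.5; strictly
#'   above is pruned).
#' @return pruned [neuron_tree()].
#' @export
prune_geometry <- function(tree, min_angle = 80, radius_ratio = 1.5) {
  brs <- branch_decompose(tree)
  if (!length(brs)) return(tree)
  bad_start <- integer(0)
  # index branches by their start node for parent lookup
  by_end <- stats::setNames(seq_along(brs),
                            vapply(brs, function(b) b$end_id, 1))
  for (b in brs) {
    pb_i <- by_end[as.character(b$start_id)]
    if (is.na(pb_i)) next  # root branch: no parent branch
    pb <- brs[[pb_i]]
    ang <- parent_child_angle(tree, pb, b)
    rr <- branch_mean_radius(tree, b) / branch_mean_radius(tree, pb)
    if ((!is.na(ang) && ang < min_angle) || rr > radius_ratio) {
      bad_start <- c(bad_start, b$node_ids[2])
    }
  }
  if (!length(bad_start)) return(tree)
  bad <- descendant_ids(tree, bad_start)
  subset_tree(tree, setdiff(tree$nodes$id, bad))
}

#' Prune crossover artefacts
#'
#' Crossover structures are multifurcations (more than two children)
#' and consecutive bifurcations closer than `cross_dist`. At each
#' crossover, child branches at a small angle to the parent branch
#' (below `small_angle`, 180 = straight) are removed; child branches
#' at a mediocre angle (between `small_angle` and `mid_angle`) are kept
#' only when some sibling branch forms a near-collinear pair with them
#' (child-child angle above `large_angle`), i.e. when they belong to a
#' through-path of a crossing fibre.
#'
#' @param tree a [neuron_tree()].
#' @param small_angle,mid_angle,large_angle angle bands in degrees
#'   (defaults 80, 100, 150).
#' @param cross_dist distance defining consecutive bifurcations
#'   (default 5).
#' @return pruned [neuron_tree()].
#' @export
prune_crossovers <- function(tree, small_angle = 80, mid_angle = 100,
                             large_angle = 150, cross_dist = 5) {
  nd <- tree$nodes
  nkid <- n_children_vec(tree)
  xyz <- node_xyz(tree)
  brs <- branch_decompose(tree)
  by_end <- stats::setNames(seq_along(brs),
                            vapply(brs, function(b) b$end_id, 1))
  multi <- nd$id[nkid > 2]
  bif <- nd$id[nkid == 2 & nd$parent != -1L]
  consec <- character(0)
  if (length(bif) > 1) {
    bxyz <- xyz[match(bif, nd$id), , drop = FALSE]
    dd <- as.matrix(stats::dist(bxyz))
    consec <- bif[apply(dd <= cross_dist & upper.tri(dd) |
                          t(dd <= cross_dist & upper.tri(dd)), 1, any)]
  }
  crossover <- union(multi, consec)
  if (!length(crossover)) return(tree)
  bad_start <- integer(0)
  for (cn in crossover) {
    pb_i <- by_end[as.character(cn)]
    if (is.na(pb_i)) next
    pb <- brs[[pb_i]]
    child_brs <- Filter(function(b) b$start_id == cn, brs)
    if (length(child_brs) < 2) next
    angs <- vapply(child_brs, function(b)
      parent_child_angle(tree, pb, b), 1)
    for (ci in seq_along(child_brs)) {
      a <- angs[ci]
      if (is.na(a)) next
      if (a < small_angle) {
        bad_start <- c(bad_start, child_brs[[ci]]$node_ids[2])
      } else if (a <= mid_angle) {
        pair <- FALSE
        for (cj in seq_along(child_brs)) {
          if (cj == ci) next
          cc <- angle_deg(branch_dir(tree, child_brs[[ci]]),
                          branch_dir(tree, child_brs[[cj]]))
          if (!is.na(cc) && cc > large_angle) pair <- TRUE
        }
        if (!pair) bad_start <- c(bad_start, child_brs[[ci]]$node_ids[2])
      }
    }
  }
  if (!length(bad_start)) return(tree)
  bad <- descendant_ids(tree, bad_start)
  subset_tree(tree, setdiff(tree$nodes$id, bad))
}

#' Prune branches belonging to foreign somas
#'
#' Putative foreign somas are clusters of large-radius nodes (radius
#' above `candidate_radius`) whose summed cross-section area exceeds
#' `area_thresh`; nodes within `soma_exclude` of the true soma are
#' never tested. For each foreign soma, every branch on the path
#' between it and the root is assigned to whichever soma it "points
#' at" more: the side with the lower length-weighted integral of
#' deviation angles (angle between the branch and the radial line to
#' the respective soma, accumulated over the branches in between).
#' The first path branch (walking from the root) whose integral
#' favours the foreign soma marks the cut; ties keep the side with
#' more nodes.
#'
#' @param tree a [neuron_tree()] with radii.
#' @param candidate_radius minimum node radius of a candidate, same
#'   units as radii (default 5).
#' @param area_thresh summed pi r^2 area threshold (default 500).
#' @param soma_exclude protection radius around the true soma
#'   (default 50).
#' @param cluster_dist distance within which candidate nodes pool
#'   their area (default 10).
#' @return pruned [neuron_tree()].
#' @export
prune_foreign_somas <- function(tree, candidate_radius = 5,
                                area_thresh = 500, soma_exclude = 50,
                                cluster_dist = 10) {
  nd <- tree$nodes
  xyz <- node_xyz(tree)
  root_row <- which(nd$parent == -1L)
  droot <- sqrt(rowSums(sweep(xyz, 2, xyz[root_row, ])^2))
  cand <- which(nd$radius > candidate_radius & droot > soma_exclude &
                  nd$parent != -1L)
  if (!length(cand)) return(tree)
  # pool areas of nearby candidates
  cl <- rep(0L, length(cand))
  ncl <- 0L
  for (i in seq_along(cand)) {
    if (cl[i] != 0L) next
    ncl <- ncl + 1L
    cl[i] <- ncl
    for (j in seq_along(cand)) {
      if (cl[j] == 0L &&
          sqrt(sum((xyz[cand[i], ] - xyz[cand[j], ])^2)) <= cluster_dist) {
        cl[j] <- ncl
      }
    }
  }
  areas <- tapply(pi * nd$radius[cand]^2, cl, sum)
  foreign <- as.integer(names(areas)[areas > area_thresh])
  if (!length(foreign)) return(tree)
  brs <- branch_decompose(tree)
  by_end <- stats::setNames(seq_along(brs),
                            vapply(brs, function(b) b$end_id, 1))
  bad <- integer(0)
  for (fc in foreign) {
    members <- cand[cl == fc]
    # representative: largest-radius node of the cluster
    fnode <- members[which.max(nd$radius[members])]
    fxyz <- xyz[fnode, ]
    # path of branches from root to the branch containing fnode
    path_ids <- integer(0)
    cur <- nd$id[fnode]
    repeat {
      bi <- NA
      for (k in seq_along(brs)) {
        if (cur %in% brs[[k]]$node_ids[-1]) { bi <- k; break }
      }
      if (is.na(bi)) break
      path_ids <- c(bi, path_ids)
      cur <- brs[[bi]]$start_id
      if (cur == nd$id[root_row]) break
    }
    if (!length(path_ids)) next
    dev_angle <- function(b, soma_xyz) {
      # angle between the branch direction and the radial line from
      # the soma to the branch end nearer that soma
      i1 <- match(b$start_id, nd$id); i2 <- match(b$end_id, nd$id)
      d1 <- sqrt(sum((xyz[i1, ] - soma_xyz)^2))
      d2 <- sqrt(sum((xyz[i2, ] - soma_xyz)^2))
      near <- if (d1 <= d2) i1 else i2
      v <- xyz[if (near == i1) i2 else i1, ] - xyz[near, ]
      radial <- xyz[near, ] - soma_xyz
      a <- angle_deg(v, radial)
      if (is.na(a)) 0 else a
    }
    lens <- vapply(brs[path_ids], function(b) b$path_length, 1)
    dev_cur <- vapply(brs[path_ids], dev_angle, 1,
                      soma_xyz = xyz[root_row, ])
    dev_for <- vapply(brs[path_ids], dev_angle, 1, soma_xyz = fxyz)
    np <- length(path_ids)
    cut_at <- NA_integer_
    for (k in seq_len(np)) {
      # integral toward current soma: branches 1..k (between branch k
      # and the root); toward foreign soma: branches k..np
      i_cur <- sum(dev_cur[1:k] * lens[1:k]) / sum(lens[1:k])
      i_for <- sum(dev_for[k:np] * lens[k:np]) / sum(lens[k:np])
      if (i_for < i_cur) { cut_at <- k; break }
    }
    if (is.na(cut_at)) next
    cut_branch <- brs[[path_ids[cut_at]]]
    cut_head <- cut_branch$node_ids[2]
    would_remove <- descendant_ids(tree, cut_head)
    if (length(would_remove) * 2 == nrow(nd)) {
      next  # exact tie in nodes: keep the larger (here equal) side
    }
    bad <- union(bad, would_remove)
  }
  if (!length(bad)) return(tree)
  subset_tree(tree, setdiff(nd$id, bad))
}

#' Prune circuitous (winding) branches
#'
#' A branch is removed (with descendants) when the tracked path is
#' more than `max_ratio` times longer than the straight-line distance.
#' By default the path from the soma to the branch end is tested
#' (`scope = "to_soma"`); `scope = "branch"` tests each branch's own
#' path against its chord.
#'
#' @param tree a [neuron_tree()].
#' @param max_ratio winding cutoff (default 3; strictly above prunes).
#' @param scope `"to_soma"` or `"branch"`.
#' @return pruned [neuron_tree()].
#' @export
prune_winding <- function(tree, max_ratio = 3,
                          scope = c("to_soma", "branch")) {
  scope <- match.arg(scope)
  brs <- branch_decompose(tree)
  if (!length(brs)) return(tree)
  nd <- tree$nodes
  xyz <- node_xyz(tree)
  root_row <- which(nd$parent == -1L)
  pd <- path_dist_to_root(tree)
  bad_start <- integer(0)
  for (b in brs) {
    erow <- match(b$end_id, nd$id)
    if (scope == "to_soma") {
      eu <- sqrt(sum((xyz[erow, ] - xyz[root_row, ])^2))
      ratio <- if (eu > 0) pd[erow] / eu else Inf
    } else {
      ratio <- if (b$euclidean_span > 0)
        b$path_length / b$euclidean_span else Inf
    }
    if (ratio > max_ratio) bad_start <- c(bad_start, b$node_ids[2])
  }
  if (!length(bad_start)) return(tree)
  bad <- descendant_ids(tree, bad_start)
  subset_tree(tree, setdiff(nd$id, bad))
}

#' Curate a raw local reconstruction
#'
#' Applies the pruning filters (geometry, crossover, foreign-soma,
#' winding — plus an optional consensus merge against a reference
#' reconstruction) as independent passes over the raw tree and
#' intersects the surviving node sets; the largest root-connected
#' component of the intersection is kept. Results with fewer than
#' `min_nodes` nodes are flagged for discarding.
#'
#' @param tree raw [neuron_tree()].
#' @param reference optional second-tracer [neuron_tree()] for
#'   [consensus_merge()].
#' @param min_nodes discard threshold (default 20: strictly fewer
#'   nodes is discarded).
#' @return list: `tree` (curated), `report` (per-filter removed node
#'   counts, final node count, `discard` flag).
#' @export
curate <- function(tree, reference = NULL, min_nodes = 20) {
  n0 <- nrow(tree$nodes)
  passes <- list(
    geometry = prune_geometry(tree),
    crossover = prune_crossovers(tree),
    foreign_soma = prune_foreign_somas(tree),
    winding = prune_winding(tree))
  if (!is.null(reference)) {
    passes$consensus <- consensus_merge(tree, reference)
  }
  keep <- Reduce(intersect, lapply(passes, function(t) t$nodes$id))
  out <- subset_tree(tree, keep)
  report <- list(
    removed = vapply(passes, function(t) n0 - nrow(t$nodes), 1),
    final_nodes = nrow(out$nodes),
    discard = nrow(out$nodes) < min_nodes)
  list(tree = out, report = report)
}
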