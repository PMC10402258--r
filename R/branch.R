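#' Decompose a skeleton into branches
#'
#' A branch is the node path between two consecutive critical points
#' (root, branch point, or tip); interior nodes have exactly one child.
#' Orders are assigned from the root outwards, root branches being
#' order 1, and a node with k > 2 children starts k branches (each one
#' order above its parent branch, i.e. a multifurcation behaves like
#' stacked bifurcations for ordering).
#'
#' @param tree a [neuron_tree()].
#' @param structures optional integer vector; only edges whose child
#'   node carries one of these SWC structure codes are decomposed
#'   (e.g. `2` for axon). The root is always a valid branch start.
#' @return list of branches; each has `node_ids` (path, first element is
#'   the parent critical point), `path_length`, `euclidean_span`,
#'   `order`, and `end_id`/`start_id` helpers.
#' @export
branch_decompose <- function(tree, structures = NULL) {
  nd <- tree$nodes
  if (!is.null(structures)) {
    keep <- nd$structure %in% structures | nd$parent == -1L
    tree2 <- subset_tree(tree, nd$id[keep])
    nd <- tree2$nodes
  } else tree2 <- tree
  if (nrow(nd) < 2) return(list())
  nkid <- n_children_vec(tree2)
  root <- tree_root_id(tree2)
  critical <- nd$id[nkid >= 2 | nkid == 0 | nd$parent == -1L]
  kids <- tree_children(tree2)
  xyz <- as.matrix(nd[, c("x", "y", "z")])
  rowof <- function(id) match(id, nd$id)
  out <- list()
  # stack of (start critical id, order)
  stack <- list(list(id = root, order = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    ch <- kids[[as.character(top$id)]]
    if (is.null(ch) || !length(ch)) next
    ch <- sort(ch)
    for (ci in seq_along(ch)) {
      path <- c(top$id, ch[ci])
      cur <- ch[ci]
      while (!(cur %in% critical)) {
        nxt <- kids[[as.character(cur)]]
        path <- c(path, nxt[1])
        cur <- nxt[1]
      }
      rows <- rowof(path)
      seg <- xyz[rows[-1], , drop = FALSE] -
        xyz[rows[-length(rows)], , drop = FALSE]
      plen <- sum(sqrt(rowSums(seg^2)))
      span <- sqrt(sum((xyz[rows[length(rows)], ] - xyz[rows[1], ])^2))
      # stacked-bifurcation convention: at a k-furcation the first two
      # children share the order, each further child sits one deeper
      ord <- top$order + max(0L, ci - 2L)
      out[[length(out) + 1L]] <- list(
        node_ids = path, start_id = path[1], end_id = cur,
        path_length = plen, euclidean_span = span, order = ord)
      stack[[length(stack) + 1L]] <- list(id = cur, order = ord + 1L)
    }
  }
  out
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) return(v)
  v / n
}

angle_deg <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  cc <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, cc))) * 180 / pi
}

#' number of tips in the subtree rooted at each node id
#' @noRd
tip_counts <- function(tree) {
  nd <- tree$nodes
  nkid <- n_children_vec(tree)
  idx <- match(nd$parent, nd$id)
  cnt <- as.numeric(nkid == 0)
  ord <- rev(topo_order(tree))
  for (i in ord) if (!is.na(idx[i])) cnt[idx[i]] <- cnt[idx[i]] + cnt[i]
  stats::setNames(cnt, nd$id)
}

#' Per-branch and per-bifurcation local morphometric features
#'
#' Computes, for every branch: path length (`br_length`), order
#' (`br_order`) and contraction (`br_contraction` = chord / path); and
#' for every bifurcation: Euclidean and path distance to the soma
#' (`bif_EucDist2soma`, `bif_PathDist2soma`), partition asymmetry
#' (`asymmetry`, |l - r| / (l + r - 2) over subtree tip counts, 0 for a
#' (1,1) split), local and remote bifurcation amplitude (`ampl_local`
#' between the directions to the immediate child nodes, `ampl_remote`
#' between the directions to the child-branch endpoints) and local and
#' remote tilt (`tilt_local`, `tilt_remote`: the smaller angle between
#' the incoming parent direction and the two child directions).
#' Angles are in degrees. Multifurcations contribute one entry per
#' consecutive child pair.
#'
#' @param tree a [neuron_tree()].
#' @return list with data.frames `branches` and `bifurcations`.
#' @export
local_branch_features <- function(tree) {
  brs <- branch_decompose(tree)
  branches <- data.frame(
    end_id = vapply(brs, function(b) b$end_id, 1),
    br_length = vapply(brs, function(b) b$path_length, 1),
    br_order = vapply(brs, function(b) b$order, 1),
    br_contraction = vapply(brs, function(b)
      if (b$path_length > 0) b$euclidean_span / b$path_length else 1, 1))
  nd <- tree$nodes
  nkid <- n_children_vec(tree)
  bif_ids <- nd$id[nkid >= 2]
  if (!length(bif_ids)) {
    return(list(branches = branches,
                bifurcations = data.frame(
                  bif_id = integer(), bif_EucDist2soma = numeric(),
                  bif_PathDist2soma = numeric(), asymmetry = numeric(),
                  ampl_local = numeric(), ampl_remote = numeric(),
                  tilt_local = numeric(), tilt_remote = numeric())))
  }
  kids <- tree_children(tree)
  xyz <- node_xyz(tree)
  rowof <- function(id) match(id, nd$id)
  pd <- path_dist_to_root(tree)
  root_xyz <- xyz[rowof(tree_root_id(tree)), ]
  tips <- tip_counts(tree)
  # remote endpoint of the branch starting with child c at node b
  branch_end <- stats::setNames(
    vapply(brs, function(b) b$end_id, 1),
    vapply(brs, function(b) paste(b$start_id, b$node_ids[2]), ""))
  acc <- list(bif_id = numeric(0), euc = numeric(0), pd = numeric(0),
              asym = numeric(0), al = numeric(0), ar = numeric(0),
              tl = numeric(0), tr = numeric(0))
  for (b in bif_ids) {
    brow <- rowof(b)
    ch <- sort(kids[[as.character(b)]])
    par_id <- nd$parent[brow]
    vin <- if (par_id == -1L) c(NA, NA, NA)
      else xyz[brow, ] - xyz[rowof(par_id), ]
    for (ci in seq_len(length(ch) - 1L)) {
      c1 <- ch[ci]; c2 <- ch[ci + 1L]
      v1 <- xyz[rowof(c1), ] - xyz[brow, ]
      v2 <- xyz[rowof(c2), ] - xyz[brow, ]
      e1 <- branch_end[[paste(b, c1)]]
      e2 <- branch_end[[paste(b, c2)]]
      r1 <- xyz[rowof(e1), ] - xyz[brow, ]
      r2 <- xyz[rowof(e2), ] - xyz[brow, ]
      t1 <- tips[[as.character(c1)]]; t2 <- tips[[as.character(c2)]]
      tl <- tr <- NA_real_
      if (!anyNA(vin)) {
        tl <- min(angle_deg(vin, v1), angle_deg(vin, v2))
        tr <- min(angle_deg(vin, r1), angle_deg(vin, r2))
      }
      acc$bif_id <- c(acc$bif_id, b)
      acc$euc <- c(acc$euc, sqrt(sum((xyz[brow, ] - root_xyz)^2)))
      acc$pd <- c(acc$pd, pd[brow])
      acc$asym <- c(acc$asym,
                    if (t1 + t2 > 2) abs(t1 - t2) / (t1 + t2 - 2) else 0)
      acc$al <- c(acc$al, angle_deg(v1, v2))
      acc$ar <- c(acc$ar, angle_deg(r1, r2))
      acc$tl <- c(acc$tl, tl)
      acc$tr <- c(acc$tr, tr)
    }
  }
  list(branches = branches,
       bifurcations = data.frame(
         bif_id = acc$bif_id, bif_EucDist2soma = acc$euc,
         bif_PathDist2soma = acc$pd, asymmetry = acc$asym,
         ampl_local = acc$al, ampl_remote = acc$ar,
         tilt_local = acc$tl, tilt_remote = acc$tr))
}
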