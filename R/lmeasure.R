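lmeasure_names <- c(
  "Nodes", "SomaSurface", "Stems", "Bifurcations", "Branches", "Tips",
  "OverallWidth", "OverallHeight", "OverallDepth", "AverageDiameter",
  "Length", "Surface", "Volume", "MaxEuclideanDistance",
  "MaxPathDistance", "MaxBranchOrder", "AverageContraction",
  "AverageFragmentation", "AverageParent-daughterRatio",
  "AverageBifurcationAngleLocal", "AverageBifurcationAngleRemote",
  "HausdorffDimension")

#' Whole-neuron morphometric features (L-Measure style)
#'
#' The 22 classical global features: node count, soma surface (4 pi r^2
#' of the root), stem count, bifurcation count (a k-furcation counts as
#' k - 1), branch count, tip count, bounding-box extents, average
#' diameter (mean of 2 r over nodes), total cable length, membrane
#' surface and volume (frustum-free cylinder sums 2 pi r l and
#' pi r^2 l per compartment, r of the child node), maximal Euclidean
#' and path distance from the soma, maximal branch order, average
#' branch contraction (chord / path), average fragmentation
#' (compartments per branch), average parent-daughter radius ratio over
#' bifurcation daughters, average local and remote bifurcation angles
#' in degrees, and a box-counting Hausdorff dimension.
#'
#' The Hausdorff dimension uses 3-D box counting at four dyadic scales
#' starting from the tree bounding box, with nodes densely resampled
#' along edges, and the least-squares slope of log N vs log(1/s).
#'
#' @param tree a [neuron_tree()] with at least two nodes.
#' @param lf optional precomputed [local_branch_features()] result (a
#'   cache used when both feature sets are needed).
#' @return named numeric vector of length 22.
#' @export
lmeasure_features <- function(tree, lf = NULL) {
  nd <- tree$nodes
  if (nrow(nd) < 2) stop("lmeasure_features needs a tree with >= 2 nodes")
  nkid <- n_children_vec(tree)
  root_row <- which(nd$parent == -1L)
  brs <- branch_decompose(tree)
  len <- edge_lengths(tree)
  pd <- path_dist_to_root(tree)
  xyz <- node_xyz(tree)
  droot <- sqrt(rowSums((xyz - matrix(xyz[root_row, ], nrow(nd), 3,
                                      byrow = TRUE))^2))
  idx <- match(nd$parent, nd$id)
  haspar <- !is.na(idx)
  contraction <- vapply(brs, function(b)
    if (b$path_length > 0) b$euclidean_span / b$path_length else 1, 1)
  frag <- vapply(brs, function(b) length(b$node_ids) - 1L, 1L)
  # parent-daughter ratio over daughters at bifurcations
  bif_rows <- which(nkid >= 2)
  pdr <- numeric(0)
  for (i in bif_rows) {
    drows <- which(haspar & idx == i)
    if (nd$radius[i] > 0) pdr <- c(pdr, nd$radius[drows] / nd$radius[i])
  }
  if (is.null(lf)) lf <- local_branch_features(tree)
  bifs <- lf$bifurcations
  c(stats::setNames(c(
    nrow(nd),
    4 * pi * nd$radius[root_row]^2,
    sum(nd$parent == nd$id[root_row]),
    sum(pmax(nkid - 1L, 0L)) - max(0L, nkid[root_row] - 1L),
    length(brs),
    sum(nkid == 0),
    diff(range(nd$x)), diff(range(nd$y)), diff(range(nd$z)),
    mean(2 * nd$radius),
    sum(len),
    sum(2 * pi * nd$radius[haspar] * len[haspar]),
    sum(pi * nd$radius[haspar]^2 * len[haspar]),
    max(droot),
    max(pd),
    if (length(brs)) max(vapply(brs, function(b) b$order, 1)) else 0,
    mean(contraction),
    mean(frag),
    if (length(pdr)) mean(pdr) else 0,
    if (nrow(bifs)) mean(bifs$ampl_local) else 0,
    if (nrow(bifs)) mean(bifs$ampl_remote) else 0,
    hausdorff_dimension(tree)),
    lmeasure_names))
}

#' Box-counting fractal dimension of a skeleton
#'
#' @param tree a [neuron_tree()].
#' @param levels number of dyadic scales (box side halves each level).
#' @return estimated dimension (slope of log N over log 1/s).
#' @export
hausdorff_dimension <- function(tree, levels = 4L) {
  pts <- densify_points(tree)
  lo <- apply(pts, 2, min)
  side <- max(apply(pts, 2, max) - lo)
  if (side == 0) return(0)
  ns <- numeric(levels)
  ss <- numeric(levels)
  for (l in seq_len(levels)) {
    s <- side / 2^(l - 1)
    cell <- floor(sweep(pts, 2, lo) / s)
    cell[cell >= 2^(l - 1)] <- 2^(l - 1) - 1  # boundary points
    ns[l] <- nrow(unique(cell))
    ss[l] <- s
  }
  stats::coef(stats::lm(log(ns) ~ log(1 / ss)))[[2]]
}

#' dense point sampling along all edges (~1 point per min(edge)/2)
#' @noRd
densify_points <- function(tree, step = NULL) {
  nd <- tree$nodes
  idx <- match(nd$parent, nd$id)
  has <- !is.na(idx)
  xyz <- node_xyz(tree)
  if (is.null(step)) {
    len <- edge_lengths(tree)
    step <- max(stats::median(len[has]) / 2, 1e-6)
  }
  pts <- list(xyz)
  for (i in which(has)) {
    a <- xyz[idx[i], ]; b <- xyz[i, ]
    l <- sqrt(sum((b - a)^2))
    k <- floor(l / step)
    if (k >= 1) {
      f <- seq_len(k) / (k + 1)
      pts[[length(pts) + 1L]] <-
        cbind(a[1] + f * (b[1] - a[1]), a[2] + f * (b[2] - a[2]),
              a[3] + f * (b[3] - a[3]))
    }
  }
  m <- do.call(rbind, pts)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Principal-component shape features of a skeleton point cloud
#'
#' PCA of the node coordinates: the explained variance ratios of the
#' first three principal components (summing to 1) and the
#' sum-normalised absolute loadings of the first component (three
#' values summing to 1). Degenerate clouds (fewer than 3 distinct
#' points, or collinear) yield variance ratios (1, 0, 0).
#'
#' @param tree a [neuron_tree()] (or a 3-column coordinate matrix).
#' @return named numeric vector: pc1_var, pc2_var, pc3_var, pc1_x,
#'   pc1_y, pc1_z.
#' @export
pca_shape_features <- function(tree) {
  xyz <- if (inherits(tree, "neuron_tree")) node_xyz(tree) else
    as.matrix(tree)
  out <- stats::setNames(c(1, 0, 0, 1, 0, 0),
                         c("pc1_var", "pc2_var", "pc3_var",
                           "pc1_x", "pc1_y", "pc1_z"))
  cc <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(cc)
  ev <- c(sv$d^2, 0, 0)[1:3]   # fewer than 3 points: pad with zeros
  if (sum(ev) == 0) return(out)
  vr <- ev / sum(ev)
  load1 <- abs(sv$v[, 1])
  if (sum(load1) == 0) load1 <- c(1, 0, 0)
  out[1:3] <- vr
  out[4:6] <- load1 / sum(load1)
  out
}
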