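features24_names <- c(
  setdiff(lmeasure_names, c("Nodes", "SomaSurface", "AverageDiameter",
                            "Surface")),
  "pc1_var", "pc2_var", "pc3_var", "pc1_x", "pc1_y", "pc1_z")

#' 24-dimensional local-dendrite feature vector
#'
#' 18 whole-neuron morphometric features (the 22 of
#' [lmeasure_features()] minus Nodes, SomaSurface, AverageDiameter and
#' Surface) plus the PCA shape features of [pca_shape_features()]: the
#' explained-variance ratios of the first three principal components
#' and the sum-normalised absolute loadings of the first component.
#'
#' @param tree a [neuron_tree()].
#' @return named numeric vector of length 24.
#' @export
features24 <- function(tree) {
  lm <- lmeasure_features(tree)
  c(lm[setdiff(lmeasure_names,
               c("Nodes", "SomaSurface", "AverageDiameter", "Surface"))],
    pca_shape_features(tree))
}

#' Feature table of a neuron population
#'
#' @param trees list of [neuron_tree()].
#' @param fn per-neuron feature function (default [features24()]).
#' @return matrix (neurons x features) with rownames from tree
#'   metadata `neuron_id` (or the list index).
#' @export
feature_table <- function(trees, fn = features24) {
  m <- t(vapply(trees, fn, fn(trees[[1]])))
  rownames(m) <- vapply(seq_along(trees), function(i) {
    id <- trees[[i]]$metadata$neuron_id
    if (is.null(id)) as.character(i) else as.character(id)
  }, "")
  m
}

#' Build a dendritic microenvironment
#'
#' The microenvironment of a target neuron fuses the feature vectors
#' of the target and its `k` most feature-similar neighbours within a
#' sphere of radius `D` micrometres. Similarity is the Euclidean
#' distance between z-scored feature vectors; the fusion is spatial
#' proximity weighted averaging with weights
#' `w_i = exp(-d_i / D) / sum(exp(-d_j / D))`, `d_i` being the
#' soma-to-soma distance.
#'
#' @param target row index (or rowname) of the target neuron.
#' @param features neurons x features matrix (raw scale; z-scoring for
#'   the similarity search is internal).
#' @param soma neurons x 3 soma positions (um).
#' @param D sphere radius, um (default 249).
#' @param k maximal number of neighbours (default 5).
#' @return list: `member_idx`, `distances`, `weights`, `fused`
#'   (feature vector on the raw scale).
#' @export
build_microenvironment <- function(target, features, soma, D = 249,
                                   k = 5) {
  stopifnot(D > 0)
  if (is.character(target)) target <- match(target, rownames(features))
  if (is.na(target) || target < 1 || target > nrow(features)) {
    stop("target neuron not found")
  }
  z <- scale(features)
  z[is.na(z)] <- 0
  d_soma <- sqrt(colSums((t(soma) - soma[target, ])^2))
  in_sphere <- which(d_soma <= D)
  in_sphere <- setdiff(in_sphere, target)
  if (length(in_sphere)) {
    fdist <- sqrt(colSums((t(z[in_sphere, , drop = FALSE]) -
                             z[target, ])^2))
    nb <- in_sphere[order(fdist)][seq_len(min(k, length(in_sphere)))]
  } else nb <- integer(0)
  idx <- c(target, nb)
  d <- d_soma[idx]
  w <- exp(-d / D)
  w <- w / sum(w)
  fused <- colSums(features[idx, , drop = FALSE] * w)
  list(member_idx = idx, distances = d, weights = w, fused = fused)
}

#' Microenvironments for every neuron of a population
#'
#' @inheritParams build_microenvironment
#' @return list: `fused` (matrix like `features`), `envs` (per-neuron
#'   microenvironment lists).
#' @export
microenvironment_table <- function(features, soma, D = 249, k = 5) {
  envs <- lapply(seq_len(nrow(features)), build_microenvironment,
                 features = features, soma = soma, D = D, k = k)
  fused <- t(vapply(envs, function(e) e$fused, features[1, ]))
  dimnames(fused) <- dimnames(features)
  list(fused = fused, envs = envs)
}

#' mutual information of two discrete vectors (natural log)
#' @noRd
mi_discrete <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  }
  s
}

#' equal-width discretisation of a z-scored feature into bins
#' @noRd
discretize_ew <- function(x, bins = 5) {
  r <- range(x)
  if (anyNA(r) || diff(r) == 0) return(rep(1L, length(x)))
  cut(x, breaks = seq(r[1], r[2], length.out = bins + 1),
      include.lowest = TRUE, labels = FALSE)
}

#' Greedy mRMR feature ranking
#'
#' Max-relevance min-redundancy selection (the mutual-information
#' difference variant): features are z-scored and discretised into
#' `bins` equal-width bins; the first pick maximises mutual
#' information with the class label, and each subsequent pick
#' maximises relevance minus the mean mutual information with the
#' already selected features. Constant features are excluded with a
#' warning.
#'
#' @param features neurons x features matrix (column names required).
#' @param labels class labels (length nrow(features), >= 2 classes).
#' @param k number of features to rank (default 3).
#' @param bins discretisation bins (default 5).
#' @return character vector of feature names, best first.
#' @export
mrmr_select <- function(features, labels, k = 3, bins = 5) {
  stopifnot(length(unique(labels)) >= 2, k <= ncol(features))
  z <- scale(features)
  const <- apply(features, 2, function(c) stats::sd(c) == 0)
  if (any(const)) {
    warning("excluding constant feature(s): ",
            paste(colnames(features)[const], collapse = ", "))
  }
  avail <- which(!const)
  disc <- lapply(seq_len(ncol(features)), function(j)
    discretize_ew(z[, j], bins))
  rel <- vapply(seq_len(ncol(features)), function(j)
    mi_discrete(disc[[j]], labels), 1)
  chosen <- integer(0)
  for (step in seq_len(min(k, length(avail)))) {
    cand <- setdiff(avail, chosen)
    score <- vapply(cand, function(j) {
      red <- if (length(chosen))
        mean(vapply(chosen, function(c)
          mi_discrete(disc[[j]], disc[[c]]), 1)) else 0
      rel[j] - red
    }, 1)
    chosen <- c(chosen, cand[which.max(score)])
  }
  colnames(features)[chosen]
}

#' RGB microenvironment map
#'
#' Maps three selected features to colour channels at each soma
#' position in atlas space: min-max normalisation to 0-255, optional
#' mirroring of right-hemisphere somas (across the mid-sagittal x
#' plane), a sparse RGB volume at atlas resolution, and channel-wise
#' maximum-intensity projections of the middle sections (within
#' `slab_um` of the mid-plane along each axis).
#'
#' @param features neurons x features matrix (raw scale).
#' @param top3 three feature names (e.g. from [mrmr_select()]).
#' @param soma neurons x 3 soma positions, um (atlas space).
#' @param atlas a [make_toy_atlas()].
#' @param mirror mirror right-hemisphere somas to the left (default
#'   FALSE).
#' @param slab_um half-thickness of the mid-section slab (default
#'   1000).
#' @return list: `points` (data.frame with voxel positions and R, G, B
#'   in 0-255), `mips` (list of three 2-D x 3-channel arrays).
#' @export
rgb_map <- function(features, top3, soma, atlas, mirror = FALSE,
                    slab_um = 1000) {
  stopifnot(length(top3) == 3, all(top3 %in% colnames(features)))
  f <- features[, top3, drop = FALSE]
  rng <- apply(f, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], .Machine$double.eps)
  rgb <- sweep(sweep(f, 2, rng[1, ]), 2, span, "/") * 255
  pos <- as.matrix(soma)
  if (mirror) {
    mid <- atlas$dims[1] * atlas$voxel_size / 2
    right <- pos[, 1] > mid
    pos[right, 1] <- 2 * mid - pos[right, 1]
  }
  vox <- floor(pos / atlas$voxel_size)
  pts <- data.frame(vx = vox[, 1], vy = vox[, 2], vz = vox[, 3],
                    R = rgb[, 1], G = rgb[, 2], B = rgb[, 3])
  mid_vox <- atlas$dims / 2
  slab <- slab_um / atlas$voxel_size
  mips <- lapply(1:3, function(ax) {
    sel <- abs(vox[, ax] + 0.5 - mid_vox[ax]) <= slab
    other <- setdiff(1:3, ax)
    img <- array(0, c(atlas$dims[other], 3))
    for (i in which(sel)) {
      a <- vox[i, other[1]] + 1; b <- vox[i, other[2]] + 1
      if (a < 1 || b < 1 || a > dim(img)[1] || b > dim(img)[2]) next
      img[a, b, ] <- pmax(img[a, b, ], as.numeric(rgb[i, ]))
    }
    img
  })
  list(points = pts, mips = mips)
}

#' K-means clustering of regions on microenvironment statistics
#'
#' Each region is summarised by the concatenated mean and variance of
#' the selected features over the microenvironments whose target soma
#' lies in the region; regions are then clustered with k-means.
#'
#' @param features microenvironment features (neurons x features).
#' @param regions region id per neuron.
#' @param k number of clusters.
#' @param top3 optional feature subset (default: all columns).
#' @param seed RNG seed for k-means.
#' @return named integer vector: cluster id per region.
#' @export
region_clusters <- function(features, regions, k, top3 = NULL,
                            seed = 1) {
  if (!is.null(top3)) features <- features[, top3, drop = FALSE]
  regs <- sort(unique(regions))
  if (k > length(regs)) stop("k exceeds the number of regions")
  summ <- t(vapply(regs, function(r) {
    f <- features[regions == r, , drop = FALSE]
    v <- apply(f, 2, stats::var)
    v[is.na(v)] <- 0
    c(colMeans(f), v)
  }, numeric(2 * ncol(features))))
  set.seed(seed)
  cl <- stats::kmeans(summ, centers = k, nstart = 10)
  stats::setNames(cl$cluster, regs)
}

#' Mean-feature profile along an ordered region path
#'
#' @param features neurons x features matrix.
#' @param regions region id per neuron.
#' @param path ordered vector of region ids.
#' @return data.frame: region (in path order), n, then per-feature
#'   means; empty regions yield NA rows flagged by `n = 0`.
#' @export
path_profile <- function(features, regions, path) {
  rows <- lapply(path, function(r) {
    f <- features[regions == r, , drop = FALSE]
    if (!nrow(f)) {
      return(data.frame(region = r, n = 0,
                        t(stats::setNames(rep(NA_real_, ncol(features)),
                                          colnames(features)))))
    }
    data.frame(region = r, n = nrow(f), t(colMeans(f)))
  })
  do.call(rbind, rows)
}

#' Radial feature profile within a region
#'
#' Bins neurons by the projection of their soma position onto an axis
#' and returns per-bin feature means, for examining gradual spatial
#' change along a direction.
#'
#' @param features neurons x features matrix.
#' @param soma neurons x 3 soma positions.
#' @param axis direction vector (3), normalised internally.
#' @param bins number of bins along the axis.
#' @return data.frame: bin centre (`t`), n, per-feature means.
#' @export
radial_profile <- function(features, soma, axis = c(1, 0, 0),
                           bins = 5) {
  u <- unit(axis)
  t_ <- as.matrix(soma) %*% u
  br <- seq(min(t_), max(t_), length.out = bins + 1)
  bin <- cut(t_, br, include.lowest = TRUE, labels = FALSE)
  rows <- lapply(seq_len(bins), function(b) {
    f <- features[bin == b, , drop = FALSE]
    data.frame(t = (br[b] + br[b + 1]) / 2, n = nrow(f),
               t(if (nrow(f)) colMeans(f) else
                 stats::setNames(rep(NA_real_, ncol(features)),
                                 colnames(features))))
  })
  do.call(rbind, rows)
}
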