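#' Empirical foreground threshold of a 16-bit brain image
#'
#' `0.9 * min(max(mu + 1.5 * sigma, 400), 1000)` where `mu` and `sigma`
#' are the global mean and standard deviation of all voxels.
#'
#' @param block an [image_block()] (16-bit intensities).
#' @return scalar threshold.
#' @export
foreground_threshold <- function(block) {
  x <- block$data
  if (length(x) == 0) stop("empty image block")
  mu <- mean(x)
  s <- stats::sd(as.vector(x))
  0.9 * min(max(mu + 1.5 * s, 400), 1000)
}

#' local-mean-subtraction denoising (5^3 box), clamped at zero
#' @noRd
adaptive_denoise <- function(x, w = 5) {
  pmax(x - box_mean(x, w), 0)
}

#' separable box mean with replicated borders
#' @noRd
box_mean <- function(x, w = 5) {
  r <- (w - 1) / 2
  for (ax in 1:3) {
    acc <- x * 0
    for (o in -r:r) {
      acc <- acc + shift_array(x, ax, o)
    }
    x <- acc / w
  }
  x
}

#' shift array along axis with edge replication
#' @noRd
shift_array <- function(x, axis, offset) {
  if (offset == 0) return(x)
  d <- dim(x)
  idx <- pmin(pmax(seq_len(d[axis]) + offset, 1), d[axis])
  switch(axis,
         x[idx, , , drop = FALSE],
         x[, idx, , drop = FALSE],
         x[, , idx, drop = FALSE])
}

#' Anisotropy salience of an image block
#'
#' The block is partitioned into cuboids; for each cuboid the
#' intensity-weighted PCA eigenvalues S1 >= S2 >= S3 of the foreground
#' voxel coordinates give the anisotropy score
#' `(S1 - S2) / (S1 + S2) * (S1 - S3) / (S1 + S3)` (1 for a line, ~0
#' for an isotropic blob; 0 when fewer than 3 foreground voxels).
#' The salience image is the adaptively denoised block times the
#' per-voxel upsampled score map.
#'
#' @param block an [image_block()].
#' @param cuboid cuboid edge length in voxels (default 16).
#' @param fg_frac_of_max voxels of a cuboid whose denoised intensity
#'   exceeds this fraction of the cuboid maximum enter the weighted
#'   PCA (default 0.5; scale-free, so a tube clipped by a cuboid
#'   border is still seen as a line).
#' @return list: `salience` (array), `score` (per-voxel score array),
#'   `denoised`.
#' @export
anisotropy_salience <- function(block, cuboid = 16, fg_frac_of_max = 0.5) {
  x <- block$data
  den <- adaptive_denoise(x)
  d <- dim(x)
  nb <- ceiling(d / cuboid)
  score <- array(0, d)
  for (bi in seq_len(nb[1])) for (bj in seq_len(nb[2]))
    for (bk in seq_len(nb[3])) {
      xs <- ((bi - 1) * cuboid + 1):min(bi * cuboid, d[1])
      ys <- ((bj - 1) * cuboid + 1):min(bj * cuboid, d[2])
      zs <- ((bk - 1) * cuboid + 1):min(bk * cuboid, d[3])
      sub <- den[xs, ys, zs, drop = FALSE]
      fg_thresh <- max(fg_frac_of_max * max(sub), .Machine$double.eps)
      fg <- which(sub >= fg_thresh, arr.ind = TRUE)
      if (nrow(fg) < 3) next
      w <- sub[fg]
      w <- w / sum(w)
      ctr <- colSums(fg * w)
      cc <- sweep(fg, 2, ctr)
      cov <- crossprod(cc * sqrt(w))
      ev <- sort(eigen(cov, symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)
      ev <- pmax(ev, 0)
      s <- if (ev[1] + ev[2] > 0 && ev[1] + ev[3] > 0)
        (ev[1] - ev[2]) / (ev[1] + ev[2]) *
        (ev[1] - ev[3]) / (ev[1] + ev[3]) else 0
      score[xs, ys, zs] <- s
    }
  list(salience = den * score, score = score, denoised = den)
}

#' Segment neurite voxels in an image block
#'
#' Implements the salience-based segmentation: blocks whose maximum
#' intensity is below `prefilter_max` (default 300) yield an empty
#' mask; otherwise the anisotropy salience image is thresholded at
#' `0.1 * thresh`.
#'
#' @param block an [image_block()].
#' @param thresh foreground threshold from [foreground_threshold()].
#' @param prefilter_max block-level pre-filter on the maximum intensity.
#' @param cuboid cuboid size for [anisotropy_salience()].
#' @return logical 3-D mask.
#' @export
segment_neurites <- function(block, thresh = foreground_threshold(block),
                             prefilter_max = 300, cuboid = 16) {
  x <- block$data
  if (max(x) < prefilter_max) return(array(FALSE, dim(x)))
  sal <- anisotropy_salience(block, cuboid = cuboid)
  sal$salience >= 0.1 * thresh
}

#' Regional neurite density vector from a segmentation mask
#'
#' Counts mask voxels per atlas region and divides by the total number
#' of neurite voxels (all-zero if the mask is empty).
#'
#' @param mask logical array, same voxel grid as the atlas volume.
#' @param atlas a [make_toy_atlas()] result.
#' @return named numeric vector over the atlas regions, summing to 1.
#' @export
neurite_density_vector <- function(mask, atlas) {
  if (!identical(dim(mask), dim(atlas$volume))) {
    stop("mask and atlas dimensions differ")
  }
  regions <- atlas$region_table$region_id
  lab <- atlas$volume[mask]
  cnt <- tabulate(lab, nbins = max(regions))[regions]
  tot <- sum(mask)
  out <- if (tot > 0) cnt / tot else rep(0, length(regions))
  stats::setNames(out, regions)
}

#' Gray-scale distance transform
#'
#' Geodesic distance from the background through the foreground mask,
#' with the step into a voxel costing `step_length / w` where `w` is
#' the voxel's normalised intensity (so a uniformly bright mask reduces
#' to the Euclidean distance transform). Computed by iterated chamfer
#' (Jacobi) relaxation over the 26-neighbourhood.
#'
#' @param mask logical 3-D foreground mask.
#' @param weights optional array of positive per-voxel weights in
#'   (0, 1]; `NULL` for the plain distance transform.
#' @param max_iter relaxation iteration cap.
#' @return numeric array of distances (0 on background).
#' @export
gsdt <- function(mask, weights = NULL, max_iter = 60) {
  d <- dim(mask)
  dist <- array(Inf, d)
  dist[!mask] <- 0
  if (!any(mask)) return(dist)
  cost <- if (is.null(weights)) array(1, d) else 1 / pmax(weights, 1e-3)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  steplen <- sqrt(offs$dx^2 + offs$dy^2 + offs$dz^2)
  for (it in seq_len(max_iter)) {
    prev <- dist
    for (o in seq_len(nrow(offs))) {
      sh <- shift_dist(dist, offs$dx[o], offs$dy[o], offs$dz[o])
      dist <- pmin(dist, sh + steplen[o] * cost)
    }
    dist[!mask] <- 0
    if (max(abs(dist - prev)[is.finite(dist) & is.finite(prev)]) < 1e-9 &&
        !any(is.finite(dist) != is.finite(prev))) break
  }
  dist[is.infinite(dist)] <- 0  # foreground islands touching no border
  dist
}

#' shift with +Inf padding (treat outside as unreachable, borders count
#' as background via the explicit background zeros)
#' @noRd
shift_dist <- function(x, dx, dy, dz) {
  d <- dim(x)
  out <- array(0, d)  # outside the block counts as background
  xs <- seq_len(d[1]) - dx; ys <- seq_len(d[2]) - dy
  zs <- seq_len(d[3]) - dz
  okx <- xs >= 1 & xs <= d[1]; oky <- ys >= 1 & ys <= d[2]
  okz <- zs >= 1 & zs <= d[3]
  out[okx, oky, okz] <- x[xs[okx], ys[oky], zs[okz]]
  out
}

#' Detect soma candidates in an image block
#'
#' Pipeline: skip blocks with maximum intensity below `min_block_max`
#' (16-bit); Z-score normalise and convert to 8-bit; binarise at the
#' 99th percentile; gray-scale distance transform of the foreground;
#' voxels whose transform value falls in `candidate_range` become
#' candidates; a non-maximal-suppression pass keeps only the strongest
#' candidate within `nms_radius` voxels.
#'
#' @param block an [image_block()] (16-bit).
#' @param min_block_max block skip threshold (default 250).
#' @param binarize_quantile foreground quantile (default 0.99).
#' @param candidate_range inclusive transform-value band
#'   (default c(5, 30)).
#' @param nms_radius suppression radius in voxels (default 8).
#' @return data.frame of candidates: center (cx, cy, cz voxel
#'   coordinates), score, refined = FALSE.
#' @export
detect_somas <- function(block, min_block_max = 250,
                         binarize_quantile = 0.99,
                         candidate_range = c(5, 30), nms_radius = 8) {
  empty <- data.frame(cx = numeric(), cy = numeric(), cz = numeric(),
                      score = numeric(), refined = logical())
  x <- block$data
  if (max(x) < min_block_max) return(empty)
  mu <- mean(x); s <- stats::sd(as.vector(x))
  z <- (x - mu) / max(s, 1e-9)
  x8 <- pmin(pmax((z - min(z)) / max(max(z) - min(z), 1e-9) * 255, 0), 255)
  th <- stats::quantile(x8, binarize_quantile)
  mask <- x8 >= th
  wts <- array(0, dim(x))
  wts[mask] <- x8[mask] / max(x8[mask])
  dt <- gsdt(mask, weights = wts)
  cand <- which(dt >= candidate_range[1] & dt <= candidate_range[2],
                arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  sc <- dt[cand]
  ord <- order(sc, decreasing = TRUE)
  kept <- matrix(NA_real_, 0, 3)
  ks <- numeric(0)
  for (i in ord) {
    p <- cand[i, ]
    if (nrow(kept) == 0 ||
        min(sqrt(rowSums(sweep(kept, 2, p)^2))) > nms_radius) {
      kept <- rbind(kept, p)
      ks <- c(ks, sc[i])
    }
  }
  data.frame(cx = kept[, 1], cy = kept[, 2], cz = kept[, 3],
             score = ks, refined = FALSE)
}

#' Refine soma candidates by mean shift and remove duplicates
#'
#' Voxels below `mu + sigma` are zero-clipped; each candidate is moved
#' to the intensity centroid of a cubic window (size `window` voxels)
#' until convergence. Candidates that converged onto the same
#' attractor (within `coincide_radius` voxels) collapse to the
#' brighter one; beyond that, two somas within `dup_radius` voxels
#' whose midpoint intensity is below the mean of their centre
#' intensities are merged (the dimmer one is dropped).
#'
#' @param candidates data.frame from [detect_somas()].
#' @param block the same [image_block()].
#' @param window mean-shift window edge length, voxels (default 15).
#' @param dup_radius duplicate radius, voxels (default 15).
#' @param coincide_radius same-attractor merge radius (default 3).
#' @param max_iter mean-shift iteration cap.
#' @return data.frame of refined candidates.
#' @export
refine_somas <- function(candidates, block, window = 15,
                         dup_radius = 15, coincide_radius = 3,
                         max_iter = 30) {
  if (!nrow(candidates)) return(candidates)
  x <- block$data
  mu <- mean(x); s <- stats::sd(as.vector(x))
  xc <- x
  xc[xc < mu + s] <- 0
  d <- dim(x)
  r <- (window - 1) / 2
  shift_once <- function(p) {
    lo <- pmax(round(p - r), 1)
    hi <- pmin(round(p + r), d)
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    sub <- xc[xs, ys, zs, drop = FALSE]
    tot <- sum(sub)
    if (tot == 0) return(p)
    w <- which(sub > 0, arr.ind = TRUE)
    v <- sub[w]
    c(sum((w[, 1] + lo[1] - 1) * v), sum((w[, 2] + lo[2] - 1) * v),
      sum((w[, 3] + lo[3] - 1) * v)) / tot
  }
  pts <- as.matrix(candidates[, c("cx", "cy", "cz")])
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    for (it in seq_len(max_iter)) {
      p2 <- shift_once(p)
      if (sqrt(sum((p2 - p)^2)) < 0.01) { p <- p2; break }
      p <- p2
    }
    pts[i, ] <- p
  }
  inten <- x[cbind(pmin(pmax(round(pts[, 1]), 1), d[1]),
                   pmin(pmax(round(pts[, 2]), 1), d[2]),
                   pmin(pmax(round(pts[, 3]), 1), d[3]))]
  keep <- rep(TRUE, nrow(pts))
  ord <- order(inten, decreasing = TRUE)
  for (i in ord) {
    if (!keep[i]) next
    for (j in ord) {
      if (i == j || !keep[j]) next
      dd <- sqrt(sum((pts[i, ] - pts[j, ])^2))
      if (dd <= coincide_radius) {
        # both converged to the same attractor
        if (inten[j] <= inten[i]) keep[j] <- FALSE else keep[i] <- FALSE
      } else if (dd <= dup_radius) {
        mid <- pmin(pmax(round((pts[i, ] + pts[j, ]) / 2), 1), d)
        if (x[mid[1], mid[2], mid[3]] < mean(c(inten[i], inten[j]))) {
          # duplicate pair: drop the dimmer of the two
          if (inten[j] <= inten[i]) keep[j] <- FALSE else keep[i] <- FALSE
        }
      }
    }
  }
  data.frame(cx = pts[keep, 1], cy = pts[keep, 2], cz = pts[keep, 3],
             score = candidates$score[keep], refined = TRUE)
}

#' Sample intensity and local radius profiles along a skeleton
#'
#' For every node: trilinear image intensity at the node position, and
#' the estimated local radius — the largest sphere radius (up to
#' `max_radius`) whose mean intensity stays at or above half the
#' centre intensity. Nodes outside the volume are flagged and get 0.
#'
#' @param tree a [neuron_tree()] registered to the block's micrometre
#'   frame.
#' @param block an [image_block()].
#' @param max_radius search cap in micrometres.
#' @param step radius search step, micrometres.
#' @return data.frame: id, intensity, radius, outside.
#' @export
sample_profiles <- function(tree, block, max_radius = 6, step = 0.25) {
  nd <- tree$nodes
  d <- dim(block$data)
  vs <- block$voxel_size
  pvox <- cbind(nd$x / vs[1], nd$y / vs[2], nd$z / vs[3]) + 0.5
  outside <- pvox[, 1] < 1 | pvox[, 1] > d[1] |
    pvox[, 2] < 1 | pvox[, 2] > d[2] |
    pvox[, 3] < 1 | pvox[, 3] > d[3]
  inten <- numeric(nrow(nd))
  radius <- numeric(nrow(nd))
  # precompute unit sphere sample directions
  dirs <- rbind(diag(3), -diag(3),
                unit(c(1, 1, 1)), unit(c(-1, 1, 1)), unit(c(1, -1, 1)),
                unit(c(1, 1, -1)), unit(c(-1, -1, 1)), unit(c(-1, 1, -1)),
                unit(c(1, -1, -1)), unit(c(-1, -1, -1)))
  for (i in seq_len(nrow(nd))) {
    if (outside[i]) next
    c0 <- trilinear(block$data, pvox[i, , drop = FALSE])
    inten[i] <- c0
    if (c0 <= 0) next
    rbest <- 0
    for (r in seq(step, max_radius, by = step)) {
      shell <- sweep(dirs * r, 2, vs, "/")
      pts <- sweep(shell, 2, pvox[i, ], "+")
      ok <- pts[, 1] >= 1 & pts[, 1] <= d[1] &
        pts[, 2] >= 1 & pts[, 2] <= d[2] &
        pts[, 3] >= 1 & pts[, 3] <= d[3]
      if (!any(ok)) break
      m <- mean(trilinear(block$data, pts[ok, , drop = FALSE]))
      if (m >= c0 / 2) rbest <- r else break
    }
    radius[i] <- rbest
  }
  data.frame(id = nd$id, intensity = inten, radius = radius,
             outside = outside)
}

#' trilinear interpolation at 1-based fractional voxel coordinates
#' @noRd
trilinear <- function(vol, pts) {
  d <- dim(vol)
  p0 <- pmin(pmax(floor(pts), 1), matrix(rep(d - 1, each = nrow(pts)),
                                         ncol = 3))
  f <- pts - p0
  f <- pmin(pmax(f, 0), 1)
  out <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (dx * f[, 1] + (1 - dx) * (1 - f[, 1])) *
      (dy * f[, 2] + (1 - dy) * (1 - f[, 2])) *
      (dz * f[, 3] + (1 - dz) * (1 - f[, 3]))
    out <- out + w * vol[cbind(p0[, 1] + dx, p0[, 2] + dy, p0[, 3] + dz)]
  }
  out
}

#' Read / write a 3-D grayscale TIFF stack
#'
#' @param path file path.
#' @param voxel_size micrometres per voxel for the returned block.
#' @param bits bit depth interpretation.
#' @return [image_block()] (read) or `path` (write).
#' @export
read_tiff_block <- function(path, voxel_size = 1, bits = 16) {
  sl <- tiff::readTIFF(path, all = TRUE)
  arr <- simplify2array(sl)          # y, x, z with values in [0,1]
  arr <- aperm(arr, c(2, 1, 3)) * (2^bits - 1)
  image_block(arr, voxel_size, bits = bits)
}

#' @rdname read_tiff_block
#' @param block an [image_block()] to write.
#' @export
write_tiff_block <- function(block, path, bits = block$bits) {
  arr <- block$data / (2^bits - 1)
  arr <- pmin(pmax(arr, 0), 1)
  sl <- lapply(seq_len(dim(arr)[3]), function(k) t(arr[, , k]))
  tiff::writeTIFF(sl, path, bits.per.sample = if (bits > 8) 16L else 8L)
  invisible(path)
}
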