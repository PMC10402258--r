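#' Image block container
#'
#' A thin wrapper for a 3-D intensity array with voxel size and origin,
#' the unit consumed by the image-domain detectors.
#'
#' @param data 3-D non-negative numeric array.
#' @param voxel_size micrometres per voxel, length 1 or 3.
#' @param origin micrometre offset of voxel (0,0,0)'s corner.
#' @param bits 8 or 16 (intensity convention).
#' @return object of class `image_block`.
#' @export
image_block <- function(data, voxel_size = 1, origin = c(0, 0, 0),
                        bits = 16) {
  stopifnot(length(dim(data)) == 3, all(dim(data) >= 8), all(data >= 0))
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  structure(list(data = data, voxel_size = voxel_size, origin = origin,
                 bits = bits), class = "image_block")
}

#' stamp an additive Gaussian blob into an accumulator array
#' @noRd
stamp_blob <- function(acc, center, sigma, amplitude, cutoff = 3) {
  dims <- dim(acc)
  lo <- pmax(floor(center - cutoff * sigma), 1)
  hi <- pmin(ceiling(center + cutoff * sigma), dims)
  if (any(lo > hi)) return(acc)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  gx <- exp(-((xs - center[1])^2) / (2 * sigma[1]^2))
  gy <- exp(-((ys - center[2])^2) / (2 * sigma[2]^2))
  gz <- exp(-((zs - center[3])^2) / (2 * sigma[3]^2))
  blob <- amplitude * (gx %o% gy %o% gz)
  acc[xs, ys, zs] <- pmax(acc[xs, ys, zs], blob)
  acc
}

#' stamp a solid soft-edged sphere (max-combined)
#' @noRd
stamp_sphere <- function(acc, center, radius, amplitude, edge = 1.5) {
  dims <- dim(acc)
  lo <- pmax(floor(center - radius - 3 * edge), 1)
  hi <- pmin(ceiling(center + radius + 3 * edge), dims)
  if (any(lo > hi)) return(acc)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  dx2 <- (xs - center[1])^2
  dy2 <- (ys - center[2])^2
  dz2 <- (zs - center[3])^2
  r <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
  prof <- amplitude / (1 + exp((r - radius) / (edge / 2)))
  acc[xs, ys, zs] <- pmax(acc[xs, ys, zs], prof)
  acc
}

#' Render neuron skeletons into a synthetic image volume
#'
#' Somas become bright soft-edged spheres (radius from the root node),
#' neurites tubes with Gaussian cross-section, and planted boutons
#' local amplitude and radius bumps. Additive Gaussian noise is scaled
#' as `amplitude / snr`; output is clamped to unsigned 16-bit.
#'
#' @param trees list of [neuron_tree()] in the volume's micrometre
#'   frame (or an empty list for a pure-noise volume).
#' @param dims voxel dimensions (3-vector).
#' @param voxel_size micrometres per voxel (scalar or 3-vector; set
#'   anisotropic values to emulate coarser z sampling).
#' @param amplitude peak signal intensity of neurites.
#' @param soma_amplitude peak soma intensity.
#' @param background mean background level.
#' @param snr signal-to-noise ratio (amplitude over the sd of the raw
#'   per-voxel noise draw); `Inf` disables noise.
#' @param noise_smooth low-pass the noise field (two 5^3 box passes)
#'   to emulate the spatial correlation that optics and downsampling
#'   averaging impose on microscopy background (default TRUE).
#' @param tube_sigma Gaussian cross-section sigma of neurites, um.
#' @param boutons optional data.frame (columns x, y, z in um,
#'   amp_scale, sigma_scale) of planted varicosities; also returned as
#'   the ground-truth ledger.
#' @param seed RNG seed for the noise.
#' @return list: `block` ([image_block()]) and `ground_truth` (soma
#'   centres in voxels, bouton table).
#' @export
render_volume <- function(trees, dims = c(96, 96, 96), voxel_size = 1,
                          amplitude = 1500, soma_amplitude = 2000,
                          background = 100, snr = 10,
                          noise_smooth = TRUE, tube_sigma = 1.2,
                          boutons = NULL, seed = 1) {
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  acc <- array(0, dims)
  soma_vox <- NULL
  for (tr in trees) {
    nd <- tr$nodes
    rvox <- function(p) p / voxel_size + 0.5  # um -> 1-based voxel center
    root <- which(nd$parent == -1L)
    cs <- rvox(c(nd$x[root], nd$y[root], nd$z[root]))
    if (nd$structure[root] == 1L) {
      acc <- stamp_sphere(acc, cs, nd$radius[root] / mean(voxel_size),
                          soma_amplitude)
      soma_vox <- rbind(soma_vox, cs)
    }
    idx <- match(nd$parent, nd$id)
    has <- which(!is.na(idx))
    sig <- tube_sigma / voxel_size
    for (i in has) {
      a <- c(nd$x[idx[i]], nd$y[idx[i]], nd$z[idx[i]])
      b <- c(nd$x[i], nd$y[i], nd$z[i])
      l <- sqrt(sum((b - a)^2))
      nstep <- max(1L, ceiling(l / (0.5 * min(voxel_size))))
      for (f in seq(0, 1, length.out = nstep + 1L)) {
        acc <- stamp_blob(acc, rvox(a + f * (b - a)), sig, amplitude)
      }
    }
  }
  if (!is.null(boutons) && nrow(boutons)) {
    for (i in seq_len(nrow(boutons))) {
      p <- c(boutons$x[i], boutons$y[i], boutons$z[i]) / voxel_size + 0.5
      acc <- stamp_blob(acc, p,
                        boutons$sigma_scale[i] * tube_sigma / voxel_size,
                        boutons$amp_scale[i] * amplitude)
    }
  }
  set.seed(seed)
  noise_sd <- if (is.finite(snr) && snr > 0) amplitude / snr else 0
  noise <- array(stats::rnorm(prod(dims), 0, noise_sd), dims)
  if (noise_smooth && noise_sd > 0) {
    noise <- box_mean(box_mean(noise, 5), 5)
  }
  img <- acc + background + noise
  img <- pmin(pmax(img, 0), 65535)
  list(block = image_block(array(img, dims), voxel_size, bits = 16),
       ground_truth = list(soma_vox = soma_vox, boutons = boutons))
}

#' Synthetic soma field: bright spheres in a noisy volume
#'
#' Places `n` non-overlapping spheres uniformly in the volume with a
#' minimum pairwise separation and renders them with additive Gaussian
#' noise (sd = amplitude / snr).
#'
#' @param n number of somas.
#' @param dims voxel dimensions.
#' @param radius sphere radius, voxels.
#' @param min_sep minimum centre separation, voxels.
#' @param amplitude peak intensity (16-bit scale).
#' @param background background level.
#' @param snr signal-to-noise ratio.
#' @param seed RNG seed.
#' @return list: `block` ([image_block()], voxel size 1 um) and
#'   `centers` (n x 3 voxel coordinates, 1-based).
#' @export
synth_soma_field <- function(n = 30, dims = c(128, 128, 128),
                             radius = 5, min_sep = 25, amplitude = 2000,
                             background = 100, snr = 8, seed = 1) {
  set.seed(seed)
  centers <- matrix(NA_real_, 0, 3)
  tries <- 0
  while (nrow(centers) < n && tries < 20000) {
    tries <- tries + 1
    p <- stats::runif(3, radius + 2, dims - radius - 2)
    if (nrow(centers) == 0 ||
        min(sqrt(rowSums(sweep(centers, 2, p)^2))) >= min_sep) {
      centers <- rbind(centers, p)
    }
  }
  if (nrow(centers) < n) stop("could not place somas with given min_sep")
  acc <- array(0, dims)
  for (i in seq_len(n)) acc <- stamp_sphere(acc, centers[i, ], radius,
                                            amplitude)
  img <- acc + background +
    stats::rnorm(length(acc), 0, amplitude / snr)
  img <- pmin(pmax(img, 0), 65535)
  list(block = image_block(array(img, dims), 1, bits = 16),
       centers = centers)
}

#' Synthetic intensity and radius profiles with planted boutons
#'
#' Generates, for every node of a tree, the image-derived quantities
#' the bouton detector consumes: an 8-bit intensity profile and a local
#' radius profile along the axon, with Gaussian bumps (default radius
#' x2, intensity 200) planted at known arc-length positions. Planted
#' positions keep a minimum arc separation.
#'
#' @param tree a [neuron_tree()] (axon nodes carry structure 2).
#' @param n_boutons number of boutons to plant.
#' @param base_intensity,base_radius axon shaft levels (8-bit / um).
#' @param bouton_intensity,bouton_radius_scale bump peak levels.
#' @param bump_sigma arc-length sigma of each bump, um.
#' @param min_gap minimum arc separation of planted boutons, um.
#' @param noise_sd additive noise on both profiles (intensity units;
#'   the radius profile receives `noise_sd / 100` um).
#' @param seed RNG seed.
#' @return list: `profiles` (data.frame id, intensity, radius),
#'   `ground_truth` (data.frame node_id, arc position within branch,
#'   path_dist, xyz).
#' @export
synth_bouton_profiles <- function(tree, n_boutons = 20,
                                  base_intensity = 90, base_radius = 0.6,
                                  bouton_intensity = 200,
                                  bouton_radius_scale = 2,
                                  bump_sigma = 1.5, min_gap = 15,
                                  noise_sd = 5, seed = 1) {
  set.seed(seed)
  nd <- tree$nodes
  pd <- path_dist_to_root(tree)
  ax <- which(nd$structure == 2L)
  if (!length(ax)) stop("tree has no axon nodes")
  intensity <- rep(0, nrow(nd))
  radius <- rep(0, nrow(nd))
  intensity[ax] <- base_intensity
  radius[ax] <- base_radius
  # choose bouton host nodes by path distance with a minimum gap
  cand <- ax[order(pd[ax])]
  chosen <- integer(0)
  for (i in sample(seq_along(cand))) {
    node <- cand[i]
    if (!length(chosen) || min(abs(pd[node] - pd[chosen])) >= min_gap) {
      chosen <- c(chosen, node)
    }
    if (length(chosen) >= n_boutons) break
  }
  chosen <- sort(chosen)
  # bumps expressed in arc length along the path to the root
  for (node in chosen) {
    d <- abs(pd[ax] - pd[node])
    # restrict to nodes on the same root path side: use euclidean gate
    eu <- sqrt((nd$x[ax] - nd$x[node])^2 +
               (nd$y[ax] - nd$y[node])^2 +
               (nd$z[ax] - nd$z[node])^2)
    w <- exp(-d^2 / (2 * bump_sigma^2)) * (eu <= 4 * bump_sigma)
    intensity[ax] <- pmax(intensity[ax],
                          base_intensity +
                            (bouton_intensity - base_intensity) * w)
    radius[ax] <- pmax(radius[ax],
                       base_radius *
                         (1 + (bouton_radius_scale - 1) * w))
  }
  intensity <- pmax(intensity + stats::rnorm(length(intensity), 0,
                                             noise_sd), 0)
  radius <- pmax(radius + stats::rnorm(length(radius), 0,
                                       noise_sd / 100), 0)
  gt <- data.frame(node_id = nd$id[chosen], path_dist = pd[chosen],
                   x = nd$x[chosen], y = nd$y[chosen], z = nd$z[chosen])
  list(profiles = data.frame(id = nd$id, intensity = intensity,
                             radius = radius),
       ground_truth = gt)
}
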