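#' Build a toy labelled atlas volume
#'
#' Emulates a low-resolution (25 micrometre voxel) labelled brain atlas
#' with a two-level hierarchy: regions grouped into compound areas.
#' The brain mask is an ellipsoid inscribed in the volume; regions are
#' the Voronoi cells of seeded interior points intersected with the
#' mask (hence connected), and compound areas group regions by k-means
#' on the seed points.
#'
#' @param n_regions number of regions (>= 2).
#' @param dims integer vector of 3 voxel dimensions (each <= 256).
#' @param n_areas number of compound areas (default ~ n_regions / 4,
#'   at least 2).
#' @param voxel_size micrometres per voxel (default 25).
#' @param seed RNG seed.
#' @return object of class `toy_atlas`: `volume` (3-D integer array,
#'   0 = background), `region_table` (region_id, name, area_id,
#'   area_name), `voxel_size`, `dims`.
#' @export
make_toy_atlas <- function(n_regions = 8, dims = c(64, 64, 64),
                           n_areas = max(2, round(n_regions / 4)),
                           voxel_size = 25, seed = 1) {
  stopifnot(n_regions >= 2, all(dims >= 8), all(dims <= 256))
  if (prod(dims) < n_regions * 8) stop("infeasible tiling: volume too small")
  set.seed(seed)
  ctr <- dims / 2
  ax <- dims / 2 - 1
  # seed points inside the ellipsoid
  seeds <- matrix(NA_real_, n_regions, 3)
  k <- 0
  while (k < n_regions) {
    p <- stats::runif(3, 0.15, 0.85) * dims
    if (sum(((p - ctr) / ax)^2) < 0.8) {
      k <- k + 1
      seeds[k, ] <- p
    }
  }
  g <- expand.grid(x = seq_len(dims[1]) - 0.5, y = seq_len(dims[2]) - 0.5,
                   z = seq_len(dims[3]) - 0.5)
  inside <- ((g$x - ctr[1]) / ax[1])^2 + ((g$y - ctr[2]) / ax[2])^2 +
    ((g$z - ctr[3]) / ax[3])^2 <= 1
  lab <- integer(nrow(g))
  gi <- as.matrix(g[inside, ])
  d2 <- matrix(0, nrow(gi), n_regions)
  for (r in seq_len(n_regions)) {
    d2[, r] <- (gi[, 1] - seeds[r, 1])^2 + (gi[, 2] - seeds[r, 2])^2 +
      (gi[, 3] - seeds[r, 3])^2
  }
  lab[inside] <- max.col(-d2, ties.method = "first")
  vol <- array(lab, dim = dims)
  km <- stats::kmeans(seeds, centers = min(n_areas, n_regions),
                      nstart = 5)
  region_table <- data.frame(
    region_id = seq_len(n_regions),
    name = sprintf("R%02d", seq_len(n_regions)),
    area_id = km$cluster,
    area_name = sprintf("CA%d", km$cluster))
  structure(list(volume = vol, region_table = region_table,
                 voxel_size = voxel_size, dims = dims,
                 seeds = seeds),
            class = "toy_atlas")
}

#' Look up atlas region labels at world coordinates
#'
#' World micrometre coordinates map to 0-based voxel indices by
#' `floor(xyz / voxel_size)` (half-open voxel ranges). Points outside
#' the volume return 0 (background).
#'
#' @param atlas a [make_toy_atlas()] result.
#' @param xyz n x 3 matrix of micrometre coordinates.
#' @return integer vector of region ids (0 = background/outside).
#' @export
atlas_lookup <- function(atlas, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  v <- floor(xyz / atlas$voxel_size)  # 0-based voxel
  ok <- v[, 1] >= 0 & v[, 1] < atlas$dims[1] &
    v[, 2] >= 0 & v[, 2] < atlas$dims[2] &
    v[, 3] >= 0 & v[, 3] < atlas$dims[3]
  out <- integer(nrow(xyz))
  out[ok] <- atlas$volume[cbind(v[ok, 1] + 1, v[ok, 2] + 1, v[ok, 3] + 1)]
  out
}

#' Random interior point of a given atlas region (micrometres)
#' @noRd
region_point <- function(atlas, region_id, n = 1) {
  w <- which(atlas$volume == region_id, arr.ind = TRUE)
  i <- w[sample.int(nrow(w), n, replace = TRUE), , drop = FALSE]
  (i - 1 + matrix(stats::runif(3 * n), n, 3)) * atlas$voxel_size
}

#' Synthetic regional neurite-density matrix with planted modules
#'
#' Rows are regions, columns are brains. Regions inside a planted
#' module share a latent per-brain loading vector (log-normal) scaled
#' by a per-region gain, plus independent Gaussian noise; background
#' regions are independent noise. All entries are clamped non-negative
#' and every column is normalised to sum to 1 (a per-brain density
#' fraction).
#'
#' @param n_regions,n_brains matrix dimensions (>= 2 each).
#' @param modules list of integer vectors of region indices (disjoint),
#'   or an integer count of planted modules whose sizes are drawn from
#'   3:6.
#' @param snr signal-to-noise ratio: sd of the shared component over sd
#'   of the additive noise.
#' @param seed RNG seed.
#' @return list with `values` (regions x brains), `region_ids`,
#'   `brain_ids`, `module_labels` (0 = background).
#' @export
make_density_matrix <- function(n_regions = 50, n_brains = 50,
                                modules = 8, snr = 10, seed = 1) {
  stopifnot(n_regions >= 2, n_brains >= 2)
  set.seed(seed)
  if (is.numeric(modules) && length(modules) == 1) {
    sizes <- sample(3:6, modules, replace = TRUE)
    if (sum(sizes) > n_regions) stop("modules do not fit in n_regions")
    pool <- sample.int(n_regions)
    modules <- split(pool[seq_len(sum(sizes))],
                     rep(seq_along(sizes), sizes))
  }
  lab <- integer(n_regions)
  for (m in seq_along(modules)) lab[modules[[m]]] <- m
  vals <- matrix(0, n_regions, n_brains)
  # background regions: private cross-brain variation (each behaves as
  # an independent singleton), as in heterogeneously labelled brains
  for (r in seq_len(n_regions)) {
    if (lab[r] == 0) {
      vals[r, ] <- stats::runif(1, 0.5, 2) * stats::rlnorm(n_brains, 0, 1)
    }
  }
  for (m in seq_along(modules)) {
    loading <- stats::rlnorm(n_brains, 0, 1)
    loading <- loading / stats::sd(loading)   # unit signal sd
    for (r in modules[[m]]) {
      gain <- stats::runif(1, 0.5, 2)
      noise <- if (snr > 0) stats::rnorm(n_brains, 0, 1 / snr) else 0
      vals[r, ] <- pmax(gain * (loading + noise), 0)
    }
  }
  vals <- sweep(vals, 2, pmax(colSums(vals), .Machine$double.eps), "/")
  list(values = vals,
       region_ids = seq_len(n_regions),
       brain_ids = sprintf("brain%03d", seq_len(n_brains)),
       module_labels = lab)
}
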