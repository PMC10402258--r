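#' Morphology class parameters for the synthetic neuron generator
#'
#' The generator grows rooted binary trees by stochastic segment
#' extension: branch (segment) lengths are Gamma distributed with the
#' given mean and sd, a branch end bifurcates with per-micrometre rate
#' `bif_rate` (probability `1 - exp(-bif_rate * length)`), growth
#' direction follows the parent direction with von Mises jitter of
#' concentration `kappa`, and the maximal branch order is capped.
#' Axons are grown as a primary tract toward `target_xyz` with
#' `n_arbors` locally dense subtrees planted at waypoints along it.
#'
#' @param mean_branch_len,branch_len_sd branch length moments (um).
#' @param bif_rate per-um bifurcation rate of dendritic growth.
#' @param max_order maximal branch order of dendritic subtrees.
#' @param n_stems number of dendritic stems.
#' @param kappa von Mises concentration of direction jitter (larger =
#'   straighter branches).
#' @param step_um node spacing along growing segments.
#' @param radius node radius (um); soma radius is `soma_radius`.
#' @param soma_radius radius of the root node (um).
#' @param has_axon,tract_len,target_xyz axon tract controls: total
#'   tract length (um) and an optional attraction target (3-vector,
#'   um); `NULL` grows the tract in a random persistent direction.
#' @param n_arbors number of axonal arbors planted along the tract.
#' @param arbor_spread spatial extent of each planted arbor (um).
#' @param arbor_branch_len mean branch length inside arbors (um).
#' @param arbor_orders branch orders grown inside each arbor.
#' @param arbor_stems subtrees planted per arbor waypoint (dense
#'   tufts need several).
#' @param has_apical whether an apical-dendrite stem is grown.
#' @return a named list of class `morph_class_params`.
#' @export
morph_class_params <- function(mean_branch_len = 40, branch_len_sd = 15,
                               bif_rate = 0.02, max_order = 4,
                               n_stems = 3, kappa = 20, step_um = 5,
                               radius = 0.5, soma_radius = 6,
                               has_axon = TRUE, tract_len = 800,
                               target_xyz = NULL, n_arbors = 2,
                               arbor_spread = 80, arbor_branch_len = 25,
                               arbor_orders = 4, arbor_stems = 3,
                               has_apical = FALSE) {
  p <- as.list(environment())
  stopifnot(p$mean_branch_len > 0, p$branch_len_sd > 0, p$bif_rate >= 0)
  if (p$bif_rate * p$mean_branch_len > 20 && !is.finite(p$max_order)) {
    stop("growth cannot terminate: bifurcation rate ~1 with unbounded order")
  }
  class(p) <- "morph_class_params"
  p
}

#' von Mises perturbation of a 3-D unit direction
#' @noRd
jitter_dir <- function(dir, kappa) {
  # sample deflection angle from von Mises(0, kappa) folded to [0, pi],
  # azimuth uniform; rotate dir by that deflection
  th <- abs(rvonmises1(kappa))
  phi <- stats::runif(1, 0, 2 * pi)
  # orthonormal frame around dir
  a <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit(pracma_cross(dir, a))
  v <- pracma_cross(dir, u)
  unit(cos(th) * dir + sin(th) * (cos(phi) * u + sin(phi) * v))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Best-Fisher rejection sampler for von Mises(0, kappa)
#' @noRd
rvonmises1 <- function(kappa) {
  if (kappa < 1e-6) return(stats::runif(1, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  repeat {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      return(sign(u3 - 0.5) * acos(max(-1, min(1, f))))
    }
  }
}

#' Grow a synthetic neuron morphology
#'
#' Grows a rooted skeleton from `soma_xyz`: dendritic stems as local
#' stochastic binary trees, and (optionally) an axon consisting of a
#' persistent primary tract toward the class target with dense arbors
#' planted at waypoints. Planted ground truth (arbor waypoint centres,
#' arbor node id sets) is attached as the `ground_truth` element of the
#' tree metadata.
#'
#' @param params a [morph_class_params()].
#' @param soma_xyz soma position (um, 3-vector).
#' @param seed RNG seed.
#' @param metadata extra metadata fields for the tree.
#' @return a [neuron_tree()].
#' @export
grow_neuron <- function(params, soma_xyz = c(0, 0, 0), seed = 1,
                        metadata = list()) {
  stopifnot(inherits(params, "morph_class_params"))
  set.seed(seed)
  env <- new.env()
  env$max_nodes <- 6000L
  env$structure <- integer(env$max_nodes)
  env$xyz <- matrix(NA_real_, env$max_nodes, 3)
  env$radius <- numeric(env$max_nodes)
  env$parent <- integer(env$max_nodes)
  env$structure[1] <- 1L
  env$xyz[1, ] <- soma_xyz
  env$radius[1] <- params$soma_radius
  env$parent[1] <- -1L
  env$nxt <- 2L
  add_node <- function(parent_id, p, structure, radius) {
    id <- env$nxt
    if (id > env$max_nodes) return(id - 1L)
    env$nxt <- id + 1L
    env$structure[id] <- structure
    env$xyz[id, ] <- p
    env$radius[id] <- radius
    env$parent[id] <- parent_id
    id
  }
  grow_segment <- function(parent_id, p0, dir, len, structure, kappa,
                           attract = NULL, attract_w = 0) {
    nstep <- max(1L, ceiling(len / params$step_um))
    step <- len / nstep
    id <- parent_id; p <- p0
    for (i in seq_len(nstep)) {
      dir <- jitter_dir(dir, kappa)
      if (!is.null(attract) && attract_w > 0) {
        dir <- unit((1 - attract_w) * dir + attract_w * unit(attract - p))
      }
      p <- p + step * dir
      id <- add_node(id, p, structure, params$radius)
    }
    list(id = id, p = p, dir = dir)
  }
  grow_subtree <- function(parent_id, p0, dir, structure, order,
                           mean_len, sd_len, bif_rate, max_order,
                           kappa) {
    if (env$nxt > env$max_nodes) return(invisible(NULL))
    shape <- (mean_len / sd_len)^2
    len <- stats::rgamma(1, shape = shape, rate = shape / mean_len)
    seg <- grow_segment(parent_id, p0, dir, len, structure, kappa)
    p_bif <- 1 - exp(-bif_rate * len)
    if (order < max_order && stats::runif(1) < p_bif) {
      ax <- unit(stats::rnorm(3))
      half <- stats::runif(1, 20, 45) * pi / 180
      for (s in c(-1, 1)) {
        d2 <- unit(cos(half) * seg$dir +
                     sin(half) * s * unit(pracma_cross(seg$dir, ax)))
        grow_subtree(seg$id, seg$p, d2, structure, order + 1L,
                     mean_len, sd_len, bif_rate, max_order, kappa)
      }
    }
    invisible(NULL)
  }
  # dendrites
  for (s in seq_len(params$n_stems)) {
    dir <- unit(stats::rnorm(3))
    grow_subtree(1L, soma_xyz, dir, 3L, 1L, params$mean_branch_len,
                 params$branch_len_sd, params$bif_rate,
                 params$max_order, params$kappa)
  }
  if (params$has_apical) {
    grow_subtree(1L, soma_xyz, c(0, 1, 0), 4L, 1L,
                 params$mean_branch_len * 1.5, params$branch_len_sd,
                 params$bif_rate, params$max_order, params$kappa)
  }
  gt <- list(arbor_centers = NULL, arbor_nodes = list())
  if (params$has_axon) {
    dir0 <- if (!is.null(params$target_xyz))
      unit(params$target_xyz - soma_xyz) else unit(stats::rnorm(3))
    n_arb <- max(0L, params$n_arbors)
    # waypoint fractions along the tract where arbors are planted
    frac <- if (n_arb > 0) seq(1 / n_arb, 1, length.out = n_arb) else numeric()
    wp_len <- c(0, frac) * params$tract_len
    id <- 1L; p <- soma_xyz; dir <- dir0
    centers <- matrix(NA_real_, n_arb, 3)
    for (a in seq_len(max(1L, n_arb))) {
      seg_len <- if (n_arb > 0) wp_len[a + 1] - wp_len[a] else
        params$tract_len
      seg <- grow_segment(id, p, dir, seg_len, 2L, params$kappa * 4,
                          attract = params$target_xyz, attract_w = 0.3)
      id <- seg$id; p <- seg$p; dir <- seg$dir
      if (n_arb > 0) {
        centers[a, ] <- p
        first_arbor_row <- env$nxt
        for (st in seq_len(params$arbor_stems)) {
          grow_subtree(id, p, jitter_dir(dir, 2), 2L, 1L,
                       params$arbor_branch_len,
                       params$arbor_branch_len / 3,
                       3 / params$arbor_branch_len,  # dense branching
                       params$arbor_orders, params$kappa / 2)
        }
        gt$arbor_nodes[[a]] <- seq.int(first_arbor_row,
                                       env$nxt - 1L)
      }
    }
    gt$arbor_centers <- centers
  }
  n <- env$nxt - 1L
  nodes <- data.frame(id = seq_len(n), structure = env$structure[1:n],
                      x = env$xyz[1:n, 1], y = env$xyz[1:n, 2],
                      z = env$xyz[1:n, 3], radius = env$radius[1:n],
                      parent = env$parent[1:n])
  metadata$ground_truth <- gt
  metadata$params <- params
  neuron_tree(nodes, metadata = metadata)
}

#' Grow a population of synthetic neurons with planted classes
#'
#' @param class_list named list of [morph_class_params()].
#' @param n_per_class neurons per class.
#' @param soma_centers optional list of class soma-cluster centres
#'   (3-vectors, um); defaults to well-separated points.
#' @param soma_spread sd of soma scatter around its class centre (um).
#' @param seed RNG seed.
#' @return list with `trees`, `labels` (class index per neuron) and
#'   `soma` (n x 3 matrix).
#' @export
synth_population <- function(class_list, n_per_class = 15,
                             soma_centers = NULL, soma_spread = 100,
                             seed = 1) {
  set.seed(seed)
  k <- length(class_list)
  if (is.null(soma_centers)) {
    soma_centers <- lapply(seq_len(k), function(i)
      c(1000 * i, 500 * (i %% 2), 400))
  }
  trees <- list(); labels <- integer(0); soma <- NULL
  for (ci in seq_len(k)) {
    for (j in seq_len(n_per_class)) {
      s <- soma_centers[[ci]] + stats::rnorm(3, 0, soma_spread)
      tr <- grow_neuron(class_list[[ci]], s,
                        seed = seed * 1000 + ci * 100 + j,
                        metadata = list(class = ci,
                                        neuron_id = length(trees) + 1L))
      trees[[length(trees) + 1L]] <- tr
      labels <- c(labels, ci)
      soma <- rbind(soma, s)
    }
  }
  list(trees = trees, labels = labels, soma = soma)
}
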