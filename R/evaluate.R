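#' Soma-detector recovery on the synthetic soma field
#'
#' Renders the default soma field (30 spheres, SNR 8, 128^3 voxels),
#' runs detection and mean-shift refinement, and matches detections to
#' the planted centres within `tol` voxels.
#'
#' @param seed generator seed.
#' @param tol match tolerance, voxels (default 2).
#' @param ... overrides for [synth_soma_field()].
#' @return list: precision, recall, mean_loc_error, n_true,
#'   n_detected.
#' @export
eval_soma_detection <- function(seed = 1, tol = 2, ...) {
  sf <- synth_soma_field(seed = seed, ...)
  cand <- detect_somas(sf$block)
  ref <- refine_somas(cand, sf$block)
  det <- as.matrix(ref[, c("cx", "cy", "cz")])
  if (!nrow(det)) {
    return(list(precision = 0, recall = 0, mean_loc_error = NA,
                n_true = nrow(sf$centers), n_detected = 0))
  }
  d_true <- apply(sf$centers, 1, function(p)
    min(sqrt(rowSums(sweep(det, 2, p)^2))))
  d_det <- apply(det, 1, function(p)
    min(sqrt(rowSums(sweep(sf$centers, 2, p)^2))))
  list(precision = mean(d_det <= tol),
       recall = mean(d_true <= tol),
       mean_loc_error = mean(d_true[d_true <= tol]),
       n_true = nrow(sf$centers), n_detected = nrow(det))
}

#' Bouton-detector recovery on planted profiles
#'
#' Grows `n_neurons` axons, plants `n_boutons` profile bumps on each,
#' runs the detector, and matches detections to the planted positions
#' within `tol_um` (Euclidean).
#'
#' @param seed generator seed.
#' @param n_neurons,n_boutons problem size (defaults 20 and 20).
#' @param tol_um match tolerance, um (default 2).
#' @return list: f1, precision, recall, mean_pos_error, n_true,
#'   n_detected.
#' @export
eval_bouton_detection <- function(seed = 1, n_neurons = 20,
                                  n_boutons = 20, tol_um = 2) {
  tp <- 0; fp <- 0; fn <- 0; errs <- numeric(0)
  for (i in seq_len(n_neurons)) {
    p <- morph_class_params(n_stems = 0, n_arbors = 2,
                            tract_len = 1200)
    tr <- grow_neuron(p, seed = seed * 1000 + i)
    sp <- synth_bouton_profiles(tr, n_boutons = n_boutons,
                                seed = seed * 1000 + i)
    bs <- detect_boutons(tr, sp$profiles)
    gt <- sp$ground_truth
    det <- node_xyz(tr)[match(bs$boutons$node_id, tr$nodes$id), ,
                        drop = FALSE]
    if (nrow(det)) {
      gxyz <- as.matrix(gt[, c("x", "y", "z")])
      d_gt <- apply(gxyz, 1, function(q)
        min(sqrt(rowSums(sweep(det, 2, q)^2))))
      d_det <- apply(det, 1, function(q)
        min(sqrt(rowSums(sweep(gxyz, 2, q)^2))))
      tp <- tp + sum(d_gt <= tol_um)
      fn <- fn + sum(d_gt > tol_um)
      fp <- fp + sum(d_det > tol_um)
      errs <- c(errs, d_gt[d_gt <= tol_um])
    } else fn <- fn + nrow(gt)
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  list(f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0,
       precision = prec, recall = rec,
       mean_pos_error = mean(errs),
       n_true = tp + fn, n_detected = tp + fp)
}

#' Tight-module recovery on planted density matrices
#'
#' @param seeds generator seeds (one planted matrix each; default
#'   1:20).
#' @param snr signal-to-noise ratio (default 10).
#' @return list: ari (per seed), mean_ari.
#' @export
eval_module_recovery <- function(seeds = 1:20, snr = 10) {
  ari <- vapply(seeds, function(s) {
    dm <- make_density_matrix(snr = snr, seed = s)
    mc <- correlation_map(dm)
    tm <- tight_modules(initial_modules(mc),
                        target_correlated_sets(mc), mc)
    lab <- module_labels(tm, length(dm$region_ids))
    sel <- dm$module_labels > 0
    mclust::adjustedRandIndex(lab[sel], dm$module_labels[sel])
  }, 1)
  list(ari = ari, mean_ari = mean(ari))
}

#' Four distinct morphology classes used by the typing experiments
#' @noRd
typing_classes <- function() {
  list(
    local_dense = morph_class_params(mean_branch_len = 30,
                                     bif_rate = 0.03, n_stems = 4,
                                     n_arbors = 1, tract_len = 500),
    long_sparse = morph_class_params(mean_branch_len = 80,
                                     bif_rate = 0.01, n_stems = 2,
                                     n_arbors = 2, tract_len = 1500),
    multi_arbor = morph_class_params(mean_branch_len = 50,
                                     bif_rate = 0.05, n_stems = 3,
                                     n_arbors = 3, tract_len = 1000,
                                     arbor_spread = 150),
    wide_wandering = morph_class_params(mean_branch_len = 120,
                                        bif_rate = 0.008, n_stems = 5,
                                        n_arbors = 1, tract_len = 2500,
                                        kappa = 8))
}

#' Full-morphology typing recovery on four planted classes
#'
#' @param seeds seeds (default 1:10); each grows 60 neurons (15 per
#'   class) and clusters them at k = 4.
#' @return list: ari (per seed), mean_ari.
#' @export
eval_typing_recovery <- function(seeds = 1:10) {
  cls <- typing_classes()
  ari <- vapply(seeds, function(s) {
    pop <- synth_population(cls, n_per_class = 15, seed = s)
    ft <- feature_table(pop$trees, features47)
    S <- similarity_matrix(ft, pop$soma)
    lab <- spectral_cluster(S, 4, seed = s)
    mclust::adjustedRandIndex(lab, pop$labels)
  }, 1)
  list(ari = ari, mean_ari = mean(ari))
}

#' Planted-arbor-count recovery
#'
#' Grows `n_neurons` axons with planted arbor counts cycling through
#' `k_values` and scores [auto_arbor_k()] against the plant.
#'
#' @param seed base seed.
#' @param n_neurons number of neurons (default 20).
#' @param k_values planted counts (default 1:3).
#' @return list: hit_rate, hits, n.
#' @export
eval_arbor_recovery <- function(seed = 1, n_neurons = 20,
                                k_values = 1:3) {
  hits <- 0
  for (i in seq_len(n_neurons)) {
    k <- k_values[((i - 1) %% length(k_values)) + 1]
    p <- morph_class_params(n_stems = 0, n_arbors = k,
                            tract_len = 900 * max(k, 1),
                            arbor_spread = 60)
    tr <- grow_neuron(p, seed = seed * 100 + i)
    hits <- hits + (auto_arbor_k(tr) == k)
  }
  list(hit_rate = hits / n_neurons, hits = hits, n = n_neurons)
}

#' DS block-structure recovery on three planted super-classes
#'
#' Grows `n_per_class` neurons for the cortex-like, thalamus-like and
#' striatum-like regimes, assembles cross-scale vectors, and compares
#' the within-class diagonal of the DS matrix with the between-class
#' entries.
#'
#' @param seeds seeds (default 1:10).
#' @param n_per_class neurons per class (default 20).
#' @return list: gap (per seed), mean_gap, within, between.
#' @export
eval_ds_gap <- function(seeds = 1:10, n_per_class = 20) {
  cfg <- pipeline_config()
  classes <- lapply(cfg$classes, function(p)
    do.call(morph_class_params, p))
  within <- between <- numeric(0)
  gap <- vapply(seeds, function(s) {
    cfg$seed <- s
    pop <- synth_population(classes, n_per_class = n_per_class,
                            seed = s)
    cs <- assemble_cross_scale(pop, cfg)
    labels <- names(cfg$classes)[pop$labels]
    v <- ds_matrix(cs$vectors, labels)$values
    w <- mean(diag(v)); b <- mean(v[upper.tri(v)])
    within <<- c(within, w); between <<- c(between, b)
    w - b
  }, 1)
  list(gap = gap, mean_gap = mean(gap), within = within,
       between = between)
}
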