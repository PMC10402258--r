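#' Default pipeline configuration
#'
#' All numeric conventions of the analysis in one place: detector
#' constants, curation cutoffs, microenvironment radius, arbor and
#' hub parameters, bouton filters, module sizes, and the synthetic
#' study conditions (three planted super-classes emulating
#' cortex-like, thalamus-like and striatum-like parameter regimes).
#'
#' @param seed master seed.
#' @param n_per_class neurons per synthetic class (default 12).
#' @param stages character vector of stages to run (default all):
#'   "synth", "features", "microenv", "morphotype", "subneuronal",
#'   "boutons", "ds", "modules".
#' @return named list (class `pipeline_config`).
#' @export
pipeline_config <- function(seed = 1, n_per_class = 12,
                            stages = c("synth", "features", "microenv",
                                       "morphotype", "subneuronal",
                                       "boutons", "ds", "modules")) {
  cfg <- list(
    seed = seed, n_per_class = n_per_class, stages = stages,
    microenv = list(D = 249, k = 5),
    curation = list(min_angle = 80, large_angle = 150,
                    radius_ratio = 1.5, winding = 3, min_nodes = 20,
                    dup_radius = 15),
    arbors = list(k = 2, density_radius = 20, distal_um = 750),
    hubs = list(spacing = 80, sphere = 500, min_neighbors = 70),
    boutons = list(fragment = 20, min_intensity = 120,
                   radius_ratio = 1.5, dedupe = 5),
    modules = list(cutoff = 0.8, size_range = c(3, 15)),
    profile_bins = 30,
    classes = list(
      cortex_like = list(mean_branch_len = 35, bif_rate = 0.035,
                         n_stems = 4, n_arbors = 2, tract_len = 1600,
                         kappa = 18, has_apical = TRUE),
      thalamus_like = list(mean_branch_len = 60, bif_rate = 0.015,
                           n_stems = 3, n_arbors = 2, tract_len = 2600,
                           kappa = 25, has_apical = FALSE),
      striatum_like = list(mean_branch_len = 45, bif_rate = 0.025,
                           n_stems = 5, n_arbors = 2, tract_len = 1000,
                           kappa = 10, has_apical = FALSE)))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Assemble cross-scale vectors for a synthetic population
#'
#' Runs the per-neuron stages (local-dendrite features and
#' microenvironment fusion, whole-morphology features, arbor
#' decomposition at two axonal arbors, synthetic bouton profiles and
#' detection, primary tract) and concatenates the five blocks.
#'
#' @param pop a [synth_population()] result.
#' @param cfg a [pipeline_config()].
#' @return list: `vectors` (neurons x 84, z-scored per dimension),
#'   `raw` (pre-standardisation), `bouton_sets`, `tracts`,
#'   `arbor_stats` (neurons x 8 summary), `features24`, `features47`.
#' @export
assemble_cross_scale <- function(pop, cfg = pipeline_config()) {
  trees <- pop$trees
  n <- length(trees)
  lm18 <- function(tree) {
    lmeasure_features(tree)[setdiff(lmeasure_names,
      c("Nodes", "SomaSurface", "AverageDiameter", "Surface"))]
  }
  dendrite_tree <- function(tr) {
    nd <- tr$nodes
    keep <- nd$id[nd$structure %in% c(1L, 3L, 4L)]
    if (length(keep) < 3) tr else subset_tree(tr, keep)
  }
  f24 <- t(vapply(trees, function(tr) features24(dendrite_tree(tr)),
                  numeric(24)))
  me <- microenvironment_table(f24, pop$soma, D = cfg$microenv$D,
                               k = cfg$microenv$k)
  micro18 <- me$fused[, seq_len(18), drop = FALSE]
  full18 <- t(vapply(trees, lm18, numeric(18)))
  f47 <- t(vapply(trees, features47, numeric(47)))
  arbor_block <- matrix(0, n, 16)
  arbor_stats <- matrix(0, n, 8)
  bouton_sets <- vector("list", n)
  tracts <- vector("list", n)
  bouton_block <- matrix(0, n, 6)
  motif_block <- matrix(0, n, 26)
  for (i in seq_len(n)) {
    tr <- trees[[i]]
    ar <- decompose_arbors(tr, k = cfg$arbors$k, seed = cfg$seed)
    art <- attr(ar, "tree")
    af <- lapply(ar, arbor_features, tree = art,
                 density_radius = cfg$arbors$density_radius,
                 distal_threshold = cfg$arbors$distal_um)
    kinds <- vapply(ar, function(a) a$kind, "")
    vec4 <- function(a) if (is.null(a)) rep(0, 4) else
      c(a$n_branch, a$volume, a$max_density, a$dist2soma)
    apical <- af[kinds == "apical"]
    basal <- af[kinds == "basal"]
    axonal <- af[kinds == "axonal"]
    if (length(axonal) > 1) {
      axonal <- axonal[order(vapply(axonal, function(a) a$dist2soma,
                                    1))]
    }
    arbor_block[i, ] <- c(
      vec4(if (length(apical)) apical[[1]] else NULL),
      vec4(if (length(basal)) basal[[1]] else NULL),
      vec4(if (length(axonal) >= 1) axonal[[1]] else NULL),
      vec4(if (length(axonal) >= 2) axonal[[2]] else NULL))
    ax4 <- t(vapply(axonal, function(a)
      c(a$n_branch, a$volume, a$max_density, a$dist2soma),
      numeric(4)))
    arbor_stats[i, ] <- c(colMeans(ax4),
                          if (nrow(ax4) > 1) apply(ax4, 2, stats::sd)
                          else rep(0, 4))
    sp <- synth_bouton_profiles(tr, n_boutons = 20,
                                seed = cfg$seed * 10000 + i)
    bs <- classify_teb_epb(detect_boutons(tr, sp$profiles,
      fragment_um = cfg$boutons$fragment,
      min_intensity = cfg$boutons$min_intensity,
      radius_ratio = cfg$boutons$radius_ratio,
      dedupe_um = cfg$boutons$dedupe))
    bouton_sets[[i]] <- bs
    b <- bs$boutons
    ibd <- inter_bouton_distances(bs)
    bouton_block[i, ] <- c(
      nrow(b),
      if (nrow(b)) mean(b$type == "TEB") else 0,
      if (length(ibd)) mean(ibd) else 0,
      if (length(ibd) > 1) stats::sd(ibd) else 0,
      if (nrow(b)) mean(b$path_dist) else 0,
      if (nrow(b)) max(b$path_dist) else 0)
    pt <- primary_tract(tr)
    tracts[[i]] <- pt
    chord <- sqrt(sum((pt$xyz[nrow(pt$xyz), ] - pt$xyz[1, ])^2))
    motif_block[i, 1:4] <- c(pt$length, chord,
                             if (chord > 0) pt$length / chord else 1,
                             sqrt(sum(pt$terminal^2)))
  }
  raw <- t(vapply(seq_len(n), function(i) {
    cross_scale_vector(micro18[i, ], full18[i, ], arbor_block[i, ],
                       bouton_block[i, ], motif_block[i, ])
  }, numeric(84)))
  list(vectors = cross_scale_table(raw), raw = raw,
       bouton_sets = bouton_sets, tracts = tracts,
       arbor_stats = arbor_stats, features24 = f24, features47 = f47,
       microenvironments = me)
}

#' Run the end-to-end synthetic pipeline
#'
#' Generates the synthetic study data, runs every enabled analysis
#' stage, and writes CSV/JSON outputs plus a manifest into `out_dir`.
#' The run is deterministic for a fixed config seed.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return (invisibly) a list of in-memory stage results.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = tempfile()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  on <- function(s) s %in% cfg$stages
  res <- list(config = cfg)
  t_start <- Sys.time()
  log <- file.path(out_dir, "log.jsonl")
  note <- function(stage, ...) {
    cat(jsonlite::toJSON(list(stage = stage,
                              elapsed_s = round(as.numeric(
                                Sys.time() - t_start), 2), ...),
                         auto_unbox = TRUE), "\n",
        file = log, append = TRUE)
  }
  if (!on("synth")) stop("pipeline requires the synth stage")
  classes <- lapply(cfg$classes, function(p)
    do.call(morph_class_params, p))
  pop <- synth_population(classes, n_per_class = cfg$n_per_class,
                          seed = cfg$seed)
  res$pop <- pop
  note("synth", neurons = length(pop$trees))
  if (on("features") || on("ds") || on("microenv") || on("morphotype")) {
    if (!on("features")) {
      stop("stage 'ds' needs stage 'features' (cross-scale blocks missing)")
    }
    cs <- assemble_cross_scale(pop, cfg)
    res$cross_scale <- cs
    utils::write.csv(data.frame(neuron = seq_len(nrow(cs$raw)),
                                class = pop$labels, cs$raw),
                     file.path(out_dir, "cross_scale_features.csv"),
                     row.names = FALSE)
    note("features", dims = ncol(cs$raw))
  }
  if (on("morphotype")) {
    S <- similarity_matrix(res$cross_scale$features47, pop$soma)
    lab <- spectral_cluster(S, k = length(cfg$classes), seed = cfg$seed)
    res$morphotype <- lab
    utils::write.csv(data.frame(neuron = seq_along(lab),
                                cluster = lab),
                     file.path(out_dir, "morphotype_clusters.csv"),
                     row.names = FALSE)
    note("morphotype", k = length(unique(lab)))
  }
  if (on("ds")) {
    if (is.null(res$cross_scale)) {
      stop("stage 'ds' needs stage 'features' (cross-scale blocks missing)")
    }
    if (!on("boutons")) {
      stop("stage 'ds' needs stage 'boutons' (bouton block missing)")
    }
    labels <- names(cfg$classes)[pop$labels]
    ds <- ds_matrix(res$cross_scale$vectors, labels)
    res$ds <- ds
    sds <- per_scale_ds(res$cross_scale$vectors, labels)
    res$scale_ds <- sds
    res$scale_dist <- scale_distances(sds)
    res$moments <- moment_summary(sds)
    utils::write.csv(ds$values, file.path(out_dir, "ds_matrix.csv"))
    utils::write.csv(res$scale_dist,
                     file.path(out_dir, "scale_distances.csv"))
    utils::write.csv(res$moments, file.path(out_dir, "moments.csv"),
                     row.names = FALSE)
    note("ds")
  }
  if (on("modules")) {
    dm <- make_density_matrix(seed = cfg$seed)
    mc <- correlation_map(dm)
    tm <- tight_modules(initial_modules(mc,
                                        cfg$modules$size_range),
                        target_correlated_sets(mc, cfg$modules$cutoff),
                        mc)
    res$modules <- tm
    writeLines(jsonlite::toJSON(list(
      stage = tm$stage,
      modules = tm$modules,
      consistency = round(tm$consistency, 4)), auto_unbox = TRUE),
      file.path(out_dir, "modules.json"))
    note("modules", n = length(tm$modules))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("morphoscale")),
    seed = cfg$seed,
    stages = cfg$stages,
    config_hash = config_hash(cfg),
    outputs = list.files(out_dir))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                              pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(res)
}

#' deterministic hash of the resolved configuration
#' @noRd
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg[setdiff(names(cfg), "stages")],
                        auto_unbox = TRUE, digits = NA)
  # rolling polynomial hash over the serialised config
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", h)
}
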