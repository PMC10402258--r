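#' 47-dimensional full-morphology feature vector
#'
#' Seven global features (Stems, Branches, OverallWidth, OverallHeight,
#' OverallDepth, OverallVolume — the bounding-box volume — and Length)
#' plus min, max, mean and standard deviation of the ten per-branch /
#' per-bifurcation features of [local_branch_features()]. Trees
#' without bifurcations get zeros (with attribute `no_bifurcations`)
#' for the bifurcation-based statistics.
#'
#' @param tree a [neuron_tree()].
#' @return named numeric vector of length 47.
#' @export
features47 <- function(tree) {
  lf <- local_branch_features(tree)
  lm <- lmeasure_features(tree, lf = lf)
  glob <- c(lm[c("Stems", "Branches", "OverallWidth", "OverallHeight",
                 "OverallDepth")],
            OverallVolume = unname(lm["OverallWidth"] *
                                     lm["OverallHeight"] *
                                     lm["OverallDepth"]),
            Length = unname(lm["Length"]))
  stat4 <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(min = 0, max = 0, mean = 0, sd = 0))
    c(min = min(x), max = max(x), mean = mean(x),
      sd = if (length(x) > 1) stats::sd(x) else 0)
  }
  feats <- list(
    br_length = lf$branches$br_length,
    br_order = lf$branches$br_order,
    br_contraction = lf$branches$br_contraction,
    bif_EucDist2soma = lf$bifurcations$bif_EucDist2soma,
    bif_PathDist2soma = lf$bifurcations$bif_PathDist2soma,
    asymmetry = lf$bifurcations$asymmetry,
    ampl_local = lf$bifurcations$ampl_local,
    ampl_remote = lf$bifurcations$ampl_remote,
    tilt_local = lf$bifurcations$tilt_local,
    tilt_remote = lf$bifurcations$tilt_remote)
  out <- c(glob, unlist(lapply(names(feats), function(nm)
    stats::setNames(stat4(feats[[nm]]),
                    paste0(nm, "_", c("min", "max", "mean", "sd"))))))
  if (!nrow(lf$bifurcations)) attr(out, "no_bifurcations") <- TRUE
  out
}

#' Spatially tuned similarity matrix of a neuron population
#'
#' `S_ij = cos(z_i, z_j) * exp(-d_ij / d_norm)`: the cosine similarity
#' of z-scored feature vectors damped by the exponential of the
#' normalised soma-to-soma distance, so spatially distant neurons with
#' matching features score lower than close ones.
#'
#' @param features neurons x features matrix (raw scale).
#' @param soma neurons x 3 soma positions (um).
#' @param d_norm distance normalisation (default: the maximum pairwise
#'   soma distance in the data set).
#' @return symmetric matrix with unit diagonal.
#' @export
similarity_matrix <- function(features, soma, d_norm = NULL) {
  z <- scale(features)
  z[is.na(z)] <- 0
  nrm <- sqrt(rowSums(z^2))
  if (any(nrm == 0)) stop("zero-norm feature vector after z-scoring")
  zn <- z / nrm
  cossim <- tcrossprod(zn)
  d <- as.matrix(stats::dist(soma))
  if (is.null(d_norm)) d_norm <- max(d)
  if (d_norm <= 0) d_norm <- 1
  s <- cossim * exp(-d / d_norm)
  diag(s) <- 1
  (s + t(s)) / 2
}

#' Spectral clustering of a similarity matrix
#'
#' Negative affinities are clamped to zero, the symmetric normalised
#' Laplacian embedding of the top `k` eigenvectors is row-normalised,
#' and k-means (fixed seed) assigns the labels. Disconnected affinity
#' graphs are clustered per component with a warning.
#'
#' @param S symmetric similarity matrix.
#' @param k number of clusters (>= 2).
#' @param seed RNG seed for k-means.
#' @return integer label vector (1..k).
#' @export
spectral_cluster <- function(S, k, seed = 1) {
  stopifnot(k >= 2, nrow(S) == ncol(S))
  W <- pmax(S, 0)
  diag(W) <- 0
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  comp <- igraph::components(g)
  if (comp$no > 1) {
    warning("similarity graph has ", comp$no,
            " components; clustering components separately")
    labels <- integer(nrow(W))
    offset <- 0L
    for (ci in seq_len(comp$no)) {
      idx <- which(comp$membership == ci)
      kk <- min(length(idx), max(1L, round(k * length(idx) / nrow(W))))
      if (length(idx) == 1 || kk == 1) {
        labels[idx] <- offset + 1L
        offset <- offset + 1L
      } else {
        labels[idx] <- offset + spectral_embed_kmeans(
          W[idx, idx], kk, seed)
        offset <- offset + kk
      }
    }
    return(labels)
  }
  spectral_embed_kmeans(W, k, seed)
}

spectral_embed_kmeans <- function(W, k, seed) {
  dg <- pmax(rowSums(W), .Machine$double.eps)
  Dm <- 1 / sqrt(dg)
  L <- diag(nrow(W)) - (Dm * W) %*% diag(Dm)
  eig <- eigen((L + t(L)) / 2, symmetric = TRUE)
  n <- nrow(W)
  U <- eig$vectors[, (n - k + 1):n, drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  U <- U / pmax(rn, .Machine$double.eps)
  set.seed(seed)
  stats::kmeans(U, centers = k, nstart = 20, iter.max = 50)$cluster
}

#' Eigengap diagnostic for choosing the number of clusters
#'
#' @param S similarity matrix.
#' @param k_max largest k considered.
#' @return list: `eigenvalues` (smallest `k_max + 1` of the normalised
#'   Laplacian) and `k_best` (position of the largest gap).
#' @export
eigengap <- function(S, k_max = 6) {
  W <- pmax(S, 0)
  diag(W) <- 0
  dg <- pmax(rowSums(W), .Machine$double.eps)
  Dm <- 1 / sqrt(dg)
  L <- diag(nrow(W)) - (Dm * W) %*% diag(Dm)
  ev <- sort(eigen((L + t(L)) / 2, symmetric = TRUE,
                   only.values = TRUE)$values)
  m <- min(k_max + 1, length(ev))
  gaps <- diff(ev[seq_len(m)])
  list(eigenvalues = ev[seq_len(m)], k_best = which.max(gaps))
}

#' Mean silhouette of soma positions for every cluster pair
#'
#' For each pair of clusters, the mean silhouette coefficient
#' `(b - a) / max(a, b)` of the member soma positions (singleton
#' clusters contribute 0 by convention).
#'
#' @param positions n x d coordinate matrix.
#' @param labels cluster labels.
#' @return matrix of pairwise mean silhouettes (NA diagonal).
#' @export
silhouette_separation <- function(positions, labels) {
  labs <- sort(unique(labels))
  stopifnot(length(labs) >= 2)
  out <- matrix(NA_real_, length(labs), length(labs),
                dimnames = list(labs, labs))
  for (a in seq_along(labs)) for (b in seq_along(labs)) {
    if (b <= a) next
    idx <- labels %in% labs[c(a, b)]
    ll <- as.integer(factor(labels[idx]))
    if (min(table(ll)) < 2) { out[a, b] <- out[b, a] <- 0; next }
    sil <- cluster::silhouette(ll,
                               stats::dist(positions[idx, , drop = FALSE]))
    out[a, b] <- out[b, a] <- mean(sil[, "sil_width"])
  }
  out
}

#' Top discriminating features for every cluster pair
#'
#' Runs [mrmr_select()] independently for each unordered cluster pair
#' and summarises, per cluster, how often each feature lands in a
#' top-`k` list of its pairs (the hit rate).
#'
#' @param features neurons x features matrix.
#' @param labels cluster labels.
#' @param k features per pair (default 3).
#' @return list: `pairs` (data.frame cluster_a, cluster_b, and the
#'   selected names), `hit_rate` (clusters x features matrix in
#'   [0, 1]).
#' @export
pairwise_discriminators <- function(features, labels, k = 3) {
  labs <- sort(unique(labels))
  stopifnot(length(labs) >= 2)
  pairs <- list()
  hits <- matrix(0, length(labs), ncol(features),
                 dimnames = list(labs, colnames(features)))
  npairs <- stats::setNames(numeric(length(labs)), labs)
  for (a in seq_along(labs)) for (b in seq_along(labs)) {
    if (b <= a) next
    idx <- labels %in% labs[c(a, b)]
    sel <- suppressWarnings(
      mrmr_select(features[idx, , drop = FALSE], labels[idx], k = k))
    pairs[[length(pairs) + 1L]] <- data.frame(
      cluster_a = labs[a], cluster_b = labs[b],
      t(stats::setNames(sel, paste0("top", seq_along(sel)))))
    for (cl in c(labs[a], labs[b])) {
      hits[as.character(cl), sel] <-
        hits[as.character(cl), sel] + 1
      npairs[as.character(cl)] <- npairs[as.character(cl)] + 1
    }
  }
  list(pairs = do.call(rbind, pairs),
       hit_rate = hits / pmax(npairs, 1))
}

#' Branch counts against bifurcation-to-soma distance
#'
#' Bins every bifurcation by its Euclidean distance to the soma
#' (default 30 um bins) and reports, per cluster, the mean and
#' standard deviation across member neurons of the per-neuron
#' bifurcation counts in each bin.
#'
#' @param trees list of [neuron_tree()].
#' @param labels cluster label per tree.
#' @param bin bin width, um (default 30).
#' @return list of two matrices (`mean`, `sd`), clusters x bins.
#' @export
branch_distance_profile <- function(trees, labels, bin = 30) {
  stopifnot(bin > 0)
  per_tree <- lapply(trees, function(tr) {
    lf <- local_branch_features(tr)
    lf$bifurcations$bif_EucDist2soma
  })
  maxd <- max(c(0, unlist(per_tree)))
  nb <- max(1L, ceiling((maxd + 1e-9) / bin))
  counts <- do.call(rbind, lapply(per_tree, function(d) {
    tabulate(pmin(floor(d / bin) + 1L, nb), nbins = nb)
  }))
  labs <- sort(unique(labels))
  mk <- function(fn) {
    vals <- vapply(labs, function(l) {
      apply(counts[labels == l, , drop = FALSE], 2, fn)
    }, numeric(nb))
    m <- t(matrix(vals, nrow = nb))
    dimnames(m) <- list(labs, paste0("[", (seq_len(nb) - 1) * bin, ",",
                                     seq_len(nb) * bin, ")"))
    m
  }
  list(mean = mk(mean),
       sd = mk(function(x) if (length(x) > 1) stats::sd(x) else 0))
}
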