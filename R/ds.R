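cross_scale_blocks <- function() {
  list(microenviron = 18L, fullMorpho = 18L, arbor = 16L, bouton = 6L,
       motif = 26L)
}

#' Cross-scale feature vector of a neuron
#'
#' Concatenates standardised feature blocks from five morphometry
#' scales: microenvironment (18 morphometric features of the fused
#' local dendrite), full morphology (the same 18 features of the whole
#' neuron), arbor (apical, basal and two axonal arbors x n_branch,
#' volume, max_density, dist2soma; absent apical blocks are zeros),
#' bouton (the six radar summary features) and motif (primary-tract
#' descriptors, zero-padded to the configured width). Each block is
#' z-scored across the population by [cross_scale_table()].
#'
#' @param micro 18-vector of microenvironment features.
#' @param fullmorpho 18-vector of whole-neuron features.
#' @param arbor 16-vector of arbor features (zeros where absent).
#' @param bouton 6-vector of bouton summaries.
#' @param motif tract feature vector (padded/truncated to the motif
#'   block width).
#' @return named numeric vector of total dimension 84.
#' @export
cross_scale_vector <- function(micro, fullmorpho, arbor, bouton,
                               motif) {
  bl <- cross_scale_blocks()
  fit <- function(x, n, nm) {
    x <- as.numeric(x)
    if (length(x) > n) x <- x[seq_len(n)]
    if (length(x) < n) x <- c(x, rep(0, n - length(x)))
    stats::setNames(x, paste0(nm, "_", seq_len(n)))
  }
  if (length(micro) != bl$microenviron) {
    stop("microenvironment block must have ", bl$microenviron,
         " features")
  }
  if (length(fullmorpho) != bl$fullMorpho) {
    stop("full-morphology block must have ", bl$fullMorpho, " features")
  }
  c(fit(micro, bl$microenviron, "microenviron"),
    fit(fullmorpho, bl$fullMorpho, "fullMorpho"),
    fit(arbor, bl$arbor, "arbor"),
    fit(bouton, bl$bouton, "bouton"),
    fit(motif, bl$motif, "motif"))
}

#' Population table of cross-scale vectors, block-standardised
#'
#' @param vectors neurons x 84 matrix (rows from
#'   [cross_scale_vector()]).
#' @return matrix of the same shape with every dimension z-scored over
#'   the population (constant dimensions stay 0).
#' @export
cross_scale_table <- function(vectors) {
  z <- scale(vectors)
  z[is.na(z)] <- 0
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z
}

#' block index helper: which columns belong to each scale
#' @noRd
block_columns <- function() {
  bl <- cross_scale_blocks()
  ends <- cumsum(unlist(bl))
  starts <- c(1, utils::head(ends, -1) + 1)
  stats::setNames(Map(seq, starts, ends), names(bl))
}

#' Diversity-and-Stereotypy (DS) matrix
#'
#' Every entry is the average Pearson correlation coefficient between
#' the cross-scale vectors of all neuron pairs of the two types
#' (dimensions acting as observations); diagonal entries average the
#' intra-type pairs with self-pairs excluded. Pairs involving a
#' zero-variance vector are excluded from the averages; singleton
#' types have an undefined diagonal (NA).
#'
#' @param vectors neurons x dims matrix (use [cross_scale_table()]).
#' @param labels type label per neuron.
#' @return object of class `ds_matrix`: `values` (types x types),
#'   `n_excluded` (pairs dropped for zero variance).
#' @export
ds_matrix <- function(vectors, labels) {
  labs <- sort(unique(labels))
  sds <- apply(vectors, 1, stats::sd)
  valid <- sds > 0
  cc <- matrix(NA_real_, nrow(vectors), nrow(vectors))
  cc[valid, valid] <- suppressWarnings(stats::cor(t(vectors[valid, ,
                                                            drop = FALSE])))
  vals <- matrix(NA_real_, length(labs), length(labs),
                 dimnames = list(labs, labs))
  excluded <- 0L
  for (a in seq_along(labs)) for (b in seq_along(labs)) {
    if (b < a) next
    ia <- which(labels == labs[a]); ib <- which(labels == labs[b])
    sub <- cc[ia, ib, drop = FALSE]
    if (a == b) {
      if (length(ia) < 2) { vals[a, a] <- NA; next }
      sub <- sub[upper.tri(sub)]
    }
    excluded <- excluded + sum(is.na(sub))
    m <- mean(sub, na.rm = TRUE)
    vals[a, b] <- vals[b, a] <- if (is.nan(m)) NA else m
  }
  structure(list(values = vals, n_excluded = excluded),
            class = "ds_matrix")
}

#' @export
print.ds_matrix <- function(x, ...) {
  cat("DS matrix:\n")
  print(round(x$values, 3))
  invisible(x)
}

#' Per-scale DS matrices and intra-type correlation distributions
#'
#' @param vectors neurons x 84 matrix (block layout of
#'   [cross_scale_vector()]).
#' @param labels type labels.
#' @return list per scale: `ds` (ds_matrix), `intra` (named list of
#'   per-type intra-pair correlation vectors).
#' @export
per_scale_ds <- function(vectors, labels) {
  cols <- block_columns()
  lapply(cols, function(cl) {
    v <- vectors[, cl, drop = FALSE]
    ds <- ds_matrix(v, labels)
    sds <- apply(v, 1, stats::sd)
    labs <- sort(unique(labels))
    intra <- lapply(labs, function(l) {
      idx <- which(labels == l & sds > 0)
      if (length(idx) < 2) return(numeric(0))
      cc <- suppressWarnings(stats::cor(t(v[idx, , drop = FALSE])))
      cc[upper.tri(cc)]
    })
    names(intra) <- labs
    list(ds = ds, intra = intra)
  })
}

#' Distances between morphometry scales
#'
#' One minus the Pearson correlation of the vectorised upper triangles
#' (including the diagonal) of the per-scale DS matrices.
#'
#' @param scale_ds list from [per_scale_ds()] (or a list of
#'   `ds_matrix`).
#' @return symmetric scales x scales distance matrix, zero diagonal.
#' @export
scale_distances <- function(scale_ds) {
  mats <- lapply(scale_ds, function(s)
    if (inherits(s, "ds_matrix")) s$values else s$ds$values)
  stopifnot(length(mats) >= 2)
  vecs <- lapply(mats, function(m) m[upper.tri(m, diag = TRUE)])
  n <- length(vecs)
  out <- matrix(0, n, n, dimnames = list(names(mats), names(mats)))
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (b <= a) next
    ok <- !is.na(vecs[[a]]) & !is.na(vecs[[b]])
    d <- 1 - stats::cor(vecs[[a]][ok], vecs[[b]][ok])
    out[a, b] <- out[b, a] <- d
  }
  out
}

#' Four-moment summary of intra-type correlation distributions
#'
#' Mean, standard deviation, skewness and excess kurtosis per type and
#' scale; distributions with fewer than 4 values get NA for the
#' higher moments (flagged unstable), constant distributions get sd 0
#' and NA beyond.
#'
#' @param scale_ds list from [per_scale_ds()].
#' @return data.frame: scale, type, n, mean, sd, skewness, kurtosis.
#' @export
moment_summary <- function(scale_ds) {
  rows <- list()
  for (sc in names(scale_ds)) {
    intra <- scale_ds[[sc]]$intra
    for (ty in names(intra)) {
      x <- intra[[ty]]
      n <- length(x)
      m <- if (n) mean(x) else NA
      s <- if (n > 1) stats::sd(x) else NA
      sk <- ku <- NA_real_
      if (n >= 4 && isTRUE(s > 0)) {
        sk <- e1071::skewness(x)
        ku <- e1071::kurtosis(x)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        scale = sc, type = ty, n = n, mean = m, sd = s,
        skewness = sk, kurtosis = ku)
    }
  }
  do.call(rbind, rows)
}

#' Pairwise feature correlation against spatial distance
#'
#' For every neuron pair: the Pearson correlation of their cross-scale
#' vectors, the soma-to-soma Euclidean distance, and (optionally) the
#' axon-to-axon distance (Euclidean distance of projection vectors).
#' The relationship is binned and a linear model is fitted to the
#' pairs inside `max_range`.
#'
#' @param vectors neurons x dims matrix.
#' @param soma neurons x 3 soma positions (um).
#' @param projections optional neurons x regions projection matrix for
#'   the axon-axon distance.
#' @param max_range linear fit window on the soma distance, um.
#' @param bins number of distance bins (default 10).
#' @return list: `pairs` (data.frame), `binned` (per-bin mean and sd),
#'   `fit` (slope, intercept, r of the within-range fit), and the
#'   same for the axon-axon distance when projections are given.
#' @export
distance_vs_correlation <- function(vectors, soma, projections = NULL,
                                    max_range = 4000, bins = 10) {
  n <- nrow(vectors)
  cc <- suppressWarnings(stats::cor(t(vectors)))
  d <- as.matrix(stats::dist(soma))
  ut <- upper.tri(d)
  pairs <- data.frame(dist = d[ut], cor = cc[ut])
  if (!is.null(projections)) {
    da <- as.matrix(stats::dist(projections))
    pairs$axon_dist <- da[ut]
  }
  pairs <- pairs[!is.na(pairs$cor), ]
  bin_of <- cut(pairs$dist, bins)
  binned <- data.frame(
    mid = tapply(pairs$dist, bin_of, mean),
    mean = tapply(pairs$cor, bin_of, mean),
    sd = tapply(pairs$cor, bin_of, stats::sd))
  sel <- pairs$dist <= max_range
  fit <- if (sum(sel) >= 3) {
    lm <- stats::lm(cor ~ dist, data = pairs[sel, ])
    list(slope = unname(stats::coef(lm)[2]),
         intercept = unname(stats::coef(lm)[1]),
         r = suppressWarnings(stats::cor(pairs$dist[sel],
                                         pairs$cor[sel])))
  } else NULL
  out <- list(pairs = pairs, binned = binned, fit = fit)
  if (!is.null(projections)) {
    sel2 <- pairs$axon_dist <= stats::quantile(pairs$axon_dist, 0.5)
    out$axon_fit <- if (sum(sel2) >= 3) {
      lm2 <- stats::lm(cor ~ axon_dist, data = pairs[sel2, ])
      list(slope = unname(stats::coef(lm2)[2]),
           r = suppressWarnings(stats::cor(pairs$axon_dist[sel2],
                                           pairs$cor[sel2])))
    } else NULL
  }
  out
}
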