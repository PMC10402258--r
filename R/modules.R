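#' Pairwise regional correlation map
#'
#' Spearman correlation between the cross-brain density vectors of
#' every region pair. Constant rows have no defined rank correlation
#' and are set to 0 with a warning.
#'
#' @param md density matrix (regions x brains) or the list returned by
#'   [make_density_matrix()].
#' @return symmetric regions x regions correlation matrix (diagonal 1).
#' @export
correlation_map <- function(md) {
  v <- if (is.list(md)) md$values else md
  if (ncol(v) < 3) stop("need at least 3 brains")
  const <- apply(v, 1, function(r) stats::sd(r) == 0)
  mc <- suppressWarnings(stats::cor(t(v), method = "spearman"))
  if (any(const)) {
    warning(sum(const), " constant row(s): correlations set to 0")
    mc[const, ] <- 0
    mc[, const] <- 0
  }
  diag(mc) <- 1
  mc
}

#' Intra-compound-area correlation distributions
#'
#' For each compound area, the correlation coefficients of all pairs
#' of member regions (empty for single-region areas).
#'
#' @param mc correlation map from [correlation_map()].
#' @param region_table data.frame with `region_id` and `area_id`
#'   (e.g. from [make_toy_atlas()]).
#' @return named list (one numeric vector per area).
#' @export
intra_area_consistency <- function(mc, region_table) {
  areas <- split(region_table$region_id, region_table$area_id)
  lapply(areas, function(rs) {
    i <- match(rs, region_table$region_id)
    if (length(i) < 2) return(numeric(0))
    m <- mc[i, i, drop = FALSE]
    m[upper.tri(m)]
  })
}

#' Target-correlated region sets
#'
#' For every region, the set of other regions whose cross-brain
#' density correlates with it at or above `cutoff`; nonempty sets are
#' labelled intra-CA when all members (including the target) share the
#' target's compound area.
#'
#' @param mc correlation map.
#' @param cutoff Spearman threshold (default 0.8; at-or-above keeps).
#' @param region_table optional region/area table for the CA label.
#' @return list per target region: `regions` (integer indices),
#'   `label` ("intra-CA" / "cross-CA" / NA for empty sets).
#' @export
target_correlated_sets <- function(mc, cutoff = 0.8,
                                   region_table = NULL) {
  stopifnot(cutoff > 0, cutoff <= 1)
  n <- nrow(mc)
  out <- vector("list", n)
  for (t in seq_len(n)) {
    hits <- setdiff(which(mc[t, ] >= cutoff), t)
    lab <- NA_character_
    if (length(hits) && !is.null(region_table)) {
      a <- region_table$area_id[match(c(t, hits),
                                      region_table$region_id)]
      lab <- if (length(unique(a)) == 1) "intra-CA" else "cross-CA"
    }
    out[[t]] <- list(regions = hits, label = lab)
  }
  out
}

#' Initial co-occurrence modules from the dendrogram
#'
#' Hierarchical (average-linkage) clustering of regions on distance
#' `1 - rho` is cut by walking the dendrogram from the root: clusters
#' whose size falls within `size_range` become modules, larger
#' clusters are recursed into their children, and undersized clusters
#' are merged into the most-correlated module that still has room
#' (deterministic first-fit on ties). The result is a disjoint,
#' exhaustive cover of all regions.
#'
#' Clusters are taken from the dendrogram bottom-up: merge heights are
#' split into a "tight" and a "loose" mode (1-D 2-means; all merges
#' count as tight when the heights are practically constant) and a
#' module is a maximal tight cluster of admissible size. Regions left
#' over (loose singletons) are attached to the most-correlated module
#' that still has room, so the result covers every region.
#'
#' @param mc correlation map.
#' @param size_range admissible module sizes (default c(3, 15)).
#' @return list of class `module_set`: `modules` (list of integer
#'   region-index vectors), `stage = "initial"`.
#' @export
initial_modules <- function(mc, size_range = c(3, 15)) {
  n <- nrow(mc)
  if (n < size_range[1]) stop("fewer than ", size_range[1], " regions")
  hc <- stats::hclust(stats::as.dist(1 - mc), method = "average")
  nm <- nrow(hc$merge)
  members_of <- vector("list", nm)
  for (k in seq_len(nm)) {
    members_of[[k]] <- sort(unlist(lapply(hc$merge[k, ], function(ch)
      if (ch < 0) -ch else members_of[[ch]])))
  }
  h <- hc$height
  cut_h <- if (diff(range(h)) < 1e-9) Inf else {
    ctr <- range(h)
    for (it in 1:50) {
      grp <- abs(h - ctr[1]) <= abs(h - ctr[2])
      ctr2 <- c(mean(h[grp]), mean(h[!grp]))
      if (isTRUE(all.equal(ctr2, ctr))) break
      ctr <- ctr2
    }
    mean(ctr)
  }
  parent <- rep(NA_integer_, nm)
  for (k in seq_len(nm)) for (ch in hc$merge[k, ])
    if (ch > 0) parent[ch] <- k
  tight <- h <= cut_h
  sizes_k <- lengths(members_of)
  modules <- list()
  assigned <- logical(n)
  # maximal tight clusters of admissible size, tightest first
  is_candidate <- tight & sizes_k <= size_range[2]
  maximal <- is_candidate &
    vapply(seq_len(nm), function(k) {
      p <- parent[k]
      is.na(p) || !(tight[p] && sizes_k[p] <= size_range[2])
    }, TRUE)
  for (k in order(h)) {
    if (!maximal[k]) next
    m <- members_of[[k]]
    if (any(assigned[m])) next
    modules[[length(modules) + 1L]] <- m
    assigned[m] <- TRUE
  }
  # attach leftovers to the most-correlated module with room
  for (r in which(!assigned)) {
    if (!length(modules)) { modules[[1]] <- r; assigned[r] <- TRUE; next }
    aff <- vapply(modules, function(m) mean(mc[r, m]), 1)
    room <- lengths(modules) < size_range[2]
    pick <- if (any(room)) which(room)[which.max(aff[room])] else
      which.max(aff)
    modules[[pick]] <- sort(c(modules[[pick]], r))
    assigned[r] <- TRUE
  }
  # enforce admissible sizes: merge undersized modules into the most
  # correlated module with room; split oversized ones (possible after
  # forced merges) into balanced chunks along the dendrogram leaf order
  leaf_rank <- match(seq_len(n), hc$order)
  repeat {
    sizes <- lengths(modules)
    small <- which(sizes < size_range[1])
    big <- which(sizes > size_range[2])
    if (!length(small) && !length(big)) break
    if (length(small)) {
      s <- small[1]
      affinity <- vapply(seq_along(modules), function(j) {
        if (j == s) return(-Inf)
        mean(mc[modules[[s]], modules[[j]], drop = FALSE])
      }, 1)
      room <- sizes + sizes[s] <= size_range[2]
      room[s] <- FALSE
      pick <- if (any(room)) which(room)[which.max(affinity[room])] else
        which.max(affinity)
      modules[[pick]] <- sort(c(modules[[pick]], modules[[s]]))
      modules[[s]] <- NULL
    } else {
      b <- big[1]
      m <- modules[[b]][order(leaf_rank[modules[[b]]])]
      k <- ceiling(length(m) / size_range[2])
      grp <- rep(seq_len(k), each = ceiling(length(m) / k))[
        seq_along(m)]
      modules[[b]] <- NULL
      for (g in split(m, grp)) {
        modules[[length(modules) + 1L]] <- sort(g)
      }
    }
  }
  structure(list(modules = modules, stage = "initial"),
            class = "module_set")
}

#' Refine initial modules into tight modules
#'
#' Regions that occur fewer than `min_hits` times across all
#' target-correlated region sets are dropped from every module;
#' modules keeping at least `min_regions` regions survive, with a
#' consistency score (mean pairwise Spearman correlation over the
#' remaining member pairs) attached.
#'
#' @param initial a `module_set` from [initial_modules()].
#' @param target_sets output of [target_correlated_sets()] on the same
#'   correlation map.
#' @param mc the correlation map (for consistency scores).
#' @param min_hits minimum occurrence count (default 2).
#' @param min_regions minimum surviving module size (default 2).
#' @return `module_set` with `stage = "tight"` and a `consistency`
#'   vector.
#' @export
tight_modules <- function(initial, target_sets, mc, min_hits = 2,
                          min_regions = 2) {
  occ <- tabulate(unlist(lapply(target_sets, function(s) s$regions)),
                  nbins = nrow(mc))
  keep_region <- which(occ >= min_hits)
  modules <- list()
  consistency <- numeric(0)
  for (m in initial$modules) {
    m2 <- intersect(m, keep_region)
    if (length(m2) >= min_regions) {
      modules[[length(modules) + 1L]] <- m2
      sub <- mc[m2, m2]
      consistency <- c(consistency, mean(sub[upper.tri(sub)]))
    }
  }
  structure(list(modules = modules, consistency = consistency,
                 stage = "tight"), class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("%s module set: %d modules (sizes %s)\n", x$stage,
              length(x$modules),
              paste(lengths(x$modules), collapse = ", ")))
  invisible(x)
}

#' Region labels (0 = unassigned) implied by a module set
#'
#' @param ms a `module_set`.
#' @param n_regions total number of regions.
#' @return integer vector of module indices per region.
#' @export
module_labels <- function(ms, n_regions) {
  lab <- integer(n_regions)
  for (i in seq_along(ms$modules)) lab[ms$modules[[i]]] <- i
  lab
}
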