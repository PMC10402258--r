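#' arc-length position of every node within its branch, plus branch
#' assignment, for the axonal part of a tree
#' @noRd
axon_branch_arcs <- function(tree) {
  brs <- branch_decompose(tree)
  nd <- tree$nodes
  rows <- list()
  for (bi in seq_along(brs)) {
    b <- brs[[bi]]
    ids <- b$node_ids
    r <- match(ids, nd$id)
    if (!any(nd$structure[r[-1]] == 2L)) next
    xyz <- node_xyz(tree)[r, , drop = FALSE]
    seg <- sqrt(rowSums((xyz[-1, , drop = FALSE] -
                         xyz[-nrow(xyz), , drop = FALSE])^2))
    arc <- c(0, cumsum(seg))
    rows[[length(rows) + 1L]] <- data.frame(
      branch = bi, node_id = ids, arc = arc,
      branch_length = arc[length(arc)],
      terminal_branch = {
        kids <- tree_children(tree)[[as.character(b$end_id)]]
        is.null(kids) || !length(kids)
      })
  }
  list(table = do.call(rbind, rows), branches = brs)
}

#' Detect axonal boutons from intensity and radius profiles
#'
#' Axonal branches are partitioned into `fragment_um` arc-length
#' fragments; a candidate is a node where the intensity and the radius
#' profiles both peak within `overlap_um` of each other inside a
#' fragment. Candidates must have a local radius at least
#' `radius_ratio` times the median radius of surrounding nodes
#' (within `surround_um` arc length, excluding a `core_um` core) and
#' an 8-bit intensity above `min_intensity`; candidates closer than
#' `dedupe_um` keep only the brighter one.
#'
#' @param tree a [neuron_tree()].
#' @param profiles data.frame with columns id, intensity, radius (from
#'   [sample_profiles()] or [synth_bouton_profiles()]).
#' @param fragment_um fragment length, um (default 20).
#' @param overlap_um peak overlap tolerance, um (default 2).
#' @param radius_ratio surround radius ratio (default 1.5; the
#'   candidate must be strictly larger than ratio times the surround).
#' @param min_intensity 8-bit intensity floor (default 120; strictly
#'   above passes).
#' @param surround_um,core_um surround window and excluded core, um
#'   (defaults 10 and 2).
#' @param dedupe_um duplicate distance (default 5).
#' @return object of class `bouton_set`: data.frame `boutons` (node_id,
#'   branch, arc, path_dist, type placeholder, intensity,
#'   radius_ratio), `n_branches`, plus the branch table.
#' @export
detect_boutons <- function(tree, profiles, fragment_um = 20,
                           overlap_um = 2, radius_ratio = 1.5,
                           min_intensity = 120, surround_um = 10,
                           core_um = 2, dedupe_um = 5) {
  if (is.null(profiles$intensity) || is.null(profiles$radius)) {
    stop("profiles must provide intensity and radius per node")
  }
  ab <- axon_branch_arcs(tree)
  tab <- ab$table
  pd <- path_dist_to_root(tree)
  nd <- tree$nodes
  cand <- list()
  if (!is.null(tab)) {
    inten <- profiles$intensity[match(tab$node_id, profiles$id)]
    radius <- profiles$radius[match(tab$node_id, profiles$id)]
    for (b in unique(tab$branch)) {
      sel <- which(tab$branch == b)
      arc <- tab$arc[sel]
      nfrag <- max(1L, ceiling(max(arc) / fragment_um))
      frag <- pmin(floor(arc / fragment_um) + 1L, nfrag)
      for (f in unique(frag)) {
        fs <- sel[frag == f]
        if (length(fs) < 2) next
        ipk <- fs[which.max(inten[fs])]
        rpk <- fs[which.max(radius[fs])]
        if (abs(tab$arc[ipk] - tab$arc[rpk]) > overlap_um) next
        node <- tab$node_id[rpk]
        # surround radius: same branch, within surround_um, outside core
        da <- abs(tab$arc[sel] - tab$arc[rpk])
        ring <- sel[da <= surround_um & da > core_um]
        if (length(ring) < 2) next
        surround <- stats::median(radius[ring])
        rr <- if (surround > 0) radius[rpk] / surround else Inf
        if (rr < radius_ratio) next
        if (inten[ipk] <= min_intensity) next
        cand[[length(cand) + 1L]] <- data.frame(
          node_id = node, branch = b, arc = tab$arc[rpk],
          path_dist = pd[match(node, nd$id)],
          intensity = inten[ipk], radius_ratio = rr)
      }
    }
  }
  boutons <- if (length(cand)) do.call(rbind, cand) else
    data.frame(node_id = integer(), branch = integer(),
               arc = numeric(), path_dist = numeric(),
               intensity = numeric(), radius_ratio = numeric())
  # dedupe within dedupe_um (Euclidean), keeping the brighter
  if (nrow(boutons) > 1) {
    xyz <- node_xyz(tree)[match(boutons$node_id, nd$id), ,
                          drop = FALSE]
    keep <- rep(TRUE, nrow(boutons))
    ord <- order(boutons$intensity, decreasing = TRUE)
    for (i in ord) {
      if (!keep[i]) next
      d <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2))
      close <- which(keep & d < dedupe_um)
      close <- setdiff(close, i)
      keep[close] <- FALSE
    }
    boutons <- boutons[keep, , drop = FALSE]
  }
  rownames(boutons) <- NULL
  boutons$type <- rep(NA_character_, nrow(boutons))
  structure(list(boutons = boutons, branch_table = tab,
                 tree = tree), class = "bouton_set")
}

#' @export
print.bouton_set <- function(x, ...) {
  cat(sprintf("bouton_set: %d boutons (%s)\n", nrow(x$boutons),
              paste(names(table(x$boutons$type)),
                    table(x$boutons$type), collapse = ", ")))
  invisible(x)
}

#' Classify boutons as terminaux (TEB) or en passant (EPB)
#'
#' A bouton on a terminal branch whose remaining arc to the branch tip
#' is at most `tau` micrometres is a terminaux bouton; all others are
#' en passant.
#'
#' @param bs a `bouton_set`.
#' @param tau tip distance, um (default 5; `tau = 0` restricts TEB to
#'   exact tip nodes).
#' @return the `bouton_set` with `type` filled in.
#' @export
classify_teb_epb <- function(bs, tau = 5) {
  b <- bs$boutons
  tab <- bs$branch_table
  if (nrow(b)) {
    for (i in seq_len(nrow(b))) {
      sel <- tab$branch == b$branch[i]
      blen <- tab$branch_length[sel][1]
      term <- tab$terminal_branch[sel][1]
      b$type[i] <- if (term && (blen - b$arc[i]) <= tau) "TEB" else "EPB"
    }
  }
  bs$boutons <- b
  bs
}

#' Radial (distance-to-soma) distribution of boutons
#'
#' Histogram of bouton path distances to the soma, normalised to sum
#' to 1, plus the occupancy of four per-type max-normalised distance
#' quartiles.
#'
#' @param bs a `bouton_set` (typed or not).
#' @param bin_um histogram bin width (default 100).
#' @return list: `breaks`, `fraction` (sums to 1), `quartiles`
#'   (per-type 4-vector), `empty` flag.
#' @export
radial_distribution <- function(bs, bin_um = 100) {
  b <- bs$boutons
  if (!nrow(b)) {
    return(list(breaks = numeric(0), fraction = numeric(0),
                quartiles = NULL, empty = TRUE))
  }
  d <- b$path_dist
  breaks <- seq(0, max(d) + bin_um, by = bin_um)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  types <- if (all(is.na(b$type))) list(all = seq_len(nrow(b))) else
    split(seq_len(nrow(b)), b$type)
  qt <- lapply(types, function(idx) {
    dn <- d[idx] / max(d[idx])
    q <- cut(dn, breaks = c(-Inf, 0.25, 0.5, 0.75, Inf),
             labels = FALSE)
    tabulate(q, 4) / length(idx)
  })
  list(breaks = breaks, fraction = h$counts / sum(h$counts),
       quartiles = qt, empty = FALSE)
}

#' Six-feature bouton summaries per neuron group, radar-scaled
#'
#' Per group: the average number of boutons per neuron, the TEB ratio,
#' and the mean and sd of the inter-bouton distance (arc length from a
#' bouton to its predecessor toward the soma) plus the mean and max
#' distance to soma. Feature values are min-max scaled to 0-100 across
#' groups (a single group yields all zeros, flagged).
#'
#' @param bouton_sets list of typed `bouton_set` (one per neuron).
#' @param groups group label per neuron.
#' @return list: `raw` (groups x 6), `scaled` (0-100), `degenerate`
#'   flag.
#' @export
radar_features <- function(bouton_sets, groups) {
  per_neuron <- t(vapply(bouton_sets, function(bs) {
    b <- bs$boutons
    n <- nrow(b)
    ibd <- inter_bouton_distances(bs)
    c(n_boutons = n,
      teb_ratio = if (n) mean(b$type == "TEB", na.rm = TRUE) else 0,
      ibd_mean = if (length(ibd)) mean(ibd) else 0,
      ibd_sd = if (length(ibd) > 1) stats::sd(ibd) else 0,
      d2s_mean = if (n) mean(b$path_dist) else 0,
      d2s_max = if (n) max(b$path_dist) else 0)
  }, numeric(6)))
  glab <- sort(unique(groups))
  raw <- t(vapply(glab, function(g)
    colMeans(per_neuron[groups == g, , drop = FALSE]), numeric(6)))
  rownames(raw) <- glab
  degenerate <- length(glab) < 2
  scaled <- if (degenerate) raw * 0 else {
    rng <- apply(raw, 2, range)
    span <- pmax(rng[2, ] - rng[1, ], .Machine$double.eps)
    sweep(sweep(raw, 2, rng[1, ]), 2, span, "/") * 100
  }
  list(raw = raw, scaled = scaled, degenerate = degenerate)
}

#' arc distances from each bouton to its predecessor toward the soma
#' (per branch; the first bouton of a branch has no predecessor)
#' @noRd
inter_bouton_distances <- function(bs) {
  b <- bs$boutons
  if (nrow(b) < 2) return(numeric(0))
  out <- numeric(0)
  for (br in unique(b$branch)) {
    arcs <- sort(b$arc[b$branch == br])
    if (length(arcs) > 1) out <- c(out, diff(arcs))
  }
  out
}

#' Branch-level bouton statistics
#'
#' Labels every axonal branch as a bouton-branch or a null-branch,
#' reports per-branch length, order and curviness (1 minus the chord
#' over the path length), classifies bifurcations by the presence of
#' boutons in their two child branches (B0 both, B1 one, B2 none) and
#' tabulates the within-branch positional quartile of each bouton.
#'
#' @param bs a `bouton_set`.
#' @return list: `branches` (data.frame branch, length, order,
#'   curviness, n_boutons, class), `bifurcation_types` (table over B0,
#'   B1, B2), `quartile_share` (4-vector summing to 1 over boutons on
#'   bouton-branches).
#' @export
branch_bouton_stats <- function(bs) {
  tree <- bs$tree
  brs <- branch_decompose(tree)
  tab <- bs$branch_table
  b <- bs$boutons
  idx <- sort(unique(tab$branch))
  branches <- do.call(rbind, lapply(idx, function(bi) {
    br <- brs[[bi]]
    nb <- sum(b$branch == bi)
    data.frame(branch = bi, length = br$path_length,
               order = br$order,
               curviness = 1 - (if (br$path_length > 0)
                 br$euclidean_span / br$path_length else 1),
               n_boutons = nb,
               class = if (nb > 0) "bouton" else "null")
  }))
  # bifurcation typing over axonal bifurcations
  nd <- tree$nodes
  with_boutons <- unique(b$branch)
  start_of <- vapply(brs, function(x) x$start_id, 1)
  types <- character(0)
  for (bid in unique(start_of[idx])) {
    kids <- which(start_of == bid)
    kids <- intersect(kids, idx)
    if (length(kids) != 2) next
    k <- sum(kids %in% with_boutons)
    types <- c(types, c("B2", "B1", "B0")[k + 1])
  }
  qshare <- rep(NA_real_, 4)
  if (nrow(b)) {
    blen <- tab$branch_length[match(paste(b$branch),
                                    paste(tab$branch))]
    frac <- ifelse(blen > 0, b$arc / blen, 0)
    q <- cut(frac, c(-Inf, 0.25, 0.5, 0.75, Inf), labels = FALSE)
    qshare <- tabulate(q, 4) / nrow(b)
  }
  list(branches = branches,
       bifurcation_types = table(factor(types,
                                        levels = c("B0", "B1", "B2"))),
       quartile_share = qshare)
}
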