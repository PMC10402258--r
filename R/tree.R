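#' Neuron skeleton trees
#'
#' A `neuron_tree` is a rooted skeleton read from (or written to) the
#' 7-column SWC format: one row per node with fields `id`, `structure`
#' (1 soma, 2 axon, 3 basal dendrite, 4 apical dendrite), `x`, `y`, `z`
#' (micrometres), `radius` (micrometres) and `parent` (`-1` for the root).
#' The object stores the node table plus free-form metadata (brain id,
#' soma region, projection class, cortical layer).
#'
#' @param nodes data.frame with columns id, structure, x, y, z, radius,
#'   parent.
#' @param metadata named list of neuron-level annotations.
#' @param validate check the tree invariants (single root, no dangling
#'   parents, acyclic, connected).
#' @return An object of class `neuron_tree`.
#' @export
neuron_tree <- function(nodes, metadata = list(), validate = TRUE) {
  required <- c("id", "structure", "x", "y", "z", "radius", "parent")
  if (!all(required %in% names(nodes))) {
    stop("nodes must have columns: ", paste(required, collapse = ", "))
  }
  nodes <- as.data.frame(nodes)[required]
  nodes$id <- as.integer(nodes$id)
  nodes$structure <- as.integer(nodes$structure)
  nodes$parent <- as.integer(nodes$parent)
  rownames(nodes) <- NULL
  tree <- structure(list(nodes = nodes, metadata = metadata),
                    class = "neuron_tree")
  if (validate) validate_tree(tree)
  tree
}

#' @export
print.neuron_tree <- function(x, ...) {
  n <- nrow(x$nodes)
  cat(sprintf("neuron_tree: %d nodes, %d stems, %d tips\n",
              n, length(tree_children(x)[[as.character(tree_root_id(x))]]),
              sum(n_children_vec(x) == 0)))
  invisible(x)
}

validate_tree <- function(tree) {
  nd <- tree$nodes
  if (anyDuplicated(nd$id)) stop("duplicate node ids")
  if (any(nd$id <= 0)) stop("node ids must be positive")
  if (any(nd$radius < 0)) stop("negative radius")
  roots <- which(nd$parent == -1L)
  if (length(roots) == 0) stop("no root node (parent -1) found")
  if (length(roots) > 1) {
    stop("multiple roots: ids ", paste(nd$id[roots], collapse = ", "))
  }
  dangling <- setdiff(nd$parent, c(-1L, nd$id))
  if (length(dangling)) {
    stop("dangling parent id(s): ", paste(dangling, collapse = ", "))
  }
  # reachability from root (also excludes cycles off the root component)
  idx <- match(nd$parent, nd$id)           # NA for root
  seen <- logical(nrow(nd))
  seen[roots] <- TRUE
  repeat {
    new <- !seen & seen[idx]
    new[is.na(new)] <- FALSE
    if (!any(new)) break
    seen[new] <- TRUE
  }
  if (!all(seen)) {
    stop("nodes not reachable from root: ids ",
         paste(nd$id[!seen], collapse = ", "))
  }
  invisible(tree)
}

tree_root_id <- function(tree) tree$nodes$id[tree$nodes$parent == -1L]

#' number of children per node (in node-table order)
#' @noRd
n_children_vec <- function(tree) {
  nd <- tree$nodes
  tab <- table(factor(nd$parent[nd$parent != -1L], levels = nd$id))
  as.integer(tab)
}

#' children lists indexed by node id (as character)
#' @noRd
tree_children <- function(tree) {
  nd <- tree$nodes
  kids <- split(nd$id[nd$parent != -1L],
                factor(nd$parent[nd$parent != -1L], levels = nd$id))
  kids
}

node_xyz <- function(tree) as.matrix(tree$nodes[, c("x", "y", "z")])

#' Euclidean length of the edge above each node (0 for root)
#' @noRd
edge_lengths <- function(tree) {
  nd <- tree$nodes
  idx <- match(nd$parent, nd$id)
  len <- numeric(nrow(nd))
  has <- !is.na(idx)
  d <- node_xyz(tree)[has, , drop = FALSE] -
    node_xyz(tree)[idx[has], , drop = FALSE]
  len[has] <- sqrt(rowSums(d^2))
  len
}

#' path distance from root to every node
#' @noRd
path_dist_to_root <- function(tree) {
  nd <- tree$nodes
  idx <- match(nd$parent, nd$id)
  len <- edge_lengths(tree)
  ord <- topo_order(tree)
  pd <- numeric(nrow(nd))
  for (i in ord) {
    if (!is.na(idx[i])) pd[i] <- pd[idx[i]] + len[i]
  }
  pd
}

#' row indices in topological order (root first)
#' @noRd
topo_order <- function(tree) {
  nd <- tree$nodes
  idx <- match(nd$parent, nd$id)
  n <- nrow(nd)
  depth <- rep(NA_integer_, n)
  depth[is.na(idx)] <- 0L
  d <- 0L
  while (anyNA(depth)) {
    nxt <- which(is.na(depth) & !is.na(depth[idx]) & depth[idx] == d)
    if (!length(nxt)) {
      nxt <- which(is.na(depth) & !is.na(depth[idx]))
      if (!length(nxt)) break
      depth[nxt] <- depth[idx[nxt]] + 1L
      next
    }
    depth[nxt] <- d + 1L
    d <- d + 1L
  }
  order(depth)
}

#' Read a neuron skeleton from an SWC file
#'
#' Accepts the standard 7-column whitespace-separated SWC layout with
#' `#` comment lines. Coordinates and radii are taken as micrometres.
#'
#' @param path file path.
#' @param metadata optional named list attached to the tree.
#' @return a validated [neuron_tree()].
#' @export
read_swc <- function(path, metadata = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lineno <- which(keep)
  fields <- strsplit(trimws(raw[keep]), "\\s+")
  bad <- which(vapply(fields, length, 1L) != 7L)
  if (length(bad)) {
    stop(sprintf("malformed SWC line %d in %s (expected 7 fields)",
                 lineno[bad[1]], path))
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(m, 1, anyNA))[1]
    stop(sprintf("malformed SWC line %d in %s (non-numeric field)",
                 lineno[bad], path))
  }
  nodes <- data.frame(id = m[, 1], structure = m[, 2], x = m[, 3],
                      y = m[, 4], z = m[, 5], radius = m[, 6],
                      parent = m[, 7])
  neuron_tree(nodes, metadata = metadata)
}

#' Write a neuron skeleton to an SWC file
#'
#' @param tree a [neuron_tree()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path) {
  nd <- tree$nodes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id type x y z radius parent", con)
  writeLines(sprintf("%d %d %.6g %.6g %.6g %.6g %d",
                     nd$id, nd$structure, nd$x, nd$y, nd$z, nd$radius,
                     nd$parent), con)
  invisible(path)
}

#' Keep a subset of nodes, preserving reachability from the root
#'
#' Nodes whose ancestors were dropped are removed as well (the largest
#' rooted component is retained).
#' @noRd
subset_tree <- function(tree, keep_ids) {
  nd <- tree$nodes
  root <- tree_root_id(tree)
  keep_ids <- union(keep_ids, root)
  keep <- nd$id %in% keep_ids
  # drop nodes disconnected from root after subsetting
  idx <- match(nd$parent, nd$id)
  ok <- keep & FALSE
  ok[nd$parent == -1L & keep] <- TRUE
  repeat {
    new <- keep & !ok & !is.na(idx) & ok[idx]
    new[is.na(new)] <- FALSE
    if (!any(new)) break
    ok[new] <- TRUE
  }
  neuron_tree(nd[ok, , drop = FALSE], metadata = tree$metadata,
              validate = FALSE)
}

#' descendant row indices (inclusive) of a set of node ids
#' @noRd
descendant_ids <- function(tree, ids) {
  nd <- tree$nodes
  inset <- nd$id %in% ids
  idx <- match(nd$parent, nd$id)
  repeat {
    new <- !inset & !is.na(idx) & inset[idx]
    if (!any(new)) break
    inset[new] <- TRUE
  }
  nd$id[inset]
}

#' Resample a skeleton to a maximum inter-node spacing
#'
#' Critical points (root, bifurcations, tips) are preserved exactly;
#' every edge run between them is re-interpolated so that consecutive
#' nodes are at most `spacing` micrometres apart along the path.
#' Radii and structure labels are linearly interpolated / inherited.
#'
#' @param tree a [neuron_tree()].
#' @param spacing maximum node spacing in micrometres (> 0).
#' @return a resampled [neuron_tree()].
#' @export
resample_tree <- function(tree, spacing) {
  stopifnot(spacing > 0)
  brs <- branch_decompose(tree)
  nd <- tree$nodes
  rowof <- function(id) match(id, nd$id)
  root <- tree_root_id(tree)
  rrow <- rowof(root)
  out <- data.frame(id = 1L, structure = nd$structure[rrow],
                    x = nd$x[rrow], y = nd$y[rrow], z = nd$z[rrow],
                    radius = nd$radius[rrow], parent = -1L)
  # map original critical node id -> new id
  newid <- c(stats::setNames(1L, as.character(root)))
  nxt <- 2L
  pieces <- list(out)
  for (b in brs) {
    rows <- rowof(b$node_ids)
    xyz <- as.matrix(nd[rows, c("x", "y", "z")])
    rad <- nd$radius[rows]
    str <- nd$structure[rows[length(rows)]]
    seglen <- sqrt(rowSums((xyz[-1, , drop = FALSE] -
                            xyz[-nrow(xyz), , drop = FALSE])^2))
    arc <- c(0, cumsum(seglen))
    total <- arc[length(arc)]
    nseg <- max(1L, ceiling(total / spacing))
    tgt <- seq(0, total, length.out = nseg + 1L)[-1]
    if (total == 0) {
      px <- rep(xyz[nrow(xyz), 1], length(tgt))
      py <- rep(xyz[nrow(xyz), 2], length(tgt))
      pz <- rep(xyz[nrow(xyz), 3], length(tgt))
      pr <- rep(rad[length(rad)], length(tgt))
    } else {
      k <- pmin(pmax(findInterval(tgt, arc, rightmost.closed = TRUE), 1L),
                nrow(xyz) - 1L)
      f <- ifelse(seglen[k] > 0, (tgt - arc[k]) / seglen[k], 0)
      px <- xyz[k, 1] + f * (xyz[k + 1L, 1] - xyz[k, 1])
      py <- xyz[k, 2] + f * (xyz[k + 1L, 2] - xyz[k, 2])
      pz <- xyz[k, 3] + f * (xyz[k + 1L, 3] - xyz[k, 3])
      pr <- rad[k] + f * (rad[k + 1L] - rad[k])
    }
    ids <- seq.int(nxt, length.out = length(tgt))
    parent_new <- newid[[as.character(b$node_ids[1])]]
    pieces[[length(pieces) + 1L]] <- data.frame(
      id = ids, structure = str, x = px, y = py, z = pz, radius = pr,
      parent = c(parent_new, ids[-length(ids)]))
    nxt <- nxt + length(tgt)
    newid[[as.character(b$node_ids[length(b$node_ids)])]] <-
      ids[length(ids)]
  }
  neuron_tree(do.call(rbind, pieces), metadata = tree$metadata)
}

#' Read / write a directory-of-SWC dataset with a metadata sidecar
#'
#' A dataset is a directory of SWC files plus a `metadata.csv` sidecar
#' with one row per neuron: `file`, `neuron_id`, `brain_id`, `region`,
#' `projection_class` (ET/IT/core/matrix/none) and `layer` (optional).
#' Metadata fields are attached to each tree's `metadata` list on
#' reading and recovered from it on writing.
#'
#' @param dir dataset directory.
#' @return `read_swc_dataset`: a list of [neuron_tree()].
#' @export
read_swc_dataset <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) stop("no metadata.csv in ", dir)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(i) {
    md <- as.list(meta[i, setdiff(names(meta), "file")])
    read_swc(file.path(dir, meta$file[i]), metadata = md)
  })
}

#' @rdname read_swc_dataset
#' @param trees list of [neuron_tree()] to write.
#' @export
write_swc_dataset <- function(trees, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  get_md <- function(tr, f, default) {
    v <- tr$metadata[[f]]
    if (is.null(v)) default else v
  }
  rows <- lapply(seq_along(trees), function(i) {
    f <- sprintf("neuron_%04d.swc", i)
    write_swc(trees[[i]], file.path(dir, f))
    data.frame(
      file = f,
      neuron_id = get_md(trees[[i]], "neuron_id", i),
      brain_id = get_md(trees[[i]], "brain_id", NA),
      region = get_md(trees[[i]], "region", NA),
      projection_class = get_md(trees[[i]], "projection_class",
                                "none"),
      layer = get_md(trees[[i]], "layer", NA))
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  invisible(dir)
}
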