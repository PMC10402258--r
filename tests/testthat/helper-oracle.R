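# Naive per-definition reimplementations of the morphometric features,
# written as plain recursions/loops, independent of the package's
# vectorised code paths. Used as the reference in oracle-equivalence
# tests.

oracle_morphometry <- function(tree) {
  nd <- tree$nodes
  ids <- nd$id
  getrow <- function(id) nd[match(id, ids), ]
  pos <- function(id) {
    r <- getrow(id)
    c(r$x, r$y, r$z)
  }
  children <- function(id) sort(ids[nd$parent == id])
  root <- ids[nd$parent == -1]
  euclid <- function(a, b) sqrt(sum((a - b)^2))
  ang <- function(u, v) {
    c1 <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    acos(min(1, max(-1, c1))) * 180 / pi
  }

  # ---- branches by explicit recursion
  branches <- list()
  walk <- function(start, order) {
    for (ch in children(start)) {
      path <- c(start, ch)
      cur <- ch
      while (length(children(cur)) == 1) {
        cur <- children(cur)
        path <- c(path, cur)
      }
      branches[[length(branches) + 1L]] <<-
        list(path = path, order = order, start = start, end = cur)
      if (length(children(cur)) >= 1) walk(cur, order + 1)
    }
  }
  walk(root, 1)
  path_len <- vapply(branches, function(b) {
    s <- 0
    for (i in seq_len(length(b$path) - 1)) {
      s <- s + euclid(pos(b$path[i]), pos(b$path[i + 1]))
    }
    s
  }, 1)
  chord <- vapply(branches, function(b)
    euclid(pos(b$path[1]), pos(b$path[length(b$path)])), 1)

  # ---- per-node quantities
  nch <- vapply(ids, function(i) length(children(i)), 1)
  tips <- ids[nch == 0]
  path_to_root <- function(id) {
    s <- 0
    while (id != root) {
      p <- getrow(id)$parent
      s <- s + euclid(pos(id), pos(p))
      id <- p
    }
    s
  }
  ntips_below <- function(id) {
    ch <- children(id)
    if (!length(ch)) return(1)
    sum(vapply(ch, ntips_below, 1))
  }

  # ---- 22 global features
  length_total <- 0
  surface <- 0
  volume <- 0
  for (i in seq_len(nrow(nd))) {
    if (nd$parent[i] == -1) next
    l <- euclid(pos(ids[i]), pos(nd$parent[i]))
    length_total <- length_total + l
    surface <- surface + 2 * pi * nd$radius[i] * l
    volume <- volume + pi * nd$radius[i]^2 * l
  }
  bifs <- ids[nch >= 2 & ids != root]
  pdr <- c()
  for (b in ids[nch >= 2]) {
    for (ch in children(b)) {
      pdr <- c(pdr, getrow(ch)$radius / getrow(b)$radius)
    }
  }
  # angles at every node with >= 2 children (consecutive child pairs)
  al <- ar <- c()
  bif_rows <- list()
  for (b in ids[nch >= 2]) {
    ch <- children(b)
    # remote endpoint: walk each child branch to its end
    remote <- vapply(ch, function(c1) {
      cur <- c1
      while (length(children(cur)) == 1) cur <- children(cur)
      cur
    }, 1)
    for (i in seq_len(length(ch) - 1)) {
      v1 <- pos(ch[i]) - pos(b)
      v2 <- pos(ch[i + 1]) - pos(b)
      r1 <- pos(remote[i]) - pos(b)
      r2 <- pos(remote[i + 1]) - pos(b)
      al <- c(al, ang(v1, v2))
      ar <- c(ar, ang(r1, r2))
      t1 <- ntips_below(ch[i])
      t2 <- ntips_below(ch[i + 1])
      tl <- tr <- NA
      if (b != root) {
        vin <- pos(b) - pos(getrow(b)$parent)
        tl <- min(ang(vin, v1), ang(vin, v2))
        tr <- min(ang(vin, r1), ang(vin, r2))
      }
      bif_rows[[length(bif_rows) + 1]] <- list(
        bif_id = b,
        euc = euclid(pos(b), pos(root)),
        pd = path_to_root(b),
        asym = if (t1 + t2 > 2) abs(t1 - t2) / (t1 + t2 - 2) else 0,
        al = ang(v1, v2), ar = ang(r1, r2), tl = tl, tr = tr)
    }
  }

  # Hausdorff dimension: same definition, independent loops
  step <- {
    lens <- c()
    for (i in seq_len(nrow(nd))) {
      if (nd$parent[i] != -1) {
        lens <- c(lens, euclid(pos(ids[i]), pos(nd$parent[i])))
      }
    }
    max(median(lens) / 2, 1e-6)
  }
  pts <- NULL
  for (i in seq_len(nrow(nd))) pts <- rbind(pts, pos(ids[i]))
  for (i in seq_len(nrow(nd))) {
    if (nd$parent[i] == -1) next
    a <- pos(nd$parent[i]); b <- pos(ids[i])
    l <- euclid(a, b)
    k <- floor(l / step)
    if (k >= 1) {
      for (j in seq_len(k)) pts <- rbind(pts, a + j / (k + 1) * (b - a))
    }
  }
  lo <- apply(pts, 2, min)
  side <- max(apply(pts, 2, max) - lo)
  hd <- 0
  if (side > 0) {
    xs <- ys <- c()
    for (l in 1:4) {
      s <- side / 2^(l - 1)
      keys <- character(0)
      for (i in seq_len(nrow(pts))) {
        cell <- floor((pts[i, ] - lo) / s)
        cell[cell >= 2^(l - 1)] <- 2^(l - 1) - 1
        keys <- c(keys, paste(cell, collapse = "/"))
      }
      xs <- c(xs, log(1 / s))
      ys <- c(ys, log(length(unique(keys))))
    }
    hd <- sum((xs - mean(xs)) * (ys - mean(ys))) /
      sum((xs - mean(xs))^2)
  }

  contraction <- ifelse(path_len > 0, chord / path_len, 1)
  global <- c(
    Nodes = nrow(nd),
    SomaSurface = 4 * pi * getrow(root)$radius^2,
    Stems = length(children(root)),
    Bifurcations = length(bifs),
    Branches = length(branches),
    Tips = length(tips),
    OverallWidth = max(nd$x) - min(nd$x),
    OverallHeight = max(nd$y) - min(nd$y),
    OverallDepth = max(nd$z) - min(nd$z),
    AverageDiameter = mean(2 * nd$radius),
    Length = length_total,
    Surface = surface,
    Volume = volume,
    MaxEuclideanDistance = max(vapply(ids, function(i)
      euclid(pos(i), pos(root)), 1)),
    MaxPathDistance = max(vapply(ids, path_to_root, 1)),
    MaxBranchOrder = max(vapply(branches, function(b) b$order, 1)),
    AverageContraction = mean(contraction),
    AverageFragmentation = mean(vapply(branches, function(b)
      length(b$path) - 1, 1)),
    `AverageParent-daughterRatio` = if (length(pdr)) mean(pdr) else 0,
    AverageBifurcationAngleLocal = if (length(al)) mean(al) else 0,
    AverageBifurcationAngleRemote = if (length(ar)) mean(ar) else 0,
    HausdorffDimension = hd)

  list(global = global,
       branches = data.frame(
         end_id = vapply(branches, function(b) b$end, 1),
         br_length = path_len,
         br_order = vapply(branches, function(b) b$order, 1),
         br_contraction = contraction),
       bifurcations = if (length(bif_rows)) data.frame(
         bif_id = vapply(bif_rows, `[[`, 1, "bif_id"),
         bif_EucDist2soma = vapply(bif_rows, `[[`, 1, "euc"),
         bif_PathDist2soma = vapply(bif_rows, `[[`, 1, "pd"),
         asymmetry = vapply(bif_rows, `[[`, 1, "asym"),
         ampl_local = vapply(bif_rows, `[[`, 1, "al"),
         ampl_remote = vapply(bif_rows, `[[`, 1, "ar"),
         tilt_local = vapply(bif_rows, function(r)
           if (is.null(r$tl)) NA_real_ else as.numeric(r$tl), 1),
         tilt_remote = vapply(bif_rows, function(r)
           if (is.null(r$tr)) NA_real_ else as.numeric(r$tr), 1))
       else NULL)
}

# relative comparison tolerant of near-zero values
rel_equal <- function(a, b, tol = 1e-9) {
  a <- as.vector(as.matrix(a))
  b <- as.vector(as.matrix(b))
  all(abs(a - b) <= tol * pmax(1, abs(b)), na.rm = TRUE) &&
    identical(which(is.na(a)), which(is.na(b)))
}
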