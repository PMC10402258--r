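test_that("SWC reading validates structure and round-trips exactly", {
  tr <- y_neuron()
  f <- tempfile(fileext = ".swc")
  write_swc(tr, f)
  tr2 <- read_swc(f)
  expect_equal(tr2$nodes, tr$nodes)
  # second round trip is bit-stable
  f2 <- tempfile(fileext = ".swc")
  write_swc(tr2, f2)
  expect_identical(readLines(f), readLines(f2))

  # malformed line reported with its number
  writeLines(c("# header", "1 1 0 0 0 1 -1", "2 3 1 0"), f)
  expect_error(read_swc(f), "line 3")
  # dangling parent named in the error
  writeLines(c("1 1 0 0 0 1 -1", "2 3 1 0 0 1 99"), f)
  expect_error(read_swc(f), "99")
  # multiple roots rejected
  writeLines(c("1 1 0 0 0 1 -1", "2 1 5 0 0 1 -1"), f)
  expect_error(read_swc(f), "[Mm]ultiple roots")
})

test_that("branch decomposition partitions edges with correct orders", {
  brs <- branch_decompose(y_neuron())
  expect_length(brs, 3)
  ord <- vapply(brs, function(b) b$order, 1)
  len <- vapply(brs, function(b) b$path_length, 1)
  expect_equal(sort(ord), c(1, 2, 2))
  expect_equal(sort(len), c(10, 10, 20))
  # edges partition: every non-root edge appears in exactly one branch
  n_edges <- sum(vapply(brs, function(b) length(b$node_ids) - 1, 1))
  expect_equal(n_edges, nrow(y_neuron()$nodes) - 1)

  expect_length(branch_decompose(line_tree(4)), 1)

  # path lengths are conserved against the Length feature
  tr <- random_binary_tree(11)
  expect_equal(sum(vapply(branch_decompose(tr), function(b)
    b$path_length, 1)),
    unname(lmeasure_features(tr)["Length"]))
})

test_that("whole-neuron features match hand values on the Y fixture", {
  f <- lmeasure_features(y_neuron())
  expect_equal(unname(f["Nodes"]), 5)
  expect_equal(unname(f["Stems"]), 1)
  expect_equal(unname(f["Bifurcations"]), 1)
  expect_equal(unname(f["Tips"]), 2)
  expect_equal(unname(f["Length"]), 40)
  expect_equal(unname(f["MaxEuclideanDistance"]), sqrt(500))
  expect_equal(unname(f["MaxBranchOrder"]), 2)
  expect_equal(unname(f["AverageBifurcationAngleRemote"]), 180)
  expect_error(lmeasure_features(line_tree(1)), ">= 2 nodes")
})

test_that("collinear trees give degenerate extents and contraction 1", {
  f <- lmeasure_features(line_tree(3, spacing = 10))
  expect_equal(unname(f["OverallWidth"]), 20)
  expect_equal(unname(f["OverallHeight"]), 0)
  expect_equal(unname(f["OverallDepth"]), 0)
  expect_equal(unname(f["AverageContraction"]), 1)
})

test_that("local branch features match hand values", {
  lf <- local_branch_features(y_neuron())
  expect_equal(lf$bifurcations$bif_EucDist2soma, 20)
  expect_equal(lf$bifurcations$bif_PathDist2soma, 20)
  expect_equal(lf$bifurcations$asymmetry, 0)     # (1,1) tip split
  expect_equal(lf$bifurcations$ampl_remote, 180)

  # semicircular branch: contraction = chord / arc -> 2/pi
  lf2 <- local_branch_features(semicircle_tree(10, pts = 200))
  expect_equal(lf2$branches$br_contraction, 2 / pi, tolerance = 1e-4)

  # no bifurcations -> empty bifurcation table, not an error
  lf3 <- local_branch_features(line_tree(4))
  expect_equal(nrow(lf3$bifurcations), 0)
})

test_that("all features agree with the per-definition oracle on random trees", {
  for (seed in 1:20) {
    tr <- random_binary_tree(seed)
    o <- oracle_morphometry(tr)
    f <- lmeasure_features(tr)
    expect_true(rel_equal(f[names(o$global)], o$global),
                label = paste("global features, seed", seed))
    lf <- local_branch_features(tr)
    b1 <- lf$branches[order(lf$branches$end_id), -1]
    b2 <- o$branches[order(o$branches$end_id), -1]
    expect_true(rel_equal(as.matrix(b1), as.matrix(b2)),
                label = paste("branch features, seed", seed))
    if (!is.null(o$bifurcations)) {
      f1 <- lf$bifurcations[order(lf$bifurcations$bif_id), ]
      f2 <- o$bifurcations[order(o$bifurcations$bif_id), ]
      for (cn in names(f2)) {
        expect_true(rel_equal(f1[[cn]], f2[[cn]]),
                    label = paste("bifurcation", cn, "seed", seed))
      }
    }
  }
})

test_that("binary-tree count identities hold on generated trees", {
  for (seed in 21:30) {
    tr <- random_binary_tree(seed)
    f <- lmeasure_features(tr)
    expect_equal(unname(f["Branches"]),
                 unname(f["Stems"] + 2 * f["Bifurcations"]))
    expect_equal(unname(f["Tips"]),
                 unname(f["Bifurcations"] + f["Stems"]))
    expect_gte(unname(f["Length"]), unname(f["MaxEuclideanDistance"]))
    expect_true(f["AverageContraction"] > 0 &&
                  f["AverageContraction"] <= 1)
  }
})

test_that("resampling preserves topology and bounds node spacing", {
  tr <- line_tree(2, spacing = 100)
  rt <- resample_tree(tr, 10)
  expect_equal(nrow(rt$nodes), 11)

  for (seed in 1:5) {
    tr <- random_binary_tree(seed)
    rt <- resample_tree(tr, 6)
    f0 <- lmeasure_features(tr)
    f1 <- lmeasure_features(rt)
    expect_equal(unname(f1["Tips"]), unname(f0["Tips"]))
    expect_equal(unname(f1["Bifurcations"]), unname(f0["Bifurcations"]))
    # total length changes at most one spacing per branch
    expect_lte(abs(f1[["Length"]] - f0[["Length"]]),
               6 * f0[["Branches"]])
    # spacing bound
    expect_lte(max(morphoscale:::edge_lengths(rt)), 6 + 1e-9)
  }

  # idempotent on conformant trees (same geometry)
  tr <- y_neuron()
  r1 <- resample_tree(tr, 25)
  r2 <- resample_tree(r1, 25)
  expect_equal(r1$nodes[c("x", "y", "z")], r2$nodes[c("x", "y", "z")])
})

test_that("PCA shape features handle lines, isotropy and rotations", {
  f <- pca_shape_features(line_tree(5))
  expect_equal(unname(f[1:3]), c(1, 0, 0))
  expect_equal(unname(f[4:6]), c(1, 0, 0))

  set.seed(42)
  cloud <- matrix(rnorm(3000), ncol = 3)
  fi <- pca_shape_features(cloud)
  expect_equal(unname(fi[1:3]), rep(1 / 3, 3), tolerance = 0.1)

  # rotation invariance of variance ratios
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3)
  set.seed(7)
  pts <- matrix(rnorm(300), ncol = 3) %*% diag(c(3, 2, 1))
  expect_equal(pca_shape_features(pts)[1:3],
               pca_shape_features(pts %*% R)[1:3], tolerance = 1e-9)
})

test_that("SWC datasets round-trip with their metadata sidecar", {
  trees <- list(
    neuron_tree(y_neuron()$nodes,
                metadata = list(neuron_id = 11, brain_id = "b1",
                                region = 3, projection_class = "ET",
                                layer = "L5")),
    neuron_tree(line_tree(6)$nodes,
                metadata = list(neuron_id = 12, brain_id = "b2",
                                region = 5, projection_class = "IT",
                                layer = NA)))
  d <- tempfile()
  write_swc_dataset(trees, d)
  expect_true(file.exists(file.path(d, "metadata.csv")))
  back <- read_swc_dataset(d)
  expect_length(back, 2)
  expect_equal(back[[1]]$nodes, trees[[1]]$nodes)
  expect_equal(back[[2]]$metadata$brain_id, "b2")
  expect_equal(back[[1]]$metadata$projection_class, "ET")
  expect_error(read_swc_dataset(tempfile()), "metadata.csv")
})
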