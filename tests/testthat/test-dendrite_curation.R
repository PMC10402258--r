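test_that("crowded somas are eliminated by the neighbourhood rule", {
  # isolated soma kept
  expect_true(soma_neighborhood_filter(matrix(c(0, 0, 0), 1)))
  # 7 mutually close somas: each has 6 > 5 neighbours -> all gone
  cl <- matrix(rnorm(21, sd = 10), 7, 3)
  expect_false(any(soma_neighborhood_filter(cl)))
  # exactly 5 neighbours is tolerated ("more than five")
  six <- matrix(rnorm(18, sd = 10), 6, 3)
  expect_true(all(soma_neighborhood_filter(six)))
  # the 128 um radius bounds the neighbourhood
  far <- rbind(cl, matrix(c(0, 0, 1e4), 1))
  expect_true(soma_neighborhood_filter(far)[8])
})

test_that("consensus merge prunes unsupported subtrees", {
  tr <- y_neuron()
  expect_equal(consensus_merge(tr, tr)$nodes, tr$nodes)

  # a spurious branch absent from the reference is removed wholesale
  extra <- tr$nodes
  for (i in 1:30) {
    extra <- rbind(extra, data.frame(
      id = 5 + i, structure = 3, x = 20 + 10 * i, y = 50 + 10 * i,
      z = 0, radius = .5, parent = ifelse(i == 1, 3, 4 + i)))
  }
  noisy <- neuron_tree(extra)
  merged <- consensus_merge(noisy, tr)
  expect_setequal(merged$nodes$id, tr$nodes$id)

  # empty-ish reference (root only): everything but the root goes
  ref0 <- neuron_tree(tr$nodes[1, ], validate = FALSE)
  m0 <- consensus_merge(tr, ref0)
  expect_equal(nrow(m0$nodes), 1)

  # distant roots refuse to merge
  shifted <- tr
  shifted$nodes$x <- shifted$nodes$x + 100
  expect_warning(consensus_merge(tr, shifted), "farther")
})

test_that("geometry pruning applies the angle and radius rules", {
  # doubling back at 30 degrees: removed
  pr <- prune_geometry(branch_fixture(30))
  expect_equal(nrow(pr$nodes), 5)
  # straight continuation kept
  expect_equal(nrow(prune_geometry(branch_fixture(180))$nodes), 7)
  # boundary: exactly 80 degrees is kept (< 80 prunes)
  expect_equal(nrow(prune_geometry(branch_fixture(80))$nodes), 7)
  expect_equal(nrow(prune_geometry(branch_fixture(79.5))$nodes), 5)
  # radius rule: 1.6x parent removed, 1.4x kept
  expect_equal(nrow(prune_geometry(
    branch_fixture(120, child_radius = .8))$nodes), 5)   # 1.6x
  expect_equal(nrow(prune_geometry(
    branch_fixture(120, child_radius = .7))$nodes), 7)   # 1.4x
  # idempotent
  once <- prune_geometry(branch_fixture(30))
  expect_equal(prune_geometry(once)$nodes, once$nodes)
})

test_that("crossover pruning resolves multifurcations and X crossings", {
  # trifurcation with children at 170/20/90 degrees: the 20-degree
  # child goes, the 170-degree one stays
  mk_child <- function(base_id, ang_deg, start = c(20, 0, 0)) {
    th <- (180 - ang_deg) * pi / 180
    dir <- c(cos(th), sin(th), 0)
    rbind(start + 10 * dir, start + 20 * dir)
  }
  nodes <- data.frame(id = 1:3, structure = c(1, 3, 3),
                      x = c(0, 10, 20), y = 0, z = 0, radius = .5,
                      parent = c(-1, 1, 2))
  nid <- 4
  for (a in c(170, 20, 90)) {
    pts <- mk_child(3, a)
    nodes <- rbind(nodes,
                   data.frame(id = nid, structure = 3, x = pts[1, 1],
                              y = pts[1, 2], z = 0, radius = .5,
                              parent = 3),
                   data.frame(id = nid + 1, structure = 3,
                              x = pts[2, 1], y = pts[2, 2], z = 0,
                              radius = .5, parent = nid))
    nid <- nid + 2
  }
  tri <- neuron_tree(nodes)
  pruned <- prune_crossovers(tri)
  kept <- pruned$nodes$id
  expect_false(6 %in% kept)  # the 20-degree child head
  expect_true(4 %in% kept)   # the 170-degree child survives

  # X crossing encoded as two bifurcations 3 voxels apart: the
  # through-path survives, the crossing spurs are cut
  xn <- data.frame(
    id = 1:9, structure = c(1, rep(3, 8)),
    x = c(0, 10, 13, 23, 33, 11, 6, 14.5, 19),
    y = c(0, 0, 0, 0.5, 1, 10, 18, -10, -18),
    z = 0, radius = .5,
    parent = c(-1, 1, 2, 3, 4, 2, 6, 3, 8))
  xfix <- neuron_tree(xn)
  xp <- prune_crossovers(xfix)
  expect_true(all(c(3, 4, 5) %in% xp$nodes$id))   # through path
  expect_lt(nrow(xp$nodes), 9)                     # spurs removed

  # a clean isolated bifurcation is untouched
  expect_equal(prune_crossovers(y_neuron())$nodes, y_neuron()$nodes)
})

test_that("foreign-soma pruning cuts at the deviation-angle optimum", {
  # dumbbell: true soma at origin, path along +x, foreign soma at
  # (100,0,0); twigs split the connecting fibre into branches and the
  # segment nearer the foreign soma bulges, so its deviation integral
  # favours the foreign side and the cut lands between the twigs
  n <- 11
  xs <- seq(0, 100, length.out = n)
  ys <- c(0, 0, 0, 0, 0, 0, 12, 18, 12, 4, 0)  # bulge near foreign side
  nodes <- data.frame(id = 1:n, structure = c(1, rep(3, n - 1)),
                      x = xs, y = ys, z = 0,
                      radius = c(5, rep(.5, n - 2), 14),
                      parent = c(-1, seq_len(n - 1)))
  nodes <- rbind(nodes,
                 data.frame(id = n + 1, structure = 3, x = 30, y = 5,
                            z = 0, radius = .5, parent = 4),
                 data.frame(id = n + 2, structure = 3, x = 60, y = -5,
                            z = 0, radius = .5, parent = 7))
  db <- neuron_tree(nodes)
  pruned <- prune_foreign_somas(db)
  expect_lt(nrow(pruned$nodes), n + 2)
  expect_true(1 %in% pruned$nodes$id)
  expect_false(n %in% pruned$nodes$id)  # the foreign soma is gone

  # no large-radius nodes: unchanged
  clean <- y_neuron()
  expect_equal(prune_foreign_somas(clean)$nodes, clean$nodes)
})

test_that("winding pruning applies the path/Euclid ratio rule", {
  spiral <- function(total_len, chord) {
    # planar zig-zag from the root reaching `chord` with path
    # `total_len`
    n <- 21
    xs <- seq(0, chord, length.out = n)
    amp <- sqrt(max((total_len / (n - 1))^2 -
                      (chord / (n - 1))^2, 0)) * (n - 1) / 2
    ys <- rep(c(0, amp / (n / 2)), length.out = n) * rep(1, n)
    ys <- cumsum(c(0, rep(c(1, -1), length.out = n - 1))) *
      amp / (n / 2)
    neuron_tree(data.frame(id = 1:n, structure = c(1, rep(3, n - 1)),
                           x = xs, y = ys, z = 0, radius = .5,
                           parent = c(-1, seq_len(n - 1))))
  }
  # path 40, chord 10 -> ratio 4: removed (down to the root)
  s4 <- spiral(40, 10)
  p4 <- prune_winding(s4)
  expect_equal(nrow(p4$nodes), 1)
  # straight branch kept
  st <- line_tree(10, spacing = 5)
  expect_equal(nrow(prune_winding(st)$nodes), 10)
  # ratio exactly 3 is kept ("greater than three")
  tol_tree <- spiral(30, 10)
  lf <- local_branch_features(tol_tree)
  ratio <- lf$branches$br_length /
    max(lf$branches$br_length / 3, 1e-9)  # sanity on construction
  p3 <- prune_winding(spiral(29.999, 10))
  expect_equal(nrow(p3$nodes), 21)
})

test_that("curation intersects filters, reconnects, and discards", {
  # clean dendrite passes unchanged with an empty report
  clean <- line_tree(25, spacing = 5)
  out <- curate(clean)
  expect_equal(out$tree$nodes, clean$nodes)
  expect_true(all(out$report$removed == 0))
  expect_false(out$report$discard)

  # a 15-node survivor is flagged for discarding
  small <- line_tree(15)
  rep15 <- curate(small)
  expect_true(rep15$report$discard)
  rep25 <- curate(line_tree(25))
  expect_false(rep25$report$discard)

  # intersection semantics: curated nodes are a subset of every
  # individual filter's survivors; result stays root-connected
  tr <- branch_fixture(30)
  res <- curate(tr)
  for (f in list(prune_geometry(tr), prune_crossovers(tr),
                 prune_foreign_somas(tr), prune_winding(tr))) {
    expect_true(all(res$tree$nodes$id %in% f$nodes$id))
  }
  kept <- res$tree
  expect_silent(morphoscale:::validate_tree(kept))

  # each filter is idempotent on random trees
  for (seed in 1:5) {
    rt <- random_binary_tree(seed, 40)
    for (fn in list(prune_geometry, prune_crossovers, prune_winding)) {
      once <- fn(rt)
      expect_equal(fn(once)$nodes, once$nodes)
    }
  }
})
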