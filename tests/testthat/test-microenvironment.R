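test_that("the 24-feature vector has the documented composition", {
  f <- features24(y_neuron())
  expect_length(f, 24)
  excluded <- c("Nodes", "SomaSurface", "AverageDiameter", "Surface")
  expect_false(any(excluded %in% names(f)))
  expect_true(all(c("Length", "HausdorffDimension", "pc1_var",
                    "pc1_x") %in% names(f)))
  # straight dendrite: first PC explains everything
  fl <- features24(line_tree(5))
  expect_equal(unname(fl[c("pc1_var", "pc2_var", "pc3_var")]),
               c(1, 0, 0))
  # matches independent recomputation feature by feature
  for (seed in 1:10) {
    tr <- random_binary_tree(seed)
    f <- features24(tr)
    o <- oracle_morphometry(tr)$global
    keep <- setdiff(names(o), excluded)
    expect_true(rel_equal(f[keep], o[keep]),
                label = paste("seed", seed))
  }
})

test_that("microenvironment weights follow the exponential formula", {
  set.seed(2)
  feats <- matrix(rnorm(24 * 8), 8, 24,
                  dimnames = list(NULL, paste0("f", 1:24)))
  D <- 249
  # no neighbours in the sphere: the fused vector is the target itself
  soma_far <- rbind(c(0, 0, 0), matrix(5000, 7, 3))
  me <- build_microenvironment(1, feats, soma_far, D = D)
  expect_equal(me$member_idx, 1)
  expect_equal(me$weights, 1)
  expect_equal(me$fused, feats[1, ])

  # five neighbours at distance zero: every weight is 1/6
  soma0 <- matrix(0, 8, 3)
  me0 <- build_microenvironment(1, feats, soma0, D = D)
  expect_length(me0$weights, 6)
  expect_equal(me0$weights, rep(1 / 6, 6))

  # target at d = 0 with 5 neighbours at d = D:
  # w_target = 1/(1 + 5 e^-1)
  soma_d <- rbind(c(0, 0, 0),
                  D * rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                            c(0, -1, 0), c(0, 0, 1), c(0, 0, -1),
                            c(1, 0, 0)))
  me1 <- build_microenvironment(1, feats, soma_d, D = D)
  expect_equal(me1$weights[1], 1 / (1 + 5 * exp(-1)),
               tolerance = 1e-12)
  expect_equal(me1$weights[-1], rep(exp(-1) / (1 + 5 * exp(-1)), 5),
               tolerance = 1e-12)
  expect_equal(sum(me1$weights), 1, tolerance = 1e-12)
  expect_error(build_microenvironment(99, feats, soma0), "not found")
})

test_that("fused features stay in the member convex hull", {
  set.seed(3)
  feats <- matrix(rnorm(24 * 12), 12, 24)
  soma <- matrix(rnorm(36, sd = 100), 12, 3)
  for (t in 1:12) {
    me <- build_microenvironment(t, feats, soma)
    sub <- feats[me$member_idx, , drop = FALSE]
    expect_true(all(me$fused >= apply(sub, 2, min) - 1e-12))
    expect_true(all(me$fused <= apply(sub, 2, max) + 1e-12))
    expect_equal(sum(me$weights), 1, tolerance = 1e-15)
  }
  # distances equal (all somas coincide): fusion = arithmetic mean
  soma_same <- matrix(1, 12, 3)
  me <- build_microenvironment(3, feats, soma_same, D = 1e9)
  expect_equal(me$fused, colMeans(feats[me$member_idx, ]))
})

test_that("mRMR ranks informative features first and penalises copies", {
  set.seed(4)
  n <- 120
  labels <- rep(1:2, each = n / 2)
  sig <- labels + rnorm(n, 0, 0.1)     # near-perfect separator
  noise <- matrix(rnorm(n * 4), n)
  f <- cbind(sig = sig, noise)
  colnames(f) <- c("sig", paste0("noise", 1:4))
  expect_equal(mrmr_select(f, labels, k = 3)[1], "sig")

  # an exact duplicate of the first pick ranks below a weaker but
  # complementary feature
  weak <- labels + rnorm(n, 0, 0.6)
  f2 <- cbind(sig = sig, sig_copy = sig, weak = weak)
  sel <- mrmr_select(f2, labels, k = 2)
  expect_equal(sel, c("sig", "weak"))

  # k = all features returns a permutation of all names
  perm <- mrmr_select(f, labels, k = ncol(f))
  expect_setequal(perm, colnames(f))

  # constant features are excluded with a warning
  f3 <- cbind(f, flat = rep(1, n))
  expect_warning(sel3 <- mrmr_select(f3, labels, k = 3), "constant")
  expect_false("flat" %in% sel3)
})

test_that("RGB maps hit normalisation endpoints and mirror correctly", {
  atlas <- make_toy_atlas(n_regions = 4, dims = c(32, 32, 32), seed = 2)
  feats <- matrix(c(0, 5, 10,
                    0, 5, 10,
                    0, 5, 10), 3, 3)
  colnames(feats) <- c("a", "b", "c")
  soma <- matrix(c(100, 400, 700, 400, 400, 400, 400, 400, 400), 3, 3)
  rm <- rgb_map(feats, c("a", "b", "c"), soma, atlas)
  expect_equal(rm$points$R, c(0, 127.5, 255))
  # mirroring changes only right-hemisphere points
  rm2 <- rgb_map(feats, c("a", "b", "c"), soma, atlas, mirror = TRUE)
  mid <- atlas$dims[1] * atlas$voxel_size / 2
  left <- soma[, 1] <= mid
  expect_equal(rm2$points$vx[left], rm$points$vx[left])
  expect_true(all(rm2$points$vx[!left] != rm$points$vx[!left]))
  # MIP of coincident points takes the channel-wise maximum
  soma_co <- matrix(rep(c(400, 400, 400), each = 2), 2, 3)
  f2 <- matrix(c(0, 10, 10, 0, 5, 5), 2, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  rm3 <- rgb_map(f2, c("a", "b", "c"), soma_co, atlas)
  mip <- rm3$mips[[3]]
  vx <- rm3$points$vx[1] + 1
  vy <- rm3$points$vy[1] + 1
  expect_equal(mip[vx, vy, 1], 255)  # max over the two points
  expect_equal(mip[vx, vy, 2], 255)
})

test_that("region clustering separates planted feature regimes", {
  set.seed(5)
  n <- 60
  regions <- rep(1:6, each = 10)
  shift <- ifelse(regions <= 3, 0, 8)
  feats <- cbind(rnorm(n) + shift, rnorm(n) + shift, rnorm(n))
  colnames(feats) <- c("f1", "f2", "f3")
  cl <- region_clusters(feats, regions, k = 2, seed = 1)
  expect_equal(length(unique(cl[1:3])), 1)
  expect_equal(length(unique(cl[4:6])), 1)
  expect_false(cl[["1"]] == cl[["4"]])
  # deterministic under a fixed seed
  expect_identical(cl, region_clusters(feats, regions, k = 2, seed = 1))
  expect_error(region_clusters(feats, regions, k = 10), "exceeds")
})

test_that("path and radial profiles order and average correctly", {
  feats <- matrix(rep(c(1, 2, 3), each = 4), 12, 1,
                  dimnames = list(NULL, "f"))
  regions <- rep(c(7, 5, 9), each = 4)
  pp <- path_profile(feats, regions, path = c(5, 7, 9))
  expect_equal(pp$region, c(5, 7, 9))
  expect_equal(pp$f, c(2, 1, 3))
  # empty region flagged by n = 0
  pp2 <- path_profile(feats, regions, path = c(5, 99))
  expect_equal(pp2$n, c(4, 0))
  expect_true(is.na(pp2$f[2]))

  # constant features give a flat profile
  soma <- cbind(seq(0, 100, length.out = 12), 0, 0)
  rp <- radial_profile(matrix(1, 12, 1, dimnames = list(NULL, "f")),
                       soma, bins = 4)
  expect_equal(rp$f, rep(1, 4), ignore_attr = TRUE)
  # a planted gradient is monotone along the axis
  grad <- matrix(soma[, 1] * 2, 12, 1, dimnames = list(NULL, "f"))
  rp2 <- radial_profile(grad, soma, bins = 4)
  expect_true(all(diff(rp2$f) > 0))
})

test_that("fusion sharpens class separation of straightness features", {
  # two dendrite classes differing in direction persistence
  # (straightness); somas spatially clustered by class so neighbours
  # are same-class. The Fisher ratio of the contraction feature must
  # increase after microenvironment fusion, on average over seeds.
  fisher <- function(x, lab) {
    m <- tapply(x, lab, mean)
    v <- tapply(x, lab, var)
    (m[1] - m[2])^2 / (v[1] + v[2])
  }
  gains <- vapply(1:6, function(seed) {
    straight <- morph_class_params(kappa = 60, has_axon = FALSE)
    wiggly <- morph_class_params(kappa = 4, has_axon = FALSE)
    pop <- synth_population(list(straight, wiggly), n_per_class = 10,
                            soma_centers = list(c(0, 0, 0),
                                                c(1200, 0, 0)),
                            soma_spread = 120, seed = seed)
    f24 <- feature_table(pop$trees, features24)
    me <- microenvironment_table(f24, pop$soma)
    raw <- fisher(f24[, "AverageContraction"], pop$labels)
    fused <- fisher(me$fused[, "AverageContraction"], pop$labels)
    fused / raw
  }, 1)
  expect_gt(mean(gains > 1), 0.5)
  expect_gt(mean(gains), 1)
})
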