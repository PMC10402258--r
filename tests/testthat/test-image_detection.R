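const_block <- function(value, dims = c(16, 16, 16)) {
  image_block(array(value, dims))
}

test_that("foreground threshold follows the printed formula", {
  # construct blocks with prescribed mean and sd
  mk <- function(mu, sigma) {
    n <- 4096
    x <- rep(c(mu - sigma, mu + sigma), n / 2)
    x <- x * sqrt(n / (n - 1))  # sample-sd correction
    x <- (x - mean(x)) / sd(x) * sigma + mu
    image_block(array(x, c(16, 16, 16)))
  }
  expect_equal(foreground_threshold(mk(100, 100)), 360)
  expect_equal(foreground_threshold(mk(1000, 400)), 900)
  # sigma = 0
  expect_equal(foreground_threshold(const_block(500)),
               0.9 * min(max(500, 400), 1000))
  expect_equal(foreground_threshold(const_block(2000)), 900)
})

test_that("anisotropy score separates lines from balls", {
  dims <- c(32, 32, 32)
  line <- array(0, dims)
  line[4:29, 16, 16] <- 1000
  s1 <- anisotropy_salience(image_block(line))
  expect_gt(max(s1$score), 0.9)

  ball <- array(0, dims)
  ctr <- c(16, 16, 16)
  for (dx in -5:5) for (dy in -5:5) for (dz in -5:5) {
    if (dx^2 + dy^2 + dz^2 <= 25) {
      ball[16 + dx, 16 + dy, 16 + dz] <- 1000
    }
  }
  s2 <- anisotropy_salience(image_block(ball))
  expect_lt(max(s2$score), 0.2)

  # score is rotation tolerant: diagonal line scores like an axial one
  diag_line <- array(0, dims)
  for (i in 4:29) diag_line[i, i, 16] <- 1000
  s3 <- anisotropy_salience(image_block(diag_line))
  expect_lt(abs(max(s3$score) - max(s1$score)), 0.05)
})

test_that("neurite segmentation is gated, monotone, and recovers tubes", {
  # block below the pre-filter yields an empty mask
  set.seed(1)
  noise <- array(pmax(rnorm(16^3, 100, 30), 0), c(16, 16, 16))
  expect_false(any(segment_neurites(image_block(noise))))

  nd <- data.frame(id = 1:3, structure = 2, x = c(5, 32, 58),
                   y = c(20, 32, 48), z = c(30, 32, 35), radius = .8,
                   parent = c(-1, 1, 2))
  tr <- neuron_tree(nd, validate = FALSE)
  rv <- render_volume(list(tr), dims = c(64, 64, 64), snr = 10,
                      seed = 3)
  rv0 <- render_volume(list(tr), dims = c(64, 64, 64), snr = Inf,
                       background = 0)
  core <- rv0$block$data >= 750       # half peak
  support <- rv0$block$data >= 15     # 1 percent of peak
  mask <- segment_neurites(rv$block)
  expect_gte(sum(mask & core) / sum(core), 0.9)
  expect_gte(sum(mask & support) / sum(mask), 0.8)

  # monotone: raising the threshold never adds voxels
  th <- foreground_threshold(rv$block)
  m_hi <- segment_neurites(rv$block, thresh = th * 1.5)
  expect_true(all(mask | !m_hi))
  # determinism
  expect_identical(mask, segment_neurites(rv$block))
})

test_that("regional density vectors count mask voxels per region", {
  atlas <- make_toy_atlas(n_regions = 6, dims = c(32, 32, 32), seed = 1)
  # mask fully inside one region
  w <- which(atlas$volume == 3, arr.ind = TRUE)
  mask <- array(FALSE, dim(atlas$volume))
  mask[w[1:20, ]] <- TRUE
  v <- neurite_density_vector(mask, atlas)
  expect_equal(unname(v["3"]), 1)
  expect_equal(sum(v), 1)

  # 60/40 split across two regions
  w4 <- which(atlas$volume == 4, arr.ind = TRUE)
  mask2 <- array(FALSE, dim(atlas$volume))
  mask2[w[1:60, ]] <- TRUE
  mask2[w4[1:40, ]] <- TRUE
  v2 <- neurite_density_vector(mask2, atlas)
  expect_equal(unname(v2[c("3", "4")]), c(0.6, 0.4))

  expect_error(neurite_density_vector(array(FALSE, c(8, 8, 8)), atlas),
               "dimensions")
})

test_that("gray-scale distance transform reduces to EDT when uniform", {
  mask <- array(FALSE, c(24, 24, 24))
  for (dx in -6:6) for (dy in -6:6) for (dz in -6:6) {
    if (dx^2 + dy^2 + dz^2 <= 36) mask[12 + dx, 12 + dy, 12 + dz] <- TRUE
  }
  dt <- gsdt(mask)                        # no weights: plain EDT
  dtw <- gsdt(mask, weights = array(1, dim(mask)))
  expect_equal(dt, dtw)
  # centre value approximates the radius (chamfer metric)
  expect_gt(dt[12, 12, 12], 5.5)
  expect_lt(dt[12, 12, 12], 7.5)
  expect_equal(dt[!mask], rep(0, sum(!mask)))
})

test_that("soma detection finds isolated and resolves close spheres", {
  # single sphere: exactly one candidate near the centre
  sf <- synth_soma_field(n = 1, dims = c(64, 64, 64), seed = 7)
  cand <- detect_somas(sf$block)
  expect_equal(nrow(cand), 1)
  expect_lt(sqrt(sum((as.numeric(cand[1, 1:3]) - sf$centers[1, ])^2)),
            2)

  # empty (noise-only, low max) volume: no candidates
  set.seed(8)
  dark <- image_block(array(pmax(rnorm(32^3, 80, 20), 0),
                            c(32, 32, 32)))
  expect_equal(nrow(detect_somas(dark)), 0)

  # two spheres far apart survive as 2; spheres 5 voxels apart fuse
  # into one blob and collapse to a single soma after suppression and
  # the mean-shift duplicate stage
  two <- function(sep, r) {
    acc <- array(0, c(64, 64, 64))
    acc <- morphoscale:::stamp_sphere(acc, c(32 - sep / 2, 32, 32), r,
                                      2000)
    acc <- morphoscale:::stamp_sphere(acc, c(32 + sep / 2, 32, 32), r,
                                      2000)
    set.seed(3)
    image_block(pmin(pmax(acc + 100 + rnorm(length(acc), 0, 250), 0),
                     65535))
  }
  b40 <- two(40, 5)
  expect_equal(nrow(refine_somas(detect_somas(b40), b40)), 2)
  b5 <- two(5, 4)
  expect_equal(nrow(refine_somas(detect_somas(b5), b5)), 1)
})

test_that("mean-shift refinement centres and deduplicates candidates", {
  sf <- synth_soma_field(n = 1, dims = c(64, 64, 64), seed = 9)
  ctr <- sf$centers[1, ]
  # candidate offset by 5 voxels converges to within 1 voxel
  off <- data.frame(cx = ctr[1] + 5, cy = ctr[2], cz = ctr[3],
                    score = 1, refined = FALSE)
  ref <- refine_somas(off, sf$block)
  expect_lt(sqrt(sum((as.numeric(ref[1, 1:3]) - ctr)^2)), 1)

  # duplicate pair within 15 voxels with a dim midpoint merges to one
  acc <- array(0, c(64, 64, 64))
  acc <- morphoscale:::stamp_sphere(acc, c(26, 32, 32), 2.5, 2000)
  acc <- morphoscale:::stamp_sphere(acc, c(38, 32, 32), 2.5, 1500)
  blk <- image_block(acc + 100)
  cand <- data.frame(cx = c(26, 38), cy = 32, cz = 32, score = 1,
                     refined = FALSE)
  ref2 <- refine_somas(cand, blk)
  expect_equal(nrow(ref2), 1)
  # the brighter sphere survives
  expect_lt(abs(ref2$cx[1] - 26), 1.5)

  # mean shift is a fixed point at the centroid of a symmetric sphere
  at_ctr <- data.frame(cx = 26, cy = 32, cz = 32, score = 1,
                       refined = FALSE)
  ref3 <- refine_somas(at_ctr, blk)
  expect_lt(sqrt(sum((as.numeric(ref3[1, 1:3]) - c(26, 32, 32))^2)),
            0.2)
})

test_that("profile sampling recovers tube radii and planted bumps", {
  nd <- data.frame(id = 1:2, structure = 2, x = c(8, 56), y = 32,
                   z = 32, radius = 1.5, parent = c(-1, 1))
  tr <- neuron_tree(nd, validate = FALSE)
  rv <- render_volume(list(tr), dims = c(64, 64, 64), snr = Inf,
                      tube_sigma = 1.5, background = 0)
  rt <- resample_tree(tr, 4)
  prof <- sample_profiles(rt, rv$block)
  inside <- !prof$outside & prof$intensity > 100
  expect_gt(sum(inside), 5)
  # constant-radius tube: radius profile constant within half a voxel
  r <- prof$radius[inside]
  expect_lt(diff(range(r)), 1.0)

  # node in background reads (near) zero intensity
  bg <- neuron_tree(data.frame(id = 1, structure = 2, x = 5, y = 5,
                               z = 5, radius = 1, parent = -1),
                    validate = FALSE)
  pb <- sample_profiles(bg, rv$block)
  expect_lt(pb$intensity[1], 10)

  # node outside the volume is flagged
  out <- neuron_tree(data.frame(id = 1, structure = 2, x = 1000,
                                y = 0, z = 0, radius = 1, parent = -1),
                     validate = FALSE)
  po <- sample_profiles(out, rv$block)
  expect_true(po$outside[1])
  expect_equal(po$intensity[1], 0)
})

test_that("TIFF stacks round-trip through the block container", {
  set.seed(5)
  arr <- array(sample(0:65535, 8 * 8 * 8, TRUE), c(8, 8, 8))
  blk <- image_block(arr)
  f <- tempfile(fileext = ".tif")
  write_tiff_block(blk, f)
  blk2 <- read_tiff_block(f)
  expect_equal(blk2$data, blk$data, tolerance = 1)
})
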