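# Small deterministic skeleton fixtures used across the suite.

# soma -> (10,0,0) -> (20,0,0) bifurcating into tips (20, +-10, 0)
y_neuron <- function() {
  neuron_tree(data.frame(
    id = 1:5, structure = c(1, 3, 3, 3, 3),
    x = c(0, 10, 20, 20, 20), y = c(0, 0, 0, 10, -10), z = 0,
    radius = c(5, 0.5, 0.5, 0.5, 0.5), parent = c(-1, 1, 2, 3, 3)))
}

# unbranched chain of n nodes along +x at the given spacing
line_tree <- function(n = 3, spacing = 10, structure = 3) {
  neuron_tree(data.frame(
    id = seq_len(n), structure = c(1, rep(structure, n - 1)),
    x = (seq_len(n) - 1) * spacing, y = 0, z = 0, radius = 0.5,
    parent = c(-1, seq_len(n - 1))))
}

# a single branch tracing a semicircle of the given radius in the xy
# plane, sampled at `pts` points (soma at the arc start)
semicircle_tree <- function(radius = 10, pts = 10) {
  th <- seq(0, pi, length.out = pts)
  neuron_tree(data.frame(
    id = seq_len(pts), structure = c(1, rep(3, pts - 1)),
    x = radius * cos(th), y = radius * sin(th), z = 0, radius = 0.5,
    parent = c(-1, seq_len(pts - 1))))
}

# random single-stem binary tree with <= n_max nodes, jittered
# coordinates and positive radii; grown by random attachment
random_binary_tree <- function(seed, n_max = 50) {
  set.seed(seed)
  nodes <- data.frame(id = 1L, structure = 1L, x = 0, y = 0, z = 0,
                      radius = runif(1, 2, 5), parent = -1L)
  # open ends available for extension (start with one stem)
  grow_from <- function(pid) {
    prow <- nodes[nodes$id == pid, ]
    p <- c(prow$x, prow$y, prow$z) + rnorm(3, 0, 8)
    id <- nrow(nodes) + 1L
    nodes[id, ] <<- list(id, 3L, p[1], p[2], p[3], runif(1, .2, 1.5),
                         pid)
    id
  }
  open <- grow_from(1L)
  while (nrow(nodes) < n_max - 1 && length(open)) {
    i <- sample(length(open), 1)
    pid <- open[i]
    open <- open[-i]
    act <- sample(c("tip", "extend", "bifurcate"), 1,
                  prob = c(0.25, 0.5, 0.25))
    if (act == "extend") open <- c(open, grow_from(pid))
    if (act == "bifurcate") {
      open <- c(open, grow_from(pid), grow_from(pid))
    }
  }
  neuron_tree(nodes)
}

# density matrix with two planted modules, optional noise
two_module_matrix <- function(noise = 0, n_brains = 10, seed = 1) {
  set.seed(seed)
  loading1 <- rlnorm(n_brains)
  loading2 <- rlnorm(n_brains)
  v <- rbind(1.0 * loading1, 2.0 * loading1, 0.5 * loading1,
             1.5 * loading2, 0.7 * loading2, 1.1 * loading2)
  if (noise > 0) v <- v + matrix(abs(rnorm(length(v), 0, noise)),
                                 nrow(v))
  v <- sweep(v, 2, colSums(v), "/")
  list(values = v, labels = c(1, 1, 1, 2, 2, 2))
}

# straight main path along +x with an attachable side branch; the
# side branch leaves the junction at (20,0,0) with direction `ang_deg`
# relative to straight continuation (180 = straight on)
branch_fixture <- function(ang_deg, child_radius = 0.5,
                           parent_radius = 0.5, wiggle = NULL) {
  th <- (180 - ang_deg) * pi / 180
  dir <- c(cos(th), sin(th), 0)
  p1 <- c(20, 0, 0) + 10 * dir
  p2 <- c(20, 0, 0) + 20 * dir
  neuron_tree(data.frame(
    id = 1:7, structure = c(1, rep(3, 6)),
    x = c(0, 10, 20, 30, 40, p1[1], p2[1]),
    y = c(0, 0, 0, 0, 0, p1[2], p2[2]),
    z = 0,
    radius = c(5, parent_radius, parent_radius, parent_radius,
               parent_radius, child_radius, child_radius),
    parent = c(-1, 1, 2, 3, 4, 3, 6)))
}
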