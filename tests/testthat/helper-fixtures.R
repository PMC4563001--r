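# Shared fixtures: small geometries, polylines and trees built in code.

default_geom <- function(...) projection_geometry(...)

# Right-angle 2D polyline (0,0) -> (10,0) -> (10,10), tip at the origin.
right_angle <- function() {
  data.frame(x_mm = c(0, 10, 10), y_mm = c(0, 0, 10))
}

# A 3-node vertical chain rooted at node 1.
chain_tree <- function(n = 3, step = 10) {
  vessel_tree(data.frame(
    id = seq_len(n), x_mm = 0, y_mm = (seq_len(n) - 1) * step, z_mm = 0,
    parent_id = c(NA, seq_len(n - 1))))
}

# Y-shaped tree: trunk of `trunk_n` nodes then two diverging branches.
y_tree <- function(trunk_n = 5, branch_n = 4, step = 6) {
  ids <- seq_len(trunk_n)
  nodes <- data.frame(id = ids, x_mm = 0, y_mm = (ids - 1) * step, z_mm = 0,
                      parent_id = c(NA, ids[-trunk_n]))
  top <- (trunk_n - 1) * step
  for (b in 1:2) {
    sgn <- if (b == 1) 1 else -1
    prev <- trunk_n
    for (j in seq_len(branch_n)) {
      id <- trunk_n + (b - 1) * branch_n + j
      nodes <- rbind(nodes, data.frame(
        id = id, x_mm = sgn * j * step * 0.7, y_mm = top + j * step * 0.7,
        z_mm = 0, parent_id = prev))
      prev <- id
    }
  }
  vessel_tree(nodes)
}

# Perfect binary tree of given depth embedded in 3D (ids breadth-first).
binary_tree <- function(depth = 3, step = 8) {
  nodes <- data.frame(id = 1, x_mm = 0, y_mm = 0, z_mm = 0, parent_id = NA)
  next_id <- 2
  frontier <- data.frame(id = 1, x = 0, y = 0, ang = pi / 2)
  for (d in seq_len(depth)) {
    nf <- NULL
    for (r in seq_len(nrow(frontier))) {
      for (s in c(-1, 1)) {
        ang <- frontier$ang[r] + s * 0.5 / d
        x <- frontier$x[r] + step * cos(ang)
        y <- frontier$y[r] + step * sin(ang)
        nodes <- rbind(nodes, data.frame(id = next_id, x_mm = x, y_mm = y,
                                         z_mm = d, parent_id = frontier$id[r]))
        nf <- rbind(nf, data.frame(id = next_id, x = x, y = y, ang = ang))
        next_id <- next_id + 1
      }
    }
    frontier <- nf
  }
  vessel_tree(nodes)
}

# Random tree with n nodes: each new node attaches to a uniformly chosen
# previous node, coordinates jittered so edges are non-degenerate.
random_tree <- function(n, seed) {
  withr::with_seed(seed, {
    parent <- c(NA, vapply(2:n, function(i) sample.int(i - 1, 1), integer(1)))
    xyz <- matrix(0, n, 3)
    for (i in 2:n) {
      xyz[i, ] <- xyz[parent[i], ] + stats::rnorm(3, sd = 4) + c(0, 2, 0)
    }
    vessel_tree(data.frame(id = seq_len(n), x_mm = xyz[, 1], y_mm = xyz[, 2],
                           z_mm = xyz[, 3], parent_id = parent))
  })
}

# A small simulated case on a seeded synthetic tree; returns everything a
# registration test needs.
make_sim_case <- function(seed = 7, pose = NULL, sigma_simu = 0, z_mm = 0,
                          spacing = 3, tip_rank = 3) {
  geom <- projection_geometry()
  tree <- generate_tree(tree_spec(seed = seed))
  rtree <- resample_tree(tree, spacing)
  arc <- cathreg:::node_root_arc(rtree)
  pool <- names(arc)[arc >= 120]
  tip <- pool[min(tip_rank, length(pool))]
  rc <- cathreg:::tree_bbox_center(rtree)
  if (is.null(pose)) pose <- pose_5dof(rotation_center = rc)
  sim <- simulate_catheter(rtree, tip, pose, geom, sigma_simu = sigma_simu,
                           z_mm = z_mm)
  list(geom = geom, tree = rtree, sim = sim, rc = rc, pose_true = pose)
}
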