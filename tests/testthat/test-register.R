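test_that("the tip weight is a Gaussian with an offset", {
  expect_equal(tip_weight(0, 0.2, 20), 1)
  expect_equal(tip_weight(1e6, 0.2, 20), 0.2)
  # direct scalar evaluation of the formula
  expect_equal(tip_weight(20, 0.2, 20), 0.2 + 0.8 * exp(-0.5), tolerance = 1e-12)
  x <- seq(0, 300, 10)
  w <- tip_weight(x, 0.1, 80)
  expect_true(all(w >= 0.1 & w <= 1))
  expect_true(all(diff(w) <= 0))
})

test_that("tip_distance is the minimum over all projected path points", {
  geom <- default_geom()
  path <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0))
  proj <- as.matrix(project_path(path, diag(4), geom))
  cath <- rbind(c(3, 1), c(6, 1))
  got <- tip_distance(cath, path, pose_5dof(), geom)
  d_all <- sqrt(rowSums(sweep(proj, 2, cath[1, ])^2))
  expect_equal(got$distance_mm, min(d_all))
  expect_equal(got$index, which.min(d_all))
  # coincident tip
  got0 <- tip_distance(rbind(proj[2, ], proj[3, ]), path, pose_5dof(), geom)
  expect_equal(got0$distance_mm, 0)
})

test_that("windowed_distance enumerates only the in-window points", {
  geom <- default_geom()
  # hairpin: the path doubles back so the global closest vertex is far
  # beyond the window
  path <- cbind(c(seq(0, 30, 3), seq(30, 0, -3)),
                c(rep(0, 11), rep(4, 11)), 0)
  proj <- as.matrix(project_path(path, diag(4), geom))
  arc <- c(0, cumsum(sqrt(rowSums(diff(proj)^2))))
  c_i <- proj[1, ] + c(0, 4)   # closer to the far return leg than the start
  got <- windowed_distance(c_i, path, pose_5dof(), geom, prev_index = 1,
                           d_max = 10)
  # oracle: enumerate vertices whose arc from the anchor is within d_max
  in_win <- which(arc - arc[1] <= 10)
  d_win <- sqrt(rowSums(sweep(proj[in_win, , drop = FALSE], 2, c_i)^2))
  expect_equal(got$distance_mm, min(d_win))
  expect_equal(got$index, in_win[which.min(d_win)])
  # the global minimum (on the return leg) is strictly better
  d_all <- sqrt(rowSums(sweep(proj, 2, c_i)^2))
  expect_lt(min(d_all), got$distance_mm)

  # with d_max covering everything it equals the unconstrained minimum
  # over the remainder
  got_all <- windowed_distance(c_i, path, pose_5dof(), geom, prev_index = 1,
                               d_max = 1e6)
  expect_equal(got_all$distance_mm, min(d_all))
})

test_that("the metric vanishes on a perfect overlay and composes by hand", {
  geom <- default_geom()
  cfg <- metric_config(lambda = 0.2, sigma = 20, d_max = 40, sampling = 3)
  path <- data.frame(x_mm = seq(0, 60, 3), y_mm = 5 * sin(seq(0, 60, 3) / 15),
                     z_mm = 0)
  cath <- project_path(path, diag(4), geom)
  res <- registration_metric(cath, path, pose_5dof(), geom, cfg)
  expect_equal(res$metric_mm, 0, tolerance = 1e-9)
  expect_true(all(diff(res$correspondences) >= 0))

  # two-point catheter against a straight projected line y = 0:
  # distances 2 and 3 at catheter arc 3
  straight <- data.frame(x_mm = seq(-40, 40, 2), y_mm = 0, z_mm = 0)
  cath2 <- rbind(c(0, 2), c(3, -3))
  m <- registration_metric(cath2, straight, pose_5dof(), geom, cfg)$metric_mm
  arc12 <- sqrt(sum((cath2[2, ] - cath2[1, ])^2))
  expect_equal(m, 2 + tip_weight(arc12, 0.2, 20) * 3, tolerance = 1e-9)
})

test_that("decreasing one matched distance decreases the metric", {
  geom <- default_geom()
  cfg <- metric_config()
  straight <- data.frame(x_mm = seq(-40, 40, 2), y_mm = 0, z_mm = 0)
  cath_far <- rbind(c(0, 2), c(3, -3))
  cath_near <- rbind(c(0, 2), c(3, -1))
  expect_lt(registration_metric(cath_near, straight, pose_5dof(), geom, cfg)$metric_mm,
            registration_metric(cath_far, straight, pose_5dof(), geom, cfg)$metric_mm)
})

test_that("compiled and reference metric engines agree", {
  geom <- default_geom()
  cfg <- metric_config_brute()
  withr::with_seed(17, {
    for (k in 1:8) {
      path <- data.frame(x_mm = cumsum(stats::rnorm(30, 1, 2)),
                         y_mm = cumsum(stats::rnorm(30, 1, 2)),
                         z_mm = cumsum(stats::rnorm(30, 0, 1)))
      cath <- matrix(stats::rnorm(20, sd = 30), ncol = 2)
      cath <- cath[order(cath[, 1]), ]
      pose <- pose_5dof(stats::runif(1, -10, 10), stats::runif(1, -10, 10),
                       stats::runif(1, -10, 10), stats::runif(1, -30, 30),
                       stats::runif(1, -30, 30))
      a <- registration_metric(cath, path, pose, geom, cfg, engine = "cpp")
      b <- registration_metric(cath, path, pose, geom, cfg, engine = "r")
      expect_equal(a$metric_mm, b$metric_mm, tolerance = 1e-9)
      expect_equal(a$correspondences, b$correspondences)
      expect_true(all(diff(a$correspondences) >= 0))
    }
  })
})

test_that("degenerate projections are signalled by the metric", {
  geom <- default_geom()
  path <- data.frame(x_mm = 0, y_mm = c(0, 10), z_mm = -geom$sod_mm - 5)
  expect_error(
    registration_metric(rbind(c(0, 0), c(3, 0)), path, pose_5dof(), geom,
                        metric_config()),
    "degenerate")
})

test_that("grid refinement solves separable surrogates to schedule accuracy", {
  # convex surrogate: sum of squared parameter errors, optimum inside s0
  target <- c(3, -2, 5, 17, -28)
  fn <- function(p) sum((p - target)^2)
  half <- c(7, 7, 7, 50, 50)
  res <- cathreg:::grid_refine(fn, rep(0, 5), half, 7, 0.5, 7)
  final_half <- half * 0.5^6
  expect_true(all(abs(res$par - target) <= final_half + 1e-9))
  expect_true(all(diff(res$trace) <= 0))

  # optimum outside the searched region: the result clamps to the
  # reachable span (sum of the shrinking half-intervals)
  fn1 <- function(p) (p - 60)^2
  res1 <- cathreg:::grid_refine(fn1, 0, 20, 7, 0.5, 7)
  reach <- sum(20 * 0.5^(0:6))
  expect_lte(res1$par, reach + 1e-9)
  expect_gt(res1$par, 20)   # walked beyond the initial interval, toward 60
})

test_that("compiled brute force equals the reference grid refinement", {
  case <- make_sim_case(seed = 13, pose = NULL)
  cfg <- metric_config_brute()
  path <- path_to_root(case$tree, case$sim$tip_node)
  sch <- brute_force_schedule(n_iterations = 3, steps_per_dim = 5)
  fit <- optimize_brute_force(case$sim$catheter, path, case$geom, cfg,
                              schedule = sch, rotation_center = case$rc)
  cath_m <- cathreg:::as_points2(case$sim$catheter)
  fn <- function(p) {
    pose <- pose_5dof(p[1], p[2], p[3], p[4], p[5], rotation_center = case$rc)
    registration_metric(cath_m, path, pose, case$geom, cfg)$metric_mm
  }
  ref <- cathreg:::grid_refine(fn, rep(0, 5), c(7, 7, 7, 50, 50), 3, 0.5, 5)
  expect_equal(fit$metric_mm, ref$value, tolerance = 1e-9)
  expect_equal(c(fit$pose$alpha, fit$pose$beta, fit$pose$gamma,
                 fit$pose$x, fit$pose$y), unname(ref$par), tolerance = 1e-9)
  expect_equal(fit$trace, ref$trace, tolerance = 1e-9)
})

test_that("brute force self-registers a zero-pose catheter", {
  case <- make_sim_case(seed = 5)
  reg <- register_catheter(case$sim$catheter, case$tree, case$geom,
                           optimizer = "brute_force", resample = FALSE)
  expect_lt(reg$metric_mm, 1)
  expect_true(all(diff(reg$candidates$s_max) <= 1e-9))
  err <- tip_errors(case$sim$true_tip_mm,
                    project_point(case$sim$tip_xyz, reg$pose, case$geom),
                    case$sim$tip_direction)
  expect_lt(err$e_d, 1)
})

test_that("brute force incumbent metric is non-increasing", {
  case <- make_sim_case(seed = 29,
                        pose = pose_5dof(2, -1, 3, x = 12, y = -18))
  cfg <- metric_config_brute()
  path <- path_to_root(case$tree, case$sim$tip_node)
  fit <- optimize_brute_force(case$sim$catheter, path, case$geom, cfg,
                              rotation_center = case$rc)
  expect_length(fit$trace, 7)
  expect_true(all(diff(fit$trace) <= 0))
})

test_that("Powell's method solves a quadratic surrogate", {
  target <- c(1.5, -2.5, 0.5)
  fn <- function(p) sum((p - target)^2) + 3
  res <- cathreg:::powell_minimize(fn, c(0, 0, 0), scale = c(5, 5, 5))
  expect_true(res$converged)
  expect_equal(res$par, target, tolerance = 1e-3)
  expect_equal(res$value, 3, tolerance = 1e-4)
})

test_that("Powell returns an already-optimal initial pose unchanged", {
  case <- make_sim_case(seed = 5)
  cfg <- metric_config_powell()
  path <- path_to_root(case$tree, case$sim$tip_node)
  fit <- optimize_powell(case$sim$catheter, path, case$geom, cfg,
                         init = pose_5dof(rotation_center = case$rc))
  expect_lt(abs(fit$pose$x), 0.5)
  expect_lt(abs(fit$pose$y), 0.5)
  expect_lt(fit$metric_mm, 0.5)
})

test_that("Powell stage 1 recovers a pure in-plane shift", {
  shift <- pose_5dof(x = 22, y = -31)
  case <- make_sim_case(seed = 19, pose = shift)
  cfg <- metric_config_powell()
  path <- path_to_root(case$tree, case$sim$tip_node)
  fit <- optimize_powell(case$sim$catheter, path, case$geom, cfg,
                         init = pose_5dof(rotation_center = case$rc),
                         rotation_center = case$rc)
  expect_equal(fit$pose$x, 22, tolerance = 0.5)
  expect_equal(fit$pose$y, -31, tolerance = 0.5)
  expect_lt(fit$metric_mm, 1)
})

test_that("register_catheter recovers a known in-range pose", {
  truth <- pose_5dof(alpha = 3, beta = -2, gamma = 4, x = 18, y = -12)
  case <- make_sim_case(seed = 3, pose = truth)
  # the experiment protocol's rotation center: the origin corner of a
  # 250 mm volume centered on the tree
  reg <- register_catheter(case$sim$catheter, case$tree, case$geom,
                           optimizer = "brute_force", resample = "catheter",
                           rotation_center = case$rc + c(-125, -125, -125))
  err <- tip_errors(case$sim$true_tip_mm,
                    project_point(case$sim$tip_xyz, reg$pose, case$geom),
                    case$sim$tip_direction)
  expect_lt(err$e_d, 2)
  expect_s3_class(tidy(reg), "tbl_df")
  expect_equal(nrow(glance(reg)), 1)
})

test_that("k = 1 equals optimizing only the top-ranked candidate", {
  case <- make_sim_case(seed = 23)
  full <- register_catheter(case$sim$catheter, case$tree, case$geom,
                            optimizer = "powell", resample = FALSE)
  only1 <- register_catheter(case$sim$catheter, case$tree, case$geom,
                             optimizer = "powell", k = 1, resample = FALSE)
  expect_equal(nrow(only1$candidates), 1)
  expect_equal(only1$candidates$leaf_id, full$candidates$leaf_id[1])
  expect_equal(only1$candidates$metric_mm, full$candidates$metric_mm[1],
               tolerance = 1e-9)
})

test_that("the occupied branch of a Y-tree wins registration", {
  geom <- default_geom()
  yt <- resample_tree(y_tree(trunk_n = 18, branch_n = 12, step = 6), 3)
  leaves <- tree_leaves(yt)
  occupied <- leaves[1]
  sim <- simulate_catheter(yt, occupied, pose_5dof(x = 5, y = -4), geom)
  reg <- register_catheter(sim$catheter, yt, geom, optimizer = "powell",
                           resample = FALSE)
  expect_equal(reg$best_leaf_id, occupied)
  # exhaustive oracle: optimize both leaf paths directly
  cfg <- metric_config_powell()
  ms <- vapply(leaves, function(l) {
    optimize_powell(resample_centerline(sim$catheter, cfg$sampling),
                    path_to_root(yt, l), geom, cfg,
                    init = pose_5dof(rotation_center = tree_bbox_center(yt)))$metric_mm
  }, numeric(1))
  expect_equal(names(which.min(ms)), occupied)
})
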