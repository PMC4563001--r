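test_that("tree generation is deterministic per seed", {
  a <- generate_tree(tree_spec(seed = 42))
  b <- generate_tree(tree_spec(seed = 42))
  expect_identical(a$nodes, b$nodes)
  c <- generate_tree(tree_spec(seed = 43))
  expect_false(identical(a$nodes, c$nodes))
})

test_that("branching controls the leaf count", {
  # no branching, no aorta continuation: a single chain
  chain <- generate_tree(tree_spec(branch_probability = 0,
                                   aorta_continuation_mm = 0, seed = 1))
  expect_length(tree_leaves(chain), 1)
  # full binary branching: 2^n hepatic leaves
  full <- generate_tree(tree_spec(n_generations = 3, branch_probability = 1,
                                  aorta_continuation_mm = 0, seed = 2))
  expect_length(tree_leaves(full), 8)
  # the default adds one childless aorta-continuation leaf
  full2 <- generate_tree(tree_spec(n_generations = 3, branch_probability = 1,
                                   seed = 2))
  expect_length(tree_leaves(full2), 9)
})

test_that("generated trees satisfy the tree invariants and are centered", {
  tree <- generate_tree(tree_spec(seed = 11))
  expect_s3_class(tree, "vessel_tree")   # constructor enforces invariants
  expect_gte(length(tree_leaves(tree)), 1)
  expect_equal(tree_bbox_center(tree), c(0, 0, 0), tolerance = 1e-9)
})

test_that("the perturbation sets match their stated ranges", {
  slight <- perturbation_spec("slight")
  moderate <- perturbation_spec("moderate")
  large <- perturbation_spec("large")
  expect_equal(slight$ty_range, rbind(c(-20, 20)))
  expect_equal(moderate$ty_range, rbind(c(-40, -20), c(20, 40)))
  expect_equal(large$ty_range, rbind(c(-50, -40), c(40, 50)))
  expect_equal(slight$sigma_simu_range, c(1, 5))
  expect_equal(large$sigma_simu_range, c(10, 15))
  for (s in list(slight, moderate, large)) {
    expect_equal(s$tx_range, rbind(c(-30, 30)))
    expect_equal(s$tz_range, rbind(c(-30, 30)))
    expect_equal(s$angle_range, rbind(c(-6, 6)))
  }
})

test_that("random poses stay inside their ranges (Monte-Carlo)", {
  draws <- withr::with_seed(8, {
    lapply(1:2000, function(i) random_pose(perturbation_spec("moderate")))
  })
  ty <- vapply(draws, function(d) d$pose$y, numeric(1))
  expect_true(all(abs(ty) >= 20 & abs(ty) <= 40))
  tx <- vapply(draws, function(d) d$pose$x, numeric(1))
  expect_true(all(abs(tx) <= 30))
  ang <- vapply(draws, function(d) d$pose$alpha, numeric(1))
  expect_true(all(abs(ang) <= 6))
  sig <- vapply(draws, function(d) d$sigma_simu, numeric(1))
  expect_true(all(sig >= 5 & sig <= 10))
  zs <- vapply(draws, function(d) d$z_mm, numeric(1))
  expect_true(all(abs(zs) <= 30))

  s_draws <- withr::with_seed(9, {
    vapply(1:10000, function(i) random_pose(perturbation_spec("slight"))$pose$y,
           numeric(1))
  })
  expect_true(all(abs(s_draws) <= 20))
  # mean of a U(-20,20) draw: 0 within 3 standard errors
  se <- 40 / sqrt(12) / sqrt(length(s_draws))
  expect_lt(abs(mean(s_draws)), 3 * se)
  # seeded draws reproduce
  expect_identical(random_pose(perturbation_spec("large"), seed = 5),
                   random_pose(perturbation_spec("large"), seed = 5))
})

test_that("an unsmoothed simulated catheter is exactly the projected path", {
  case <- make_sim_case(seed = 5)
  path <- path_to_root(case$tree, case$sim$tip_node)
  proj <- project_path(path, compose_pose(case$pose_true, case$geom), case$geom)
  expect_equal(unname(as.matrix(cathreg:::as_points2(case$sim$catheter))),
               unname(as.matrix(proj)), tolerance = 1e-12)
  expect_equal(case$sim$true_tip_mm, unlist(proj[1, ], use.names = FALSE))
})

test_that("smoothing a straight catheter changes nothing", {
  geom <- default_geom()
  tree <- resample_tree(vessel_tree(data.frame(
    id = 1:2, x_mm = c(0, 10), y_mm = c(0, 150), z_mm = 0,
    parent_id = c(NA, 1))), 3)
  leaf <- tree_leaves(tree)
  sim0 <- simulate_catheter(tree, leaf, pose_5dof(), geom, sigma_simu = 0)
  sim8 <- simulate_catheter(tree, leaf, pose_5dof(), geom, sigma_simu = 8)
  p0 <- cathreg:::as_points2(sim0$catheter)
  p8 <- cathreg:::as_points2(sim8$catheter)
  # same straight line; resampling for the convolution may change the
  # vertex count, so compare tips, ends and straightness
  expect_equal(p8[1, ], p0[1, ], tolerance = 1e-9)
  expect_equal(p8[nrow(p8), ], p0[nrow(p0), ], tolerance = 1e-9)
  d <- diff(p8)
  crossp <- d[-1, 1] * d[-nrow(d), 2] - d[-1, 2] * d[-nrow(d), 1]
  expect_equal(max(abs(crossp)), 0, tolerance = 1e-9)
})

test_that("smoothing reduces curvature, keeps the tip, matches an oracle", {
  # zig-zag polyline smoothed with a wide kernel
  zig <- cbind(seq(0, 60, 2), rep(c(0, 4), 16)[1:31])
  sm <- cathreg:::gaussian_smooth_polyline(zig, sigma_mm = 6, step_mm = 1)
  expect_equal(unname(sm[1, ]), unname(zig[1, ]), tolerance = 1e-9)  # tip kept
  # interior amplitude strongly reduced (reflection pins the endpoints)
  amp <- function(m) diff(range(m[, 2]))
  interior <- sm[10:(nrow(sm) - 10), ]
  expect_lt(amp(interior), amp(zig) / 4)

  # independent discrete-convolution oracle on the same resampled points
  res <- as.matrix(resample_centerline(zig, 1)[, c("x_mm", "y_mm")])
  n <- nrow(res)
  half <- min(ceiling(4 * 6 / 1), n - 1)
  ext <- rbind(2 * matrix(res[1, ], half, 2, byrow = TRUE) -
                 res[(half + 1):2, ],
               res,
               2 * matrix(res[n, ], half, 2, byrow = TRUE) -
                 res[(n - 1):(n - half), ])
  w <- stats::dnorm(-half:half, sd = 6)
  w <- w / sum(w)
  oracle <- t(vapply(seq_len(n), function(i) {
    colSums(ext[(i):(i + 2 * half), , drop = FALSE] * w)
  }, numeric(2)))
  expect_equal(unname(sm), unname(oracle), tolerance = 1e-9)
})

test_that("the simulated tip direction matches the unsmoothed projection", {
  case <- make_sim_case(seed = 9, pose = pose_5dof(x = 10, y = -5))
  path <- path_to_root(case$tree, case$sim$tip_node)
  proj <- project_path(path, compose_pose(case$pose_true, case$geom), case$geom)
  expect_equal(case$sim$tip_direction, unit_tangent_at(proj, 0),
               tolerance = 1e-12)
  expect_equal(sqrt(sum(case$sim$tip_direction^2)), 1, tolerance = 1e-12)
})

test_that("simulating from the root is rejected", {
  case <- make_sim_case(seed = 5)
  expect_error(simulate_catheter(case$tree, case$tree$root_id, pose_5dof(),
                                 case$geom), "root")
})

test_that("experiment tables are reproducible bit for bit", {
  a <- run_experiment(n_cases = 2, sets = "slight", optimizers = "powell",
                      sigma_simu = 0, seed = 77)
  b <- run_experiment(n_cases = 2, sets = "slight", optimizers = "powell",
                      sigma_simu = 0, seed = 77)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(
    as.data.frame(a),
    as.data.frame(run_experiment(n_cases = 2, sets = "slight",
                                 optimizers = "powell", sigma_simu = 0,
                                 seed = 78))))
})

test_that("experiment rows carry provenance and sane errors", {
  exp <- run_experiment(n_cases = 2, sets = c("slight", "moderate"),
                        optimizers = "powell", sigma_simu = 0, seed = 5)
  expect_s3_class(exp, "roadmap_experiment")
  expect_equal(nrow(exp), 2)
  expect_setequal(exp$set_name, c("slight", "moderate"))
  need <- c("case_id", "case_seed", "sigma_simu_mm", "true_x", "true_y",
            "true_z", "est_x", "est_y", "e_d_mm", "l_d_mm", "o_d_mm",
            "metric_mm", "best_leaf", "best_rank", "error")
  expect_true(all(need %in% names(exp)))
  ok <- is.na(exp$error)
  expect_equal(exp$e_d_mm[ok]^2, exp$l_d_mm[ok]^2 + exp$o_d_mm[ok]^2,
               tolerance = 1e-6)
})
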