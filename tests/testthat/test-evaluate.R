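test_that("tip errors decompose the displacement", {
  expect_equal(unlist(tip_errors(c(0, 0), c(0, 0), c(1, 0))), c(e_d = 0, l_d = 0, o_d = 0))
  e <- tip_errors(c(0, 0), c(3, 4), c(1, 0))
  expect_equal(unlist(e), c(e_d = 5, l_d = 3, o_d = 4))
  # displacement parallel to the tip direction is purely longitudinal
  e2 <- tip_errors(c(10, -5), c(13, -5), c(1, 0))
  expect_equal(e2$o_d, 0)
  expect_equal(e2$l_d, e2$e_d)
  expect_error(tip_errors(c(0, 0), c(1, 1), c(2, 0)), "unit")
})

test_that("e_d^2 = l_d^2 + o_d^2 for random displacements", {
  withr::with_seed(13, {
    for (k in 1:20) {
      th <- stats::runif(1, 0, 2 * pi)
      e <- tip_errors(stats::rnorm(2, sd = 20), stats::rnorm(2, sd = 20),
                      c(cos(th), sin(th)))
      expect_equal(e$e_d^2, e$l_d^2 + e$o_d^2, tolerance = 1e-9)
    }
  })
})

test_that("identical paired vessels score zero", {
  poly <- data.frame(x_mm = seq(0, 20, 2), y_mm = sin(seq(0, 20, 2)))
  expect_equal(paired_vessel_distance(list(list(poly, poly)), tip = c(0, 0)), 0)
})

test_that("parallel segments at 2 mm offset score 2 mm", {
  a <- data.frame(x_mm = seq(-10, 10, 1), y_mm = 0)
  b <- data.frame(x_mm = seq(-12, 12, 1), y_mm = 2)
  score <- paired_vessel_distance(list(list(a, b)), tip = c(0, 1), radius_mm = 30)
  expect_equal(score, 2, tolerance = 1e-9)
})

test_that("pairs outside the evaluation disk are dropped", {
  near_a <- data.frame(x_mm = seq(-5, 5, 1), y_mm = 0)
  near_b <- data.frame(x_mm = seq(-6, 6, 1), y_mm = 1)
  far_a <- near_a; far_a$y_mm <- 500
  far_b <- near_b; far_b$y_mm <- 501
  both <- paired_vessel_distance(list(list(near_a, near_b), list(far_a, far_b)),
                                 tip = c(0, 0), radius_mm = 30)
  expect_equal(both, 1, tolerance = 1e-9)   # only the near pair counts
  expect_error(paired_vessel_distance(list(list(far_a, far_b)), tip = c(0, 0)),
               "no evaluable region")
})

test_that("matches landing on an endpoint are excluded", {
  # target much shorter than the source: source samples beyond the target
  # ends project onto its first/last vertex and must be skipped
  src <- data.frame(x_mm = seq(-20, 20, 2), y_mm = 0)
  tgt <- data.frame(x_mm = c(-2, 2), y_mm = 1)
  tbl <- paired_vessel_distance(list(list(src, tgt)), tip = c(0, 0),
                                radius_mm = 30, detail = TRUE)$table
  a2b <- tbl[tbl$direction == "a_to_b", ]
  # only the source samples whose projection lies inside the segment remain
  expect_lte(a2b$n_samples, 3)
  expect_equal(a2b$mean_mm, 1, tolerance = 1e-9)
})

test_that("the paired score is symmetric and rigid-motion invariant", {
  withr::with_seed(19, {
    a <- data.frame(x_mm = cumsum(stats::runif(12, 1, 3)),
                    y_mm = cumsum(stats::rnorm(12)))
    b <- a
    b$y_mm <- b$y_mm + stats::runif(12, 0.5, 1.5)
  })
  tip <- c(mean(a$x_mm), mean(a$y_mm))
  s_ab <- paired_vessel_distance(list(list(a, b)), tip)
  s_ba <- paired_vessel_distance(list(list(b, a)), tip)
  expect_equal(s_ab, s_ba, tolerance = 1e-12)
  # common rotation + translation of both polylines and the tip
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, byrow = TRUE)
  mv <- function(p) {
    m <- as.matrix(p) %*% t(rot)
    data.frame(x_mm = m[, 1] + 40, y_mm = m[, 2] - 15)
  }
  s_moved <- paired_vessel_distance(list(list(mv(a), mv(b))),
                                    as.numeric(rot %*% tip + c(40, -15)))
  expect_equal(s_moved, s_ab, tolerance = 1e-9)
})

test_that("tip-distance buckets aggregate the same distances", {
  a <- data.frame(x_mm = seq(0, 50, 1), y_mm = 0)
  b <- data.frame(x_mm = seq(-1, 51, 1), y_mm = 3)
  tip <- c(0, 0)
  # all samples in one bucket -> bucket mean equals the global mean
  one <- distance_by_tip_bucket(list(list(a, b)), tip, bucket_edges = c(0, 200))
  expect_equal(nrow(one), 1)
  expect_equal(one$mean_mm, 3, tolerance = 1e-9)
  # split buckets: hand-computed assignment by distance from the tip
  two <- distance_by_tip_bucket(list(list(a, b)), tip, bucket_edges = c(0, 25, 200))
  expect_equal(two$mean_mm, c(3, 3), tolerance = 1e-9)
  expect_gt(two$n_samples[1], 0)
  expect_gt(two$n_samples[2], 0)
  # an empty bucket reports NA
  three <- distance_by_tip_bucket(list(list(a, b)), tip,
                                  bucket_edges = c(0, 60, 1000, 2000))
  expect_true(is.na(three$mean_mm[3]))
  expect_equal(three$n_samples[3], 0L)
})

test_that("parameter sweeps enumerate settings and score cases", {
  # synthetic score: distance of (lambda, sigma) to a case-specific optimum
  cases <- list(list(opt = c(0.1, 40)), list(opt = c(0.2, 40)))
  score_fn <- function(case, config) {
    sum(abs(c(config$lambda, config$sigma) - case$opt))
  }
  single <- parameter_sweep(cases, lambda_grid = 0.2, sigma_grid = 40,
                            d_max_grid = 20, sampling_grid = 3,
                            score_fn = score_fn)
  expect_equal(nrow(single$table), 1)
  expect_equal(single$best$lambda, 0.2)

  sw <- parameter_sweep(cases, lambda_grid = c(0, 0.1, 0.2, 0.3),
                        sigma_grid = c(20, 40), d_max_grid = 20,
                        sampling_grid = 3, score_fn = score_fn,
                        leave_one_out = TRUE)
  expect_equal(nrow(sw$table), 8)
  # the mean-optimal setting sits between the two case optima
  expect_equal(sw$best$sigma, 40)
  expect_true(sw$best$lambda %in% c(0.1, 0.2))
  # leave-one-out: fold k picks the *other* case's optimum
  expect_equal(sw$leave_one_out$lambda, c(0.2, 0.1))
  expect_equal(sw$leave_one_out$sigma, c(40, 40))
})

test_that("a dominant setting wins every leave-one-out fold", {
  cases <- list(list(id = 1), list(id = 2), list(id = 3))
  score_fn <- function(case, config) {
    if (config$lambda == 0.1) 1 else 2 + case$id
  }
  sw <- parameter_sweep(cases, lambda_grid = c(0, 0.1), sigma_grid = 20,
                        d_max_grid = 20, sampling_grid = 3,
                        score_fn = score_fn, leave_one_out = TRUE)
  expect_true(all(sw$leave_one_out$lambda == 0.1))
  expect_true(all(sw$leave_one_out$held_out_score == 1))
})

test_that("the registration-based sweep score runs end to end", {
  case0 <- make_sim_case(seed = 3)
  # reference pair: the true vessel path and its (noisy) 2D observation
  path <- path_to_root(case0$tree, case0$sim$tip_node)
  angio <- project_path(path, compose_pose(case0$pose_true, case0$geom),
                        case0$geom)
  case <- list(catheter = case0$sim$catheter, tree = case0$tree,
               geometry = case0$geom, pairs = list(list(angio, path)))
  sf <- sweep_score_registration(optimizer = "powell")
  sw <- parameter_sweep(list(case), lambda_grid = 0.2, sigma_grid = 20,
                        d_max_grid = 40, sampling_grid = 3, score_fn = sf)
  expect_lt(sw$table$score, 3)   # registered overlay close to the reference
})
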