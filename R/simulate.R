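#' Specification of a synthetic hepatic-artery-like tree
#'
#' Controls the generator in [generate_tree()]: a straight-ish trunk (the
#' abdominal aorta, rooted at its caudal end), a sharp-angled takeoff at the
#' ostium into the main hepatic branch (the anatomical celiac/hepatic turn a
#' catheter follows), an aorta continuation beyond the ostium, and recursive
#' smoothly curving binary branching of the hepatic arteries. All lengths in
#' mm, angles in degrees. With the defaults a tree has roughly 200-350
#' centerline nodes at 3 mm steps and leaf paths 150-250 mm long.
#'
#' @param n_generations Maximum branching depth below the hepatic main
#'   branch.
#' @param branch_probability Probability that a segment end bifurcates
#'   (given it has not reached `n_generations`).
#' @param segment_length_range Min/max daughter-segment length (mm).
#' @param branch_angle_range Min/max opening angle between the two daughters
#'   at a bifurcation (degrees).
#' @param takeoff_angle_range Min/max angle (degrees) between the aorta
#'   direction and the hepatic main branch at the ostium.
#' @param aorta_continuation_mm Length of the childless aorta segment
#'   continuing beyond the ostium (0 to disable, leaving a pure chain when
#'   nothing branches).
#' @param curvature_range Min/max in-plane curvature of a hepatic branch
#'   segment, in degrees per mm of arc. Each segment bends as a smooth arc
#'   with a per-segment curvature drawn from this range (hepatic arteries
#'   curve smoothly with radii of roughly 20-100 mm; centerline jitter is a
#'   segmentation artifact, not anatomy).
#' @param direction_jitter Small per-step random bend (degrees per mm)
#'   superimposed on the arcs, giving organic irregularity.
#' @param trunk_curvature Gentle bow of the aorta, degrees per mm.
#' @param trunk_length_mm Aorta length from the root to the ostium (mm).
#' @param step_mm Step between generated centerline nodes (mm).
#' @param seed Integer seed; the same seed regenerates the identical tree.
#' @return A list of class `tree_spec`.
#' @export
tree_spec <- function(n_generations = 4, branch_probability = 0.9,
                      segment_length_range = c(20, 45),
                      branch_angle_range = c(25, 70),
                      takeoff_angle_range = c(60, 100),
                      aorta_continuation_mm = 40,
                      curvature_range = c(0.5, 2.5),
                      direction_jitter = 0.1,
                      trunk_curvature = 0.1,
                      trunk_length_mm = 100, step_mm = 3, seed = 1L) {
  stopifnot(n_generations >= 0, branch_probability >= 0, branch_probability <= 1,
            length(segment_length_range) == 2, all(segment_length_range > 0),
            length(branch_angle_range) == 2, length(curvature_range) == 2,
            all(curvature_range >= 0), direction_jitter >= 0,
            trunk_curvature >= 0,
            length(takeoff_angle_range) == 2, aorta_continuation_mm >= 0,
            trunk_length_mm > 0, step_mm > 0)
  structure(list(n_generations = n_generations,
                 branch_probability = branch_probability,
                 segment_length_range = as.numeric(segment_length_range),
                 branch_angle_range = as.numeric(branch_angle_range),
                 takeoff_angle_range = as.numeric(takeoff_angle_range),
                 aorta_continuation_mm = aorta_continuation_mm,
                 curvature_range = as.numeric(curvature_range),
                 direction_jitter = direction_jitter,
                 trunk_curvature = trunk_curvature,
                 trunk_length_mm = trunk_length_mm,
                 step_mm = step_mm, seed = seed),
            class = "tree_spec")
}

# Rotate unit vector v by angle_deg about a unit axis (Rodrigues).
rotate_about_axis <- function(v, axis, angle_deg) {
  th <- angle_deg * pi / 180
  v * cos(th) + pracma_cross(axis, v) * sin(th) +
    axis * sum(axis * v) * (1 - cos(th))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# A random unit vector perpendicular to dir.
random_perpendicular <- function(dir) {
  repeat {
    r <- stats::rnorm(3)
    p <- r - sum(r * dir) * dir
    n <- sqrt(sum(p^2))
    if (n > 1e-6) return(p / n)
  }
}

#' Generate a synthetic vessel tree
#'
#' Deterministic per `spec$seed`: grows the trunk from the root, then
#' recursively splits into smoothly curving daughter segments. The finished
#' tree is recentered so its bounding-box centroid sits at the world
#' iso-center.
#'
#' @param spec A [tree_spec()].
#' @return A [vessel_tree()].
#' @examples
#' tree <- generate_tree(tree_spec(seed = 7))
#' length(tree_leaves(tree)) >= 1
#' @export
generate_tree <- function(spec) {
  stopifnot(inherits(spec, "tree_spec"))
  gen <- function() {
    ids <- character(0); xyz <- NULL; parent <- character(0)
    counter <- 0L
    new_id <- function() {
      counter <<- counter + 1L
      sprintf("n%d", counter)
    }
    add <- function(p, parent_id) {
      id <- new_id()
      ids <<- c(ids, id)
      xyz <<- rbind(xyz, p)
      parent <<- c(parent, parent_id)
      id
    }
    # walk a segment bending as a smooth arc: fixed curvature and bending
    # plane per segment, plus slight per-step jitter
    walk_segment <- function(from, from_id, dir, length_mm, curvature = NULL) {
      n_steps <- max(1L, round(length_mm / spec$step_mm))
      if (is.null(curvature)) {
        curvature <- stats::runif(1, spec$curvature_range[1],
                                  spec$curvature_range[2])
      }
      bend_axis <- random_perpendicular(dir)
      pos <- from
      pid <- from_id
      for (i in seq_len(n_steps)) {
        bend <- curvature * spec$step_mm
        if (spec$direction_jitter > 0) {
          bend <- bend + stats::rnorm(1, 0, spec$direction_jitter * spec$step_mm)
        }
        dir <- rotate_about_axis(dir, bend_axis, bend)
        # keep the bending plane perpendicular as the direction turns
        bend_axis <- bend_axis - sum(bend_axis * dir) * dir
        bend_axis <- bend_axis / sqrt(sum(bend_axis^2))
        pos <- pos + dir * spec$step_mm
        pid <- add(pos, pid)
      }
      list(pos = pos, id = pid, dir = dir)
    }
    grow <- function(from, from_id, dir, generation) {
      len <- stats::runif(1, spec$segment_length_range[1],
                          spec$segment_length_range[2])
      seg <- walk_segment(from, from_id, dir, len)
      branches <- generation < spec$n_generations &&
        stats::runif(1) < spec$branch_probability
      if (branches) {
        opening <- stats::runif(1, spec$branch_angle_range[1],
                                spec$branch_angle_range[2])
        axis <- random_perpendicular(seg$dir)
        d1 <- rotate_about_axis(seg$dir, axis, opening / 2)
        d2 <- rotate_about_axis(seg$dir, axis, -opening / 2)
        grow(seg$pos, seg$id, d1, generation + 1)
        grow(seg$pos, seg$id, d2, generation + 1)
      }
      invisible(NULL)
    }
    root_id <- add(c(0, 0, 0), NA_character_)
    trunk <- walk_segment(c(0, 0, 0), root_id, c(0, 1, 0),
                          spec$trunk_length_mm,
                          curvature = spec$trunk_curvature)
    # aorta continuation beyond the ostium: a childless leaf
    if (spec$aorta_continuation_mm > 0) {
      walk_segment(trunk$pos, trunk$id, trunk$dir, spec$aorta_continuation_mm,
                   curvature = spec$trunk_curvature)
    }
    # hepatic main branch leaves the aorta at a sharp ostium angle
    takeoff <- stats::runif(1, spec$takeoff_angle_range[1],
                            spec$takeoff_angle_range[2])
    hep_dir <- rotate_about_axis(trunk$dir, random_perpendicular(trunk$dir),
                                 takeoff)
    grow(trunk$pos, trunk$id, hep_dir, 0)
    nodes <- tibble::tibble(id = ids, x_mm = xyz[, 1], y_mm = xyz[, 2],
                            z_mm = xyz[, 3], parent_id = parent)
    tree <- vessel_tree(nodes)
    ctr <- tree_bbox_center(tree)
    tree$nodes$x_mm <- tree$nodes$x_mm - ctr[1]
    tree$nodes$y_mm <- tree$nodes$y_mm - ctr[2]
    tree$nodes$z_mm <- tree$nodes$z_mm - ctr[3]
    tree
  }
  if (is.null(spec$seed)) gen() else withr::with_seed(spec$seed, gen())
}

#' Random-perturbation sets for the simulation study
#'
#' The three named randomization sets of the simulated-catheter experiment.
#' Each component of the ground-truth transform is drawn uniformly from its
#' (possibly two-interval) range:
#'
#' * translation x: `[-30, 30]` mm for all sets;
#' * translation y: slight `[-20, 20]`, moderate `[-40, -20] U [20, 40]`,
#'   large `[-50, -40] U [40, 50]` mm;
#' * translation z (depth; never searched): `[-30, 30]` mm for all sets;
#' * rotations alpha, beta, gamma: `[-6, 6]` degrees for all sets;
#' * catheter smoothing `sigma_simu`: slight `[1, 5]`, moderate `[5, 10]`,
#'   large `[10, 15]` mm.
#'
#' @param set `"slight"`, `"moderate"` or `"large"`.
#' @return A list of class `perturbation_spec`; interval unions are matrices
#'   with one interval per row.
#' @export
perturbation_spec <- function(set = c("slight", "moderate", "large")) {
  set <- match.arg(set)
  ty <- switch(set,
    slight = rbind(c(-20, 20)),
    moderate = rbind(c(-40, -20), c(20, 40)),
    large = rbind(c(-50, -40), c(40, 50)))
  sig <- switch(set, slight = c(1, 5), moderate = c(5, 10), large = c(10, 15))
  structure(list(set_name = set,
                 tx_range = rbind(c(-30, 30)),
                 ty_range = ty,
                 tz_range = rbind(c(-30, 30)),
                 angle_range = rbind(c(-6, 6)),
                 sigma_simu_range = sig),
            class = "perturbation_spec")
}

# Uniform draw from a union of intervals (matrix, one interval per row),
# interval chosen with probability proportional to its width.
draw_from_ranges <- function(ranges) {
  w <- ranges[, 2] - ranges[, 1]
  i <- if (nrow(ranges) == 1) 1L else sample.int(nrow(ranges), 1, prob = w)
  stats::runif(1, ranges[i, 1], ranges[i, 2])
}

#' Draw a random ground-truth transform
#'
#' Samples one ground-truth perturbation from a [perturbation_spec()]. The
#' depth component `z_mm` perturbs the simulated 3D truth (it exists
#' physically) even though registration never searches it.
#'
#' @param spec A [perturbation_spec()].
#' @param rotation_center Rotation center for the drawn pose (mm).
#' @param seed Optional integer seed for a reproducible single draw.
#' @return A list: `pose` ([pose_5dof()]), `z_mm`, `sigma_simu`.
#' @export
random_pose <- function(spec, rotation_center = c(0, 0, 0), seed = NULL) {
  stopifnot(inherits(spec, "perturbation_spec"))
  draw <- function() {
    list(pose = pose_5dof(alpha = draw_from_ranges(spec$angle_range),
                          beta = draw_from_ranges(spec$angle_range),
                          gamma = draw_from_ranges(spec$angle_range),
                          x = draw_from_ranges(spec$tx_range),
                          y = draw_from_ranges(spec$ty_range),
                          rotation_center = rotation_center),
         z_mm = draw_from_ranges(spec$tz_range),
         sigma_simu = stats::runif(1, spec$sigma_simu_range[1],
                                   spec$sigma_simu_range[2]))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Gaussian smoothing of a 2D polyline along arc length, with reflected
# boundaries so the tip (first point) is preserved exactly. The polyline is
# resampled at a fine step before convolution.
gaussian_smooth_polyline <- function(pts, sigma_mm, step_mm = 1) {
  if (sigma_mm <= 0) return(pts)
  res <- as.matrix(resample_centerline(pts, step_mm)[, c("x_mm", "y_mm")])
  n <- nrow(res)
  if (n < 3) return(pts)
  half <- min(max(1L, ceiling(4 * sigma_mm / step_mm)), n - 1L)
  # reflect coordinates about both endpoints
  top <- 2 * rep(res[1, ], each = half) -
    res[seq(half + 1, 2), , drop = FALSE]
  bot <- 2 * rep(res[n, ], each = half) -
    res[seq(n - 1, n - half), , drop = FALSE]
  ext <- rbind(top, res, bot)
  w <- stats::dnorm(seq(-half, half) * step_mm, sd = sigma_mm)
  w <- w / sum(w)
  out <- matrix(0, n, 2)
  for (k in seq(-half, half)) {
    out <- out + w[k + half + 1] * ext[(half + 1 + k):(half + n + k), , drop = FALSE]
  }
  out
}

#' Simulate a 2D catheter from a vessel path
#'
#' Extracts the 3D vessel path from a chosen tip node to the root, projects
#' it under the ground-truth transform (the 5-DOF pose plus a physical depth
#' offset), and smooths the 2D projection along arc length with a Gaussian
#' of standard deviation `sigma_simu` to emulate a catheter that stretches
#' the vessel. The tip stays the first point (reflected-boundary kernel);
#' the ground-truth projected tip is recorded pre-smoothing.
#'
#' @param tree A [vessel_tree()] (typically already resampled at the working
#'   spacing).
#' @param tip_node Node id of the simulated catheter tip.
#' @param pose_true Ground-truth [pose_5dof()].
#' @param geometry A [projection_geometry()].
#' @param sigma_simu Smoothing standard deviation in mm (0 = none).
#' @param z_mm Ground-truth depth offset in mm.
#' @return A list of class `simulated_catheter`: `catheter` (a
#'   [catheter_centerline()]), `true_tip_mm` (pre-smoothing projected tip),
#'   `tip_direction` (unit 2-vector at the true tip), `tip_node`,
#'   `tip_xyz` (3D tip coordinates), `pose_true`, `z_mm`, `sigma_simu`.
#' @export
simulate_catheter <- function(tree, tip_node, pose_true, geometry,
                              sigma_simu = 0, z_mm = 0) {
  stopifnot(inherits(tree, "vessel_tree"), sigma_simu >= 0)
  path <- path_to_root(tree, tip_node)
  if (nrow(path) < 2) {
    stop("tip node must not be the root: the simulated catheter needs extent",
         call. = FALSE)
  }
  t_true <- compose_pose(pose_true, geometry, z_mm = z_mm)
  proj <- project_matrix(as_points3(path), t_true, geometry)
  true_tip <- proj[1, ]
  tip_dir <- unit_tangent_at(proj, 0)
  pts <- if (sigma_simu > 0) gaussian_smooth_polyline(proj, sigma_simu) else proj
  structure(list(catheter = catheter_centerline(pts),
                 true_tip_mm = as.numeric(true_tip),
                 tip_direction = as.numeric(tip_dir),
                 tip_node = as.character(tip_node),
                 tip_xyz = as.numeric(as_points3(path)[1, ]),
                 pose_true = pose_true, z_mm = z_mm,
                 sigma_simu = sigma_simu),
            class = "simulated_catheter")
}

#' Arc length from the root to every node
#'
#' Walks the tree edges and accumulates arc length from the root; useful for
#' choosing simulated catheter tip nodes at a given depth.
#'
#' @param tree A [vessel_tree()].
#' @return Named numeric vector (mm), one entry per node id.
#' @export
node_root_arc <- function(tree) {
  nodes <- tree$nodes
  parents <- parent_map(tree)
  coords <- as.matrix(nodes[, c("x_mm", "y_mm", "z_mm")])
  rownames(coords) <- nodes$id
  depth <- node_depths(tree)
  arc <- stats::setNames(rep(NA_real_, nrow(nodes)), nodes$id)
  arc[tree$root_id] <- 0
  for (id in names(sort(depth))) {
    p <- parents[[id]]
    if (is.na(p)) next
    arc[id] <- arc[p] + sqrt(sum((coords[id, ] - coords[p, ])^2))
  }
  arc
}

#' Run the simulated-catheter experiment
#'
#' The end-to-end simulation protocol: per case, generate a synthetic tree,
#' pick a catheter tip node, draw a ground-truth transform from the chosen
#' perturbation set, simulate the catheter, register it back with each
#' requested optimizer, and measure the projected tip error. All randomness
#' flows through the single `seed`; rerunning with the same arguments
#' reproduces the table exactly.
#'
#' @param n_cases Number of simulated cases.
#' @param sets Perturbation set names cycled over the cases.
#' @param optimizers Character vector, subset of
#'   `c("brute_force", "powell")`; each case is registered with every
#'   requested optimizer (one output row per case x optimizer).
#' @param spec A [tree_spec()]; its seed is re-drawn per case.
#' @param geometry A [projection_geometry()].
#' @param sigma_simu If not `NULL`, overrides the per-set smoothing draw
#'   (use 0 for unsmoothed catheters).
#' @param k Number of candidate leaf paths per registration.
#' @param schedule A [brute_force_schedule()].
#' @param tip_min_arc_mm Minimum arc distance (mm) from the root for the
#'   simulated tip node, so the catheter has realistic proximal extent.
#' @param rotation_center_offset_mm Named list giving, per optimizer, the
#'   offset (mm) from the tree's bounding-box centroid to the rotation
#'   center used by the registration. The default rotates the brute-force
#'   search about the corner of a typical 250 mm rotational-angiography
#'   volume centered on the tree (in clinical volumes the pose rotation
#'   acts about the image origin, which sits at a corner far from the
#'   vessels; a distant center also makes the coarse grid iterations sweep
#'   translation space more densely, improving robustness) and the Powell
#'   search about the tree-local centroid (decoupled, well-conditioned for
#'   a local method). See the methods vignette.
#' @param seed Master seed for the experiment.
#' @return A tibble of class `roadmap_experiment`, one row per case and
#'   optimizer: the drawn ground truth, the estimated pose, the tip errors
#'   `e_d`/`l_d`/`o_d` (mm), the metric, and the chosen leaf with its
#'   shape-similarity rank. Failed cases carry the error message in
#'   `error` and `NA` results.
#' @export
run_experiment <- function(n_cases,
                           sets = c("slight", "moderate", "large"),
                           optimizers = "brute_force",
                           spec = tree_spec(),
                           geometry = projection_geometry(),
                           sigma_simu = NULL, k = 5,
                           schedule = brute_force_schedule(),
                           tip_min_arc_mm = 120,
                           rotation_center_offset_mm = list(
                             brute_force = c(-125, -125, -125),
                             powell = c(0, 0, 0)),
                           seed = 1L) {
  stopifnot(n_cases >= 1, all(optimizers %in% c("brute_force", "powell")),
            all(sets %in% c("slight", "moderate", "large")))
  set_cycle <- rep(sets, length.out = n_cases)
  rows <- withr::with_seed(seed, {
    purrr::map(seq_len(n_cases), function(case_id) {
      case_seed <- sample.int(.Machine$integer.max - 2L, 1)
      run_one_case(case_id, set_cycle[case_id], case_seed, optimizers, spec,
                   geometry, sigma_simu, k, schedule, tip_min_arc_mm,
                   rotation_center_offset_mm)
    })
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "seed") <- seed
  attr(out, "spec") <- spec
  class(out) <- c("roadmap_experiment", class(out))
  out
}

run_one_case <- function(case_id, set_name, case_seed, optimizers, spec,
                         geometry, sigma_simu, k, schedule, tip_min_arc_mm,
                         rotation_center_offset_mm) {
  base <- tibble::tibble(case_id = case_id, set_name = set_name,
                         case_seed = case_seed)
  sim_env <- tryCatch({
    cfg_sampling <- metric_config_brute()$sampling
    sp <- spec
    sp$seed <- case_seed
    tree <- generate_tree(sp)
    rtree <- resample_tree(tree, cfg_sampling)
    arc <- node_root_arc(rtree)
    pool <- names(arc)[arc >= tip_min_arc_mm]
    if (length(pool) == 0) {
      pool <- names(arc)[arc >= stats::quantile(arc, 0.75)]
    }
    tip_node <- withr::with_seed(case_seed + 1L,
                                 pool[sample.int(length(pool), 1)])
    pert <- perturbation_spec(set_name)
    rc <- tree_bbox_center(rtree)
    drawn <- random_pose(pert, rotation_center = rc, seed = case_seed + 2L)
    sig <- if (is.null(sigma_simu)) drawn$sigma_simu else sigma_simu
    sim <- simulate_catheter(rtree, tip_node, drawn$pose, geometry,
                             sigma_simu = sig, z_mm = drawn$z_mm)
    list(rtree = rtree, sim = sim, drawn = drawn, sig = sig)
  }, error = function(e) e)
  if (inherits(sim_env, "error")) {
    return(dplyr::mutate(base, optimizer = optimizers[1],
                         error = conditionMessage(sim_env)))
  }
  sim <- sim_env$sim
  drawn <- sim_env$drawn
  truth <- tibble::tibble(
    sigma_simu_mm = sim_env$sig,
    true_alpha = drawn$pose$alpha, true_beta = drawn$pose$beta,
    true_gamma = drawn$pose$gamma, true_x = drawn$pose$x,
    true_y = drawn$pose$y, true_z = drawn$z_mm)
  purrr::map_dfr(optimizers, function(opt) {
    res <- tryCatch({
      # the tree is already discretized at the working sampling (a second
      # pass would only add corner-cutting drift); the simulated catheter is
      # resampled to the sampling in image mm, as annotated catheters are
      reg <- register_catheter(sim$catheter, sim_env$rtree, geometry,
                               optimizer = opt, k = k, schedule = schedule,
                               resample = "catheter",
                               rotation_center = tree_bbox_center(sim_env$rtree) +
                                 rotation_center_offset_mm[[opt]])
      reg_tip <- project_point(sim$tip_xyz, reg$pose, geometry)
      err <- tip_errors(sim$true_tip_mm, reg_tip, sim$tip_direction)
      best_rank <- reg$candidates$rank[reg$candidates$leaf_id == reg$best_leaf_id][1]
      tibble::tibble(
        optimizer = opt,
        est_alpha = reg$pose$alpha, est_beta = reg$pose$beta,
        est_gamma = reg$pose$gamma, est_x = reg$pose$x, est_y = reg$pose$y,
        e_d_mm = err$e_d, l_d_mm = err$l_d, o_d_mm = err$o_d,
        metric_mm = reg$metric_mm, best_leaf = reg$best_leaf_id,
        best_rank = best_rank, true_leaf_found =
          reg$best_tip_node == sim$tip_node,
        error = NA_character_)
    }, error = function(e) tibble::tibble(optimizer = opt,
                                          error = conditionMessage(e)))
    dplyr::bind_cols(base, truth, res)
  })
}
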