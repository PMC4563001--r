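#' Registration metric configuration
#'
#' Parameters of the weighted closest-point metric: the weight offset
#' `lambda` and decay `sigma` of the tip-centered Gaussian weight, the
#' window bound `d_max` limiting how far the point search may advance along
#' the projected vessel between consecutive catheter points, and the
#' arc-length `sampling` at which catheter and tree are discretized.
#'
#' `metric_config_brute()` and `metric_config_powell()` return the settings
#' found optimal for each optimizer in cross-validation on clinical data
#' (brute force: lambda 0.1, sigma 80, d_max 20; Powell: lambda 0.2,
#' sigma 20, d_max 40; sampling 3 mm).
#'
#' @param lambda Weight offset, in `[0, 1]`.
#' @param sigma Weight decay length in mm (> 0).
#' @param d_max Window bound in mm (> 0), measured along the projected
#'   vessel polyline.
#' @param sampling Discretization spacing in mm (> 0).
#' @return A list of class `metric_config`.
#' @export
metric_config <- function(lambda = 0.2, sigma = 20, d_max = 40, sampling = 3) {
  stopifnot(lambda >= 0, lambda <= 1, sigma > 0, d_max > 0, sampling > 0)
  structure(list(lambda = lambda, sigma = sigma, d_max = d_max,
                 sampling = sampling), class = "metric_config")
}

#' @rdname metric_config
#' @export
metric_config_brute <- function() metric_config(lambda = 0.1, sigma = 80, d_max = 20)

#' @rdname metric_config
#' @export
metric_config_powell <- function() metric_config(lambda = 0.2, sigma = 20, d_max = 40)

#' Multi-resolution brute-force search schedule
#'
#' The exhaustive optimizer runs `n_iterations` grid searches over the five
#' pose parameters; each iteration re-centers on the incumbent minimum and
#' shrinks the half-intervals by `shrink`. Each dimension is subdivided into
#' `steps_per_dim` values including the interval center (odd counts only),
#' so the incumbent is always re-evaluated and the best metric is
#' non-increasing across iterations.
#'
#' @param n_iterations Number of refinement iterations (default 7).
#' @param shrink Interval shrink factor per iteration, in (0, 1) (default 0.5).
#' @param steps_per_dim Odd number of grid values per dimension (default 7).
#' @param half_interval_trans_mm Initial half-interval for x, y (default 50 mm).
#' @param half_interval_rot_deg Initial half-interval for the three angles
#'   (default 7 degrees).
#' @return A list of class `brute_force_schedule`.
#' @export
brute_force_schedule <- function(n_iterations = 7, shrink = 0.5,
                                 steps_per_dim = 7,
                                 half_interval_trans_mm = 50,
                                 half_interval_rot_deg = 7) {
  stopifnot(n_iterations >= 1, shrink > 0, shrink < 1, steps_per_dim >= 2)
  if (steps_per_dim %% 2 == 0) {
    stop("steps_per_dim must be odd so the grid contains its center", call. = FALSE)
  }
  structure(list(n_iterations = as.integer(n_iterations), shrink = shrink,
                 steps_per_dim = as.integer(steps_per_dim),
                 half_interval_trans_mm = half_interval_trans_mm,
                 half_interval_rot_deg = half_interval_rot_deg),
            class = "brute_force_schedule")
}

#' Tip-centered metric weight
#'
#' `W(x) = lambda + (1 - lambda) * exp(-x^2 / (2 sigma^2))`: a Gaussian with
#' an offset, so distances near the catheter tip count fully (`W(0) = 1`)
#' and distal distances still count at least `lambda`.
#'
#' @param x Arc length from the catheter tip (mm), non-negative.
#' @param lambda Offset in `[0, 1]`.
#' @param sigma Decay length in mm (> 0).
#' @return Weights in `[lambda, 1]`.
#' @export
tip_weight <- function(x, lambda, sigma) {
  stopifnot(all(x >= 0), lambda >= 0, lambda <= 1, sigma > 0)
  lambda + (1 - lambda) * exp(-x^2 / (2 * sigma^2))
}

#' Catheter-tip to projected-vessel distance
#'
#' The tip term of the registration metric: the catheter tip is matched to
#' the closest point of the whole projected vessel path. The matched index
#' anchors the windowed search for the next catheter point.
#'
#' @param catheter Catheter centerline (tip first).
#' @param path 3D vessel path (tip first).
#' @param pose A [pose_5dof()] or 4x4 transform.
#' @param geometry A [projection_geometry()].
#' @return A list: `distance_mm`, `index` (1-based index into the path).
#' @export
tip_distance <- function(catheter, path, pose, geometry) {
  cath <- as_points2(catheter)
  proj <- project_matrix(as_points3(path), pose_transform(pose, geometry), geometry)
  if (nrow(proj) == 0) stop("empty vessel path", call. = FALSE)
  d2 <- (proj[, 1] - cath[1, 1])^2 + (proj[, 2] - cath[1, 2])^2
  i <- which.min(d2)
  list(distance_mm = sqrt(d2[i]), index = i)
}

#' Windowed closest-point distance for one catheter point
#'
#' Matches one catheter point to the closest of the projected vessel points
#' in the window starting at the previous match and extending root-ward no
#' further than `d_max` mm of projected arc length. The window preserves the
#' continuity of the correspondence and bounds the per-point search cost.
#'
#' @param c_i Length-2 catheter point (mm).
#' @param prev_index 1-based index of the previous match (the anchor).
#' @param d_max Window bound in mm.
#' @inheritParams tip_distance
#' @return A list: `distance_mm`, `index` (the new anchor).
#' @export
windowed_distance <- function(c_i, path, pose, geometry, prev_index, d_max) {
  proj <- project_matrix(as_points3(path), pose_transform(pose, geometry), geometry)
  stopifnot(prev_index >= 1, prev_index <= nrow(proj))
  arc <- cum_arc(proj)
  res <- windowed_distance_2d(as.numeric(c_i), proj, arc, prev_index, d_max)
  list(distance_mm = res$distance, index = res$index)
}

windowed_distance_2d <- function(c_i, proj, arc, prev_index, d_max) {
  j <- prev_index
  hi <- j
  while (hi < nrow(proj) && arc[hi + 1] - arc[j] <= d_max) hi <- hi + 1
  idx <- j:hi
  d2 <- (proj[idx, 1] - c_i[1])^2 + (proj[idx, 2] - c_i[2])^2
  b <- which.min(d2)
  list(distance = sqrt(d2[b]), index = idx[b])
}

# Accept a pose_5dof or a raw 4x4 for the pose argument.
pose_transform <- function(pose, geometry) {
  if (inherits(pose, "pose_5dof")) compose_pose(pose, geometry) else pose
}

#' Weighted closest-point registration metric
#'
#' The cumulative distance `M` between the catheter and a projected vessel
#' path under a pose. The catheter tip is matched to the closest point of
#' the linearly interpolated projected centerline; every subsequent catheter
#' point is matched within a window starting at the previous match's arc
#' position and extending `d_max` mm root-ward, and its distance is weighted
#' by [tip_weight()] of the catheter arc length from the tip. Matching
#' against the interpolated centerline (rather than its discrete vertices)
#' keeps the metric smooth in the pose parameters, which the multi-
#' resolution search relies on; [tip_distance()] and [windowed_distance()]
#' are the vertex-level counterparts. `M = 0` exactly when every matched
#' pair coincides.
#'
#' @inheritParams tip_distance
#' @param config A [metric_config()]. The catheter is expected to be
#'   resampled at `config$sampling`.
#' @param engine `"cpp"` (compiled, used by the optimizers) or `"r"`
#'   (independent reference implementation).
#' @return A list: `metric_mm`, `correspondences` (1-based path index
#'   matched to each catheter point, non-decreasing).
#' @export
registration_metric <- function(catheter, path, pose, geometry, config,
                                engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "metric_config"))
  cath <- as_points2(catheter)
  pts <- as_points3(path)
  if (nrow(cath) < 1 || nrow(pts) < 1) {
    stop("metric needs a non-empty catheter and path", call. = FALSE)
  }
  cath_arc <- cum_arc(cath)
  transform <- pose_transform(pose, geometry)
  if (engine == "cpp") {
    m34 <- projection_chain(as_rigid_transform(transform), geometry)
    res <- cpp_metric(cath, cath_arc, pts, m34,
                      config$lambda, config$sigma, config$d_max)
    if (!is.finite(res$metric)) {
      stop("degenerate projection: path point at or behind the X-ray source",
           call. = FALSE)
    }
    return(list(metric_mm = res$metric, correspondences = res$match))
  }
  proj <- project_matrix(pts, transform, geometry)
  arc <- cum_arc(proj)
  total <- arc[length(arc)]
  res <- curve_window_search(cath[1, ], proj, arc, 0, total)
  m <- res$distance
  match <- integer(nrow(cath))
  match[1] <- res$segment
  anchor_arc <- res$arc
  if (nrow(cath) > 1) {
    w <- tip_weight(cath_arc[-1], config$lambda, config$sigma)
    for (i in 2:nrow(cath)) {
      res <- curve_window_search(cath[i, ], proj, arc, anchor_arc,
                                 min(anchor_arc + config$d_max, total))
      m <- m + w[i - 1] * res$distance
      anchor_arc <- res$arc
      match[i] <- res$segment
    }
  }
  list(metric_mm = m, correspondences = match)
}

# Closest point on the linearly interpolated 2D polyline restricted to the
# arc interval [lo, hi]; reference counterpart of the compiled search.
curve_window_search <- function(p, proj, arc, lo, hi) {
  n <- nrow(proj)
  if (n == 1) {
    return(list(distance = sqrt(sum((proj[1, ] - p)^2)), arc = 0, segment = 1L))
  }
  segs <- which(arc[-n] <= hi & arc[-1] >= lo)
  best <- list(distance = Inf, arc = lo, segment = 1L)
  for (j in segs) {
    len <- arc[j + 1] - arc[j]
    a <- proj[j, ]
    d <- proj[j + 1, ] - a
    if (len <= 1e-12) {
      t <- 0
    } else {
      t <- sum((p - a) * d) / (len * len)
      tlo <- max(0, (lo - arc[j]) / len)
      thi <- min(1, (hi - arc[j]) / len)
      if (tlo > thi) next
      t <- min(max(t, tlo), thi)
    }
    q <- a + t * d
    dist <- sqrt(sum((q - p)^2))
    if (dist < best$distance) {
      best <- list(distance = dist, arc = arc[j] + t * len, segment = j)
    }
  }
  best
}

#' Multi-resolution brute-force pose optimization
#'
#' Exhaustive grid search over the five pose parameters, refined over
#' `schedule$n_iterations` iterations: iteration `i` evaluates a full
#' `steps_per_dim^5` grid spanning the incumbent plus/minus
#' `half * shrink^(i-1)` and re-centers on the grid minimum. Because the
#' grid contains its center, the incumbent metric never increases. Optima
#' outside the initial intervals are clamped to the searched region.
#'
#' @inheritParams registration_metric
#' @param schedule A [brute_force_schedule()].
#' @param rotation_center Length-3 rotation center (mm); defaults to the
#'   origin.
#' @return A list: `pose` ([pose_5dof()]), `metric_mm`, `trace` (incumbent
#'   metric after each iteration), `n_evaluations`.
#' @export
optimize_brute_force <- function(catheter, path, geometry, config,
                                 schedule = brute_force_schedule(),
                                 rotation_center = c(0, 0, 0)) {
  stopifnot(inherits(config, "metric_config"),
            inherits(schedule, "brute_force_schedule"))
  cath <- as_points2(catheter)
  pts <- as_points3(path)
  cath_arc <- cum_arc(cath)
  half <- c(rep(schedule$half_interval_rot_deg, 3),
            rep(schedule$half_interval_trans_mm, 2))
  res <- cpp_brute_force(
    cath, cath_arc, pts,
    cone_beam_matrix(geometry), geometry$detector_from_world,
    rep(0, 5), half,
    schedule$n_iterations, schedule$shrink, schedule$steps_per_dim,
    config$lambda, config$sigma, config$d_max,
    as.numeric(rotation_center))
  p <- res$params
  list(pose = pose_5dof(alpha = p[1], beta = p[2], gamma = p[3],
                        x = p[4], y = p[5], rotation_center = rotation_center),
       metric_mm = res$metric, trace = res$trace,
       n_evaluations = res$n_evaluations)
}

#' Two-stage Powell pose optimization
#'
#' Stage 1 minimizes the metric over the in-plane translation `(x, y)` with
#' the angles fixed at the initial pose; stage 2 minimizes over all five
#' parameters starting from the stage-1 result. Deterministic given the
#' initial pose and tolerances. A local method: it may converge to a local
#' minimum far from the global one.
#'
#' @inheritParams optimize_brute_force
#' @param init Initial [pose_5dof()] (default: the zero pose).
#' @param control Optional list overriding optimizer tolerances: `ftol`
#'   (metric, mm), `ptol` (parameters, mm/deg), `maxeval` per stage.
#' @return A list: `pose`, `metric_mm`, `converged`, `n_evaluations`.
#' @export
optimize_powell <- function(catheter, path, geometry, config,
                            init = pose_5dof(),
                            rotation_center = init$rotation_center,
                            control = list()) {
  stopifnot(inherits(config, "metric_config"))
  cath <- as_points2(catheter)
  pts <- as_points3(path)
  cath_arc <- cum_arc(cath)
  ctrl <- utils::modifyList(list(ftol = 1e-4, ptol = 1e-3, maxeval = 2000),
                            control)
  m34_of <- function(par) {
    pose <- pose_5dof(par[1], par[2], par[3], par[4], par[5],
                      rotation_center = rotation_center)
    projection_chain(compose_pose(pose, geometry), geometry)
  }
  fn5 <- function(par) {
    res <- cpp_metric(cath, cath_arc, pts, m34_of(par),
                      config$lambda, config$sigma, config$d_max)
    if (!is.finite(res$metric)) Inf else res$metric
  }
  p0 <- c(init$alpha, init$beta, init$gamma, init$x, init$y)
  # stage 1: in-plane translation only
  s1 <- powell_minimize(function(t) fn5(c(p0[1:3], t)), p0[4:5],
                        scale = c(50, 50), ftol = ctrl$ftol,
                        ptol = ctrl$ptol, maxeval = ctrl$maxeval)
  # stage 2: full 5 DOF from the stage-1 translation
  s2 <- powell_minimize(fn5, c(p0[1:3], s1$par),
                        scale = c(7, 7, 7, 10, 10), ftol = ctrl$ftol,
                        ptol = ctrl$ptol, maxeval = ctrl$maxeval)
  p <- s2$par
  list(pose = pose_5dof(alpha = p[1], beta = p[2], gamma = p[3],
                        x = p[4], y = p[5], rotation_center = rotation_center),
       metric_mm = s2$value,
       converged = s1$converged && s2$converged,
       n_evaluations = s1$n_evaluations + s2$n_evaluations)
}

#' Register a catheter to a vessel tree
#'
#' The full pipeline: resample tree and catheter at the metric sampling,
#' select up to `k` candidate leaf paths by shape similarity, truncate each
#' at its best tip node, optimize the five-parameter pose per candidate, and
#' keep the pair with the smallest metric.
#'
#' @param catheter Catheter centerline (tip first).
#' @param tree A [vessel_tree()].
#' @param geometry A [projection_geometry()].
#' @param optimizer `"brute_force"` or `"powell"`.
#' @param config A [metric_config()]; defaults to the optimizer's optimal
#'   settings.
#' @param k Number of candidate leaf paths (default 5).
#' @param schedule A [brute_force_schedule()] (brute force only).
#' @param rotation_center Rotation center (mm); defaults to the centroid of
#'   the tree's bounding box.
#' @param resample What to discretize at `config$sampling` before
#'   registering: `TRUE`/`"both"` (default), `"catheter"`, `"tree"`, or
#'   `FALSE`/`"none"` when the inputs are already discretized.
#' @return An object of class `catheter_registration`: best leaf, pose,
#'   metric, correspondences, and the per-candidate table (see
#'   [tidy.catheter_registration()]).
#' @export
register_catheter <- function(catheter, tree, geometry,
                              optimizer = c("brute_force", "powell"),
                              config = NULL, k = 5,
                              schedule = brute_force_schedule(),
                              rotation_center = NULL, resample = TRUE) {
  optimizer <- match.arg(optimizer)
  if (is.null(config)) {
    config <- if (optimizer == "brute_force") metric_config_brute()
              else metric_config_powell()
  }
  stopifnot(inherits(tree, "vessel_tree"), inherits(config, "metric_config"))
  if (is.null(rotation_center)) rotation_center <- tree_bbox_center(tree)
  if (isTRUE(resample)) resample <- "both"
  if (isFALSE(resample)) resample <- "none"
  resample <- match.arg(resample, c("both", "catheter", "tree", "none"))
  if (resample %in% c("both", "tree")) {
    tree <- resample_tree(tree, config$sampling)
  }
  if (resample %in% c("both", "catheter")) {
    catheter <- resample_centerline(as_points2(catheter), config$sampling)
  }
  cand <- select_candidates(catheter, tree, geometry, k = k)
  if (nrow(cand) == 0) {
    stop("no candidate leaf paths: the tree has no leaves", call. = FALSE)
  }
  fits <- purrr::map(seq_len(nrow(cand)), function(i) {
    # the full leaf path is registered; the tip term is free to match
    # anywhere along it, so shape-selection argmax jitter cannot shift the
    # registration longitudinally
    path <- path_to_root(tree, cand$leaf_id[i])
    if (optimizer == "brute_force") {
      fit <- optimize_brute_force(catheter, path, geometry, config,
                                  schedule = schedule,
                                  rotation_center = rotation_center)
      fit$converged <- TRUE
    } else {
      fit <- optimize_powell(catheter, path, geometry, config,
                             init = pose_5dof(rotation_center = rotation_center),
                             rotation_center = rotation_center)
    }
    fit$path <- path
    fit
  })
  metrics <- vapply(fits, function(f) f$metric_mm, numeric(1))
  best_i <- which.min(metrics)
  best <- fits[[best_i]]
  corr <- registration_metric(catheter, best$path, best$pose, geometry,
                              config)$correspondences
  cand$metric_mm <- metrics
  cand$alpha <- vapply(fits, function(f) f$pose$alpha, numeric(1))
  cand$beta <- vapply(fits, function(f) f$pose$beta, numeric(1))
  cand$gamma <- vapply(fits, function(f) f$pose$gamma, numeric(1))
  cand$x <- vapply(fits, function(f) f$pose$x, numeric(1))
  cand$y <- vapply(fits, function(f) f$pose$y, numeric(1))
  structure(list(
    best_leaf_id = cand$leaf_id[best_i],
    best_tip_node = cand$argmax_node[best_i],
    pose = best$pose,
    metric_mm = best$metric_mm,
    converged = best$converged,
    correspondences = corr,
    candidates = cand,
    best_path = best$path,
    catheter = catheter,
    tree = tree,
    geometry = geometry,
    config = config,
    optimizer = optimizer
  ), class = "catheter_registration")
}

#' @export
print.catheter_registration <- function(x, ...) {
  cat(sprintf("<catheter_registration> optimizer %s\n", x$optimizer))
  cat(sprintf("  best leaf '%s' (tip node '%s'), metric %.3f mm\n",
              x$best_leaf_id, x$best_tip_node, x$metric_mm))
  cat(sprintf("  pose: alpha %.2f, beta %.2f, gamma %.2f deg; x %.2f, y %.2f mm\n",
              x$pose$alpha, x$pose$beta, x$pose$gamma, x$pose$x, x$pose$y))
  cat(sprintf("  %d candidate(s) evaluated\n", nrow(x$candidates)))
  invisible(x)
}

# Generic multi-resolution grid refinement on an arbitrary objective;
# readable reference for the compiled search and the surrogate test bed.
grid_refine <- function(fn, center, half, n_iterations, shrink, steps_per_dim) {
  stopifnot(steps_per_dim %% 2 == 1)
  best_par <- center
  best_val <- fn(center)
  trace <- numeric(n_iterations)
  s <- half
  for (it in seq_len(n_iterations)) {
    center_it <- best_par
    offs <- lapply(s, function(h) seq(-h, h, length.out = steps_per_dim))
    grid <- as.matrix(expand.grid(offs, KEEP.OUT.ATTRS = FALSE))
    for (r in seq_len(nrow(grid))) {
      par <- center_it + grid[r, ]
      v <- fn(par)
      if (v < best_val) {
        best_val <- v
        best_par <- par
      }
    }
    trace[it] <- best_val
    s <- s * shrink
  }
  list(par = best_par, value = best_val, trace = trace)
}
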