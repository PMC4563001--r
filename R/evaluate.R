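#' Projected tip-error decomposition
#'
#' Splits the error between the known (ground-truth) projected tip and the
#' registered projected tip into the Euclidean distance `e_d`, the
#' longitudinal component `l_d` along the catheter direction at the true
#' tip, and the orthogonal component `o_d`, all reported as magnitudes with
#' `e_d^2 = l_d^2 + o_d^2`.
#'
#' @param true_tip_mm Length-2 ground-truth projected tip (mm).
#' @param registered_tip_mm Length-2 registered projected tip (mm).
#' @param tip_direction Unit 2-vector: catheter direction at the true tip.
#' @return A one-row tibble with columns `e_d`, `l_d`, `o_d` (mm).
#' @examples
#' tip_errors(c(0, 0), c(3, 4), c(1, 0))  # 3-4-5 triangle
#' @export
tip_errors <- function(true_tip_mm, registered_tip_mm, tip_direction) {
  stopifnot(length(true_tip_mm) == 2, length(registered_tip_mm) == 2,
            length(tip_direction) == 2)
  nrm <- sqrt(sum(tip_direction^2))
  if (abs(nrm - 1) > 1e-6) {
    stop("tip_direction must be a unit vector", call. = FALSE)
  }
  d <- as.numeric(registered_tip_mm) - as.numeric(true_tip_mm)
  t_hat <- as.numeric(tip_direction)
  o_hat <- c(-t_hat[2], t_hat[1])
  tibble::tibble(e_d = sqrt(sum(d^2)),
                 l_d = abs(sum(d * t_hat)),
                 o_d = abs(sum(d * o_hat)))
}

# Closest point on a polyline to p. Returns dist, the point, and whether the
# closest point is the polyline's first or last vertex (endpoint match).
closest_on_polyline <- function(p, poly) {
  n <- nrow(poly)
  if (n == 1) {
    return(list(distance = sqrt(sum((p - poly[1, ])^2)), point = poly[1, ],
                endpoint = TRUE))
  }
  a <- poly[-n, , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  t <- rowSums(sweep(-a, 2, -p) * ab) / pmax(len2, 1e-300)
  t <- pmin(pmax(t, 0), 1)
  cand <- a + ab * t
  d2 <- rowSums(sweep(cand, 2, p)^2)
  i <- which.min(d2)
  pt <- cand[i, ]
  eps <- 1e-9
  endpoint <- (i == 1 && sqrt(sum((pt - poly[1, ])^2)) < eps) ||
    (i == n - 1 && sqrt(sum((pt - poly[n, ])^2)) < eps)
  list(distance = sqrt(d2[i]), point = pt, endpoint = endpoint)
}

# Per-pair, per-direction sample table used by the paired-vessel metrics.
# Each row: one source sample with its closest distance to the paired
# polyline, its distance from the tip, and the endpoint-match flag.
paired_vessel_samples <- function(pairs, tip) {
  stopifnot(length(pairs) >= 1)
  tip <- as.numeric(tip)
  purrr::map_dfr(seq_along(pairs), function(i) {
    pair <- pairs[[i]]
    a <- as_points2(pair[[1]])
    b <- as_points2(pair[[2]])
    one_dir <- function(src, tgt, label) {
      res <- purrr::map(seq_len(nrow(src)), function(j)
        closest_on_polyline(src[j, ], tgt))
      tibble::tibble(
        pair_id = i, direction = label,
        tip_dist_mm = sqrt(rowSums(sweep(src, 2, tip)^2)),
        distance_mm = vapply(res, function(r) r$distance, numeric(1)),
        endpoint = vapply(res, function(r) r$endpoint, logical(1)))
    }
    dplyr::bind_rows(one_dir(a, b, "a_to_b"), one_dir(b, a, "b_to_a"))
  })
}

#' Mean closest-corresponding-points distance between paired vessels
#'
#' For each supplied pair of corresponding centerlines (typically a 2D
#' angiography vessel and its registered projected 3D partner) the symmetric
#' closest-point distance is computed in both directions, restricted to
#' source samples within `radius_mm` of the catheter tip, excluding samples
#' whose closest match lands on an endpoint of the other polyline (a
#' truncation artifact, not a correspondence). Direction means are averaged
#' per pair; the image-level score averages the pairs. Pairs with no
#' evaluable sample are dropped.
#'
#' @param pairs A list; each element a list/pair of two 2D polylines
#'   (data frames with `x_mm`, `y_mm` or n x 2 matrices).
#' @param tip Length-2 catheter tip (mm) defining the evaluation disk.
#' @param radius_mm Evaluation radius around the tip (default 30 mm).
#' @param detail If `TRUE`, also return the per-pair per-direction table.
#' @return The mean distance in mm; with `detail = TRUE`, a list
#'   `(mean_mm, table)` where `table` has one row per pair and direction
#'   (`pair_id`, `direction`, `n_samples`, `mean_mm`).
#' @export
paired_vessel_distance <- function(pairs, tip, radius_mm = 30, detail = FALSE) {
  stopifnot(radius_mm > 0)
  samples <- paired_vessel_samples(pairs, tip)
  keep <- samples[samples$tip_dist_mm <= radius_mm & !samples$endpoint, ]
  if (nrow(keep) == 0) {
    stop("no evaluable region: all pairs lie outside the tip radius or match endpoints",
         call. = FALSE)
  }
  dir_tbl <- dplyr::summarise(
    dplyr::group_by(keep, .data$pair_id, .data$direction),
    n_samples = dplyr::n(), mean_mm = mean(.data$distance_mm),
    .groups = "drop")
  pair_tbl <- dplyr::summarise(dplyr::group_by(dir_tbl, .data$pair_id),
                               mean_mm = mean(.data$mean_mm), .groups = "drop")
  score <- mean(pair_tbl$mean_mm)
  if (detail) list(mean_mm = score, table = dir_tbl) else score
}

#' Paired-vessel distance grouped by distance from the catheter tip
#'
#' The same closest-point distances as [paired_vessel_distance()] (endpoint
#' matches excluded, no radius cap), aggregated into bins of the source
#' sample's distance from the tip.
#'
#' @inheritParams paired_vessel_distance
#' @param bucket_edges Increasing numeric bin edges in mm
#'   (default `seq(0, 100, 10)`).
#' @return A tibble: `bucket_lo`, `bucket_hi`, `n_samples`, `mean_mm`
#'   (`NA` for empty bins).
#' @export
distance_by_tip_bucket <- function(pairs, tip, bucket_edges = seq(0, 100, 10)) {
  stopifnot(length(bucket_edges) >= 2, all(diff(bucket_edges) > 0))
  samples <- paired_vessel_samples(pairs, tip)
  samples <- samples[!samples$endpoint, ]
  bin <- cut(samples$tip_dist_mm, bucket_edges, include.lowest = TRUE,
             right = FALSE)
  out <- tibble::tibble(
    bucket_lo = bucket_edges[-length(bucket_edges)],
    bucket_hi = bucket_edges[-1])
  stats_tbl <- tapply(samples$distance_mm, bin, mean)
  cnt <- tapply(samples$distance_mm, bin, length)
  out$n_samples <- as.integer(ifelse(is.na(cnt), 0L, cnt))
  out$mean_mm <- as.numeric(stats_tbl)
  out
}

#' Full-factorial parameter sweep with leave-one-out selection
#'
#' Evaluates a scoring function over every combination of the metric
#' parameters on every case, reports the per-setting summary, the overall
#' best setting, and (optionally) the per-held-out-case best setting chosen
#' on the remaining cases.
#'
#' @param cases A list of cases; each is passed unchanged to `score_fn`.
#' @param lambda_grid,sigma_grid,d_max_grid,sampling_grid Numeric grids for
#'   the four metric parameters (see [metric_config()]).
#' @param score_fn `function(case, config) -> numeric` scalar score (lower
#'   is better), e.g. [sweep_score_registration()].
#' @param leave_one_out If `TRUE`, also compute the per-fold best settings.
#' @param summary `"mean"` (default) or `"median"` across cases.
#' @return A list: `table` (one row per setting with the summary `score`),
#'   `best` (the arg-min row), `scores` (case x setting matrix), and, when
#'   requested, `leave_one_out` (one row per held-out case with the setting
#'   chosen on the remainder and the held-out score).
#' @export
parameter_sweep <- function(cases, lambda_grid = c(0, 0.1, 0.2, 0.3),
                            sigma_grid = c(20, 40, 60, 80, 100),
                            d_max_grid = c(10, 20, 30, 40, 50),
                            sampling_grid = 3,
                            score_fn, leave_one_out = FALSE,
                            summary = c("mean", "median")) {
  summary <- match.arg(summary)
  stopifnot(length(cases) >= 1, is.function(score_fn))
  settings <- expand.grid(lambda = lambda_grid, sigma = sigma_grid,
                          d_max = d_max_grid, sampling = sampling_grid,
                          KEEP.OUT.ATTRS = FALSE)
  scores <- matrix(NA_real_, nrow = length(cases), ncol = nrow(settings))
  for (s in seq_len(nrow(settings))) {
    cfg <- metric_config(lambda = settings$lambda[s],
                         sigma = settings$sigma[s],
                         d_max = settings$d_max[s],
                         sampling = settings$sampling[s])
    scores[, s] <- vapply(cases, function(case) score_fn(case, cfg),
                          numeric(1))
  }
  agg <- if (summary == "mean") colMeans(scores) else
    apply(scores, 2, stats::median)
  table <- tibble::as_tibble(settings)
  table$score <- agg
  best <- table[which.min(agg), ]
  out <- list(table = table, best = best, scores = scores)
  if (leave_one_out && length(cases) > 1) {
    loo <- purrr::map_dfr(seq_along(cases), function(i) {
      rest <- scores[-i, , drop = FALSE]
      agg_rest <- if (summary == "mean") colMeans(rest) else
        apply(rest, 2, stats::median)
      b <- which.min(agg_rest)
      dplyr::bind_cols(tibble::tibble(held_out = i),
                       tibble::as_tibble(settings[b, , drop = FALSE]),
                       tibble::tibble(held_out_score = scores[i, b]))
    })
    out$leave_one_out <- loo
  }
  out
}

#' Registration-based sweep score
#'
#' Builds the default scoring function for [parameter_sweep()]: register the
#' case's catheter to its tree with the given metric configuration, project
#' the case's reference 3D vessels under the estimated pose, and return the
#' mean paired-vessel distance to the reference 2D vessels around the
#' catheter tip. Each case must carry `catheter`, `tree`, `geometry`, and
#' `pairs` (a list of `list(angio_2d, vessel_3d)` with matching labels).
#'
#' @param optimizer Optimizer handed to [register_catheter()].
#' @param radius_mm Evaluation radius (mm).
#' @param k Candidate count per registration.
#' @return A `function(case, config)` for [parameter_sweep()].
#' @export
sweep_score_registration <- function(optimizer = "powell", radius_mm = 30,
                                     k = 5) {
  function(case, config) {
    reg <- register_catheter(case$catheter, case$tree, case$geometry,
                             optimizer = optimizer, config = config, k = k)
    pairs <- purrr::map(case$pairs, function(pr) {
      list(as_points2(pr[[1]]),
           as.matrix(project_path(pr[[2]], reg$pose, case$geometry)))
    })
    tip <- as.numeric(as_points2(case$catheter)[1, ])
    paired_vessel_distance(pairs, tip, radius_mm = radius_mm)
  }
}
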