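#' Read and write vessel trees as JSON
#'
#' Schema: `{"nodes": [{"id", "x_mm", "y_mm", "z_mm", "parent_id"}]}` with
#' `parent_id` `null` for the root. Coordinates round-trip losslessly
#' (full-precision JSON numbers).
#'
#' @param tree A [vessel_tree()].
#' @param path File path.
#' @return `read_tree_json()` returns a [vessel_tree()];
#'   `write_tree_json()` returns `path` invisibly.
#' @export
write_tree_json <- function(tree, path) {
  stopifnot(inherits(tree, "vessel_tree"))
  jsonlite::write_json(list(nodes = tree$nodes), path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(obj$nodes) || !is.data.frame(obj$nodes)) {
    stop(sprintf("%s: expected a 'nodes' array of node records", path),
         call. = FALSE)
  }
  nodes <- obj$nodes
  if (!"parent_id" %in% names(nodes)) {
    stop(sprintf("%s: nodes lack a parent_id field", path), call. = FALSE)
  }
  vessel_tree(nodes)
}

#' Read and write catheter centerlines as CSV
#'
#' Plain CSV with header `u_mm,x_mm,y_mm`, rows ordered tip first. The arc
#' length column is recomputed on read.
#'
#' @param catheter A catheter centerline (see [catheter_centerline()]).
#' @param path File path.
#' @return `read_catheter_csv()` returns a [catheter_centerline()] tibble;
#'   `write_catheter_csv()` returns `path` invisibly.
#' @export
write_catheter_csv <- function(catheter, path) {
  cath <- catheter_centerline(as_points2(catheter))
  readr::write_csv(as.data.frame(cath[, c("u_mm", "x_mm", "y_mm")]), path)
  invisible(path)
}

#' @rdname write_catheter_csv
#' @export
read_catheter_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    u_mm = readr::col_double(), x_mm = readr::col_double(),
    y_mm = readr::col_double()))
  if (!all(c("x_mm", "y_mm") %in% names(df))) {
    stop(sprintf("%s: expected columns u_mm, x_mm, y_mm", path), call. = FALSE)
  }
  catheter_centerline(df[, c("x_mm", "y_mm")])
}

#' Read and write projection geometry as JSON
#'
#' Schema: `{"detector_from_world": [16 numbers, row-major], "sid_mm",
#' "sod_mm", "principal_point_mm": [u, v]}`.
#'
#' @param geometry A [projection_geometry()].
#' @param path File path.
#' @return `read_geometry_json()` returns a [projection_geometry()];
#'   `write_geometry_json()` returns `path` invisibly.
#' @export
write_geometry_json <- function(geometry, path) {
  stopifnot(inherits(geometry, "projection_geometry"))
  jsonlite::write_json(list(
    detector_from_world = as.numeric(t(geometry$detector_from_world)),
    sid_mm = geometry$sid_mm, sod_mm = geometry$sod_mm,
    principal_point_mm = geometry$principal_point_mm),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  need <- c("detector_from_world", "sid_mm", "sod_mm", "principal_point_mm")
  missing <- setdiff(need, names(obj))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing field '%s'", path, missing[1]), call. = FALSE)
  }
  if (length(obj$detector_from_world) != 16) {
    stop(sprintf("%s: detector_from_world must hold 16 numbers", path),
         call. = FALSE)
  }
  projection_geometry(
    sid_mm = obj$sid_mm, sod_mm = obj$sod_mm,
    principal_point_mm = obj$principal_point_mm,
    detector_from_world = matrix(obj$detector_from_world, 4, 4, byrow = TRUE))
}

#' Write a registration report as JSON
#'
#' Serializes the result of [register_catheter()]: the estimated pose, the
#' metric, the winning leaf, the per-candidate table, and the catheter-to-
#' vessel correspondences.
#'
#' @param result A `catheter_registration`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_registration_json <- function(result, path) {
  stopifnot(inherits(result, "catheter_registration"))
  jsonlite::write_json(list(
    optimizer = result$optimizer,
    pose = list(alpha = result$pose$alpha, beta = result$pose$beta,
                gamma = result$pose$gamma, x = result$pose$x,
                y = result$pose$y,
                rotation_center = result$pose$rotation_center),
    metric_mm = result$metric_mm,
    best_leaf_id = result$best_leaf_id,
    best_tip_node = result$best_tip_node,
    config = unclass(result$config),
    candidates = result$candidates[, c("leaf_id", "rank", "s_max", "metric_mm")],
    correspondences = result$correspondences),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write experiment tables as CSV
#'
#' @param experiment A tibble from [run_experiment()].
#' @param path File path.
#' @return `read_experiment_csv()` returns a tibble;
#'   `write_experiment_csv()` returns `path` invisibly.
#' @export
write_experiment_csv <- function(experiment, path) {
  readr::write_csv(as.data.frame(experiment), path)
  invisible(path)
}

#' @rdname write_experiment_csv
#' @export
read_experiment_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
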