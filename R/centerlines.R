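#' Catheter centerline
#'
#' Wraps an ordered 2D polyline (tip first) as a catheter centerline tibble
#' with an arc-length column. The first annotated point is taken to be the
#' catheter tip and is always retained by [resample_centerline()].
#'
#' @param points A data frame with columns `x_mm`, `y_mm` (tip first), or an
#'   n x 2 matrix. At least two points; consecutive points must be distinct.
#' @return A tibble with columns `u_mm`, `x_mm`, `y_mm` and class `catheter`.
#' @examples
#' cath <- catheter_centerline(data.frame(x_mm = c(0, 10, 10), y_mm = c(0, 0, 10)))
#' centerline_length(cath)
#' @export
catheter_centerline <- function(points) {
  pts <- as_points2(points)
  if (nrow(pts) < 2) {
    stop("a catheter centerline needs at least 2 points", call. = FALSE)
  }
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  if (any(seg <= 0)) {
    stop("consecutive catheter points must be distinct", call. = FALSE)
  }
  out <- tibble::tibble(u_mm = c(0, cumsum(seg)), x_mm = pts[, 1], y_mm = pts[, 2])
  class(out) <- c("catheter", class(out))
  out
}

#' Polyline arc length
#'
#' @param points A polyline: data frame with `x_mm`, `y_mm` (and optionally
#'   `z_mm`) or a numeric matrix with 2 or 3 columns.
#' @return Total arc length in mm.
#' @export
centerline_length <- function(points) {
  pts <- as_polyline(points)
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

# Accept 2- or 3-column polylines as a plain matrix.
as_polyline <- function(points) {
  if (is.data.frame(points)) {
    if (all(c("x_mm", "y_mm", "z_mm") %in% names(points))) {
      return(as_points3(points))
    }
    return(as_points2(points))
  }
  pts <- as.matrix(points)
  if (length(pts) == 0) return(matrix(numeric(0), ncol = 2))
  stopifnot(ncol(pts) %in% c(2, 3), is.numeric(pts))
  dimnames(pts) <- NULL
  pts
}

# Cumulative arc length (first element 0).
cum_arc <- function(pts) {
  if (nrow(pts) < 2) return(0)
  c(0, cumsum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                              pts[-nrow(pts), , drop = FALSE])^2))))
}

#' Resample a polyline at a fixed arc-length spacing
#'
#' Output points lie on the input polyline at arc lengths `0, s, 2s, ...`;
#' the first and last input points are always retained, so the total length
#' is preserved to within one spacing (the final segment may be shorter).
#'
#' @param points A 2D or 3D polyline (see [centerline_length()]).
#' @param spacing_mm Target inter-point spacing in mm (> 0).
#' @return A tibble with `x_mm`, `y_mm` (and `z_mm` for 3D input) plus the
#'   arc-length column `u_mm`.
#' @examples
#' seg <- data.frame(x_mm = c(0, 30), y_mm = c(0, 0))
#' nrow(resample_centerline(seg, 3))  # 11 points at 0, 3, ..., 30 mm
#' @export
resample_centerline <- function(points, spacing_mm) {
  stopifnot(is.numeric(spacing_mm), length(spacing_mm) == 1, spacing_mm > 0)
  pts <- as_polyline(points)
  if (nrow(pts) < 2) {
    stop("cannot resample a polyline with fewer than 2 points", call. = FALSE)
  }
  arc <- cum_arc(pts)
  total <- arc[length(arc)]
  if (total <= 0) {
    stop("cannot resample a zero-length polyline", call. = FALSE)
  }
  u <- seq(0, total, by = spacing_mm)
  # retain the endpoint; merge a final sample that collides with it
  if (total - u[length(u)] > 1e-9 * max(1, total)) {
    u <- c(u, total)
  } else {
    u[length(u)] <- total
  }
  out <- interp_polyline(pts, arc, u)
  res <- tibble::tibble(u_mm = u, x_mm = out[, 1], y_mm = out[, 2])
  if (ncol(pts) == 3) res$z_mm <- out[, 3]
  if (inherits(points, "catheter")) class(res) <- c("catheter", class(res))
  res
}

# Vectorized linear interpolation at arc lengths u (all within [0, total]).
interp_polyline <- function(pts, arc, u) {
  idx <- findInterval(u, arc, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nrow(pts) - 1L)
  seg_len <- arc[idx + 1L] - arc[idx]
  t <- ifelse(seg_len > 0, (u - arc[idx]) / seg_len, 0)
  pts[idx, , drop = FALSE] +
    (pts[idx + 1L, , drop = FALSE] - pts[idx, , drop = FALSE]) * t
}

#' Point on a polyline at a given arc length
#'
#' Linear interpolation along the polyline, the discrete realization of the
#' interpolated centerlines `C_2D(u)` and `V_proj,T(p, u)`.
#'
#' @inheritParams centerline_length
#' @param u_mm Arc length from the first point (mm), within `[0, length]`.
#' @return Numeric point (length 2 or 3).
#' @export
point_at <- function(points, u_mm) {
  pts <- as_polyline(points)
  arc <- cum_arc(pts)
  total <- arc[length(arc)]
  stopifnot(length(u_mm) == 1, is.finite(u_mm))
  if (u_mm < -1e-9 || u_mm > total + 1e-9) {
    stop(sprintf("arc length %.3f outside [0, %.3f]", u_mm, total), call. = FALSE)
  }
  u_mm <- min(max(u_mm, 0), total)
  as.numeric(interp_polyline(pts, arc, u_mm))
}

#' Unit tangent of a polyline at a given arc length
#'
#' Tangents are per-segment constants (finite differences of consecutive
#' points), oriented from the tip toward the proximal end (increasing arc
#' length). At an interior vertex the outgoing (proximal-side) segment is
#' used; at the very end the last segment is used.
#'
#' @inheritParams point_at
#' @return Unit numeric vector (length 2 or 3).
#' @export
unit_tangent_at <- function(points, u_mm) {
  pts <- as_polyline(points)
  arc <- cum_arc(pts)
  total <- arc[length(arc)]
  stopifnot(length(u_mm) == 1, is.finite(u_mm))
  if (u_mm < -1e-9 || u_mm > total + 1e-9) {
    stop(sprintf("arc length %.3f outside [0, %.3f]", u_mm, total), call. = FALSE)
  }
  u_mm <- min(max(u_mm, 0), total)
  # segment whose [arc_k, arc_{k+1}) contains u; u == total -> last segment
  idx <- findInterval(u_mm, arc)
  idx <- min(max(idx, 1L), nrow(pts) - 1L)
  d <- pts[idx + 1L, ] - pts[idx, ]
  n <- sqrt(sum(d^2))
  if (n <= 0) {
    stop("zero-length segment: tangent undefined", call. = FALSE)
  }
  as.numeric(d / n)
}

# Per-segment unit tangents and segment lengths of a polyline, dropping
# zero-length segments (duplicate vertices). Returns list(tangents, lengths,
# arc0) with arc0 the arc length at each kept segment's start.
segment_tangents <- function(pts) {
  d <- pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  arc0 <- c(0, cumsum(len))[seq_along(len)]
  keep <- len > 1e-12
  list(tangents = d[keep, , drop = FALSE] / len[keep],
       lengths = len[keep], arc0 = arc0[keep])
}
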