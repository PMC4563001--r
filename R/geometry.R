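#' C-arm cone-beam projection geometry
#'
#' Describes the fixed imaging chain of a C-arm: the rigid transform from the
#' world frame (origin at the iso-center) to the detector frame, and the
#' cone-beam intrinsics mapping detector-frame 3D points onto the 2D
#' fluoroscopic image plane. The detector frame shares its origin with the
#' world iso-center; its z axis is the projection axis (source at
#' `z = -sod_mm`, detector plane at `z = sid_mm - sod_mm`).
#'
#' @param sid_mm Source-to-detector distance (mm). Must exceed `sod_mm`.
#' @param sod_mm Source-to-isocenter distance (mm). Must be positive.
#' @param principal_point_mm Length-2 numeric, principal point in
#'   fluoroscopic image coordinates (mm). With the default identity
#'   orientation, the world iso-center projects exactly there.
#' @param detector_from_world 4x4 rigid homogeneous transform from the world
#'   frame to the detector frame (rotation block orthonormal with
#'   determinant +1).
#'
#' @return An object of class `projection_geometry`.
#' @examples
#' geom <- projection_geometry(sid_mm = 1200, sod_mm = 810)
#' project_point(c(0, 0, 0), diag(4), geom)  # the principal point
#' @export
projection_geometry <- function(sid_mm = 1200, sod_mm = 810,
                                principal_point_mm = c(0, 0),
                                detector_from_world = diag(4)) {
  stopifnot(is.numeric(sid_mm), length(sid_mm) == 1,
            is.numeric(sod_mm), length(sod_mm) == 1,
            length(principal_point_mm) == 2)
  if (!(sid_mm > sod_mm && sod_mm > 0)) {
    stop("projection geometry requires sid_mm > sod_mm > 0", call. = FALSE)
  }
  detector_from_world <- as_rigid_transform(detector_from_world,
                                            what = "detector_from_world")
  structure(
    list(sid_mm = sid_mm, sod_mm = sod_mm,
         principal_point_mm = as.numeric(principal_point_mm),
         detector_from_world = detector_from_world),
    class = "projection_geometry"
  )
}

#' @export
print.projection_geometry <- function(x, ...) {
  cat("<projection_geometry>\n")
  cat(sprintf("  SID %.1f mm, SOD %.1f mm (magnification %.3f at iso-center)\n",
              x$sid_mm, x$sod_mm, x$sid_mm / x$sod_mm))
  cat(sprintf("  principal point (%.2f, %.2f) mm\n",
              x$principal_point_mm[1], x$principal_point_mm[2]))
  rot_is_id <- isTRUE(all.equal(x$detector_from_world, diag(4),
                                tolerance = 1e-12, check.attributes = FALSE))
  cat("  detector_from_world:", if (rot_is_id) "identity" else "custom rigid", "\n")
  invisible(x)
}

# Validate a 4x4 rigid homogeneous transform; returns it as a plain matrix.
as_rigid_transform <- function(m, what = "transform", tol = 1e-8) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(4, 4))) {
    stop(sprintf("%s must be a 4x4 matrix", what), call. = FALSE)
  }
  R <- m[1:3, 1:3]
  ok <- max(abs(crossprod(R) - diag(3))) < tol &&
    abs(det(R) - 1) < tol &&
    max(abs(m[4, ] - c(0, 0, 0, 1))) < tol
  if (!ok) {
    stop(sprintf("%s is not a rigid transform (orthonormal rotation, det +1)",
                 what), call. = FALSE)
  }
  dimnames(m) <- NULL
  m
}

# 3x4 cone-beam intrinsic matrix T_proj: detector frame -> homogeneous
# fluoroscopic coordinates. Divide by the third row to get image mm.
cone_beam_matrix <- function(geometry) {
  pp <- geometry$principal_point_mm
  sid <- geometry$sid_mm
  sod <- geometry$sod_mm
  matrix(c(sid, 0,   pp[1], pp[1] * sod,
           0,   sid, pp[2], pp[2] * sod,
           0,   0,   1,     sod),
         nrow = 3, byrow = TRUE)
}

# Full projective chain for a given 4x4 pose transform T (world <- 3DRA):
# fluoro_hom = T_proj . T_det<-w . T . p_hom
projection_chain <- function(transform, geometry) {
  cone_beam_matrix(geometry) %*% geometry$detector_from_world %*% transform
}

#' Five-degrees-of-freedom registration pose
#'
#' The unknowns of the 2D/3D registration: three Euler angles (degrees) and
#' two detector-plane translations (mm). Translation along the projection
#' axis is excluded: for points far from the source it changes the projection
#' only marginally, so it is unrecoverable from a single view.
#'
#' The rotation acts about `rotation_center` (a point in the 3D vessel-tree
#' frame). Angles follow a fixed documented convention: the rotation matrix
#' is `Rz(gamma) %*% Ry(beta) %*% Rx(alpha)` (extrinsic x-y-z, equivalently
#' intrinsic z-y'-x''). The convention is configuration, not inference: the
#' angles are search variables, never reported quantities.
#'
#' @param alpha,beta,gamma Euler angles in degrees.
#' @param x,y Translations (mm) along the detector in-plane axes.
#' @param rotation_center Length-3 point (mm) about which the rotation acts.
#' @return An object of class `pose_5dof`.
#' @examples
#' compose_pose(pose_5dof(), projection_geometry())  # identity
#' @export
pose_5dof <- function(alpha = 0, beta = 0, gamma = 0, x = 0, y = 0,
                      rotation_center = c(0, 0, 0)) {
  stopifnot(length(rotation_center) == 3)
  vals <- c(alpha = alpha, beta = beta, gamma = gamma, x = x, y = y)
  stopifnot(is.numeric(vals), all(is.finite(vals)))
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma, x = x, y = y,
         rotation_center = as.numeric(rotation_center)),
    class = "pose_5dof"
  )
}

#' @export
print.pose_5dof <- function(x, ...) {
  cat(sprintf(
    "<pose_5dof> alpha %.3f, beta %.3f, gamma %.3f deg; x %.3f, y %.3f mm\n",
    x$alpha, x$beta, x$gamma, x$x, x$y))
  cat(sprintf("  rotation center (%.1f, %.1f, %.1f) mm\n",
              x$rotation_center[1], x$rotation_center[2], x$rotation_center[3]))
  invisible(x)
}

# Rotation matrix from Euler angles in degrees, Rz(g) Ry(b) Rx(a).
euler_zyx <- function(alpha, beta, gamma) {
  a <- alpha * pi / 180; b <- beta * pi / 180; g <- gamma * pi / 180
  rx <- matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, byrow = TRUE)
  ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
  rz <- matrix(c(cos(g), -sin(g), 0, sin(g), cos(g), 0, 0, 0, 1), 3, byrow = TRUE)
  rz %*% ry %*% rx
}

translation4 <- function(v) {
  m <- diag(4)
  m[1:3, 4] <- v
  m
}

#' Compose a 5-DOF pose into a 4x4 rigid world-from-tree transform
#'
#' Builds `T_w<-3DRA = T_w<-det . T_trans . T_det<-w . T_rot`: the rotation
#' acts in the vessel-tree frame about the pose's rotation center, while the
#' translation `(x, y)` (optionally a depth offset `z_mm`) is applied along
#' the detector axes, where the search lives.
#'
#' @param pose A [pose_5dof()].
#' @param geometry A [projection_geometry()].
#' @param z_mm Depth translation along the projection axis (mm). Excluded
#'   from registration, but a physical perturbation when simulating ground
#'   truth; default 0.
#' @return A 4x4 rigid homogeneous matrix.
#' @export
compose_pose <- function(pose, geometry, z_mm = 0) {
  stopifnot(inherits(pose, "pose_5dof"), inherits(geometry, "projection_geometry"))
  tdw <- geometry$detector_from_world
  twd <- solve(tdw)
  rot <- diag(4)
  rot[1:3, 1:3] <- euler_zyx(pose$alpha, pose$beta, pose$gamma)
  c3 <- pose$rotation_center
  t_rot <- translation4(c3) %*% rot %*% translation4(-c3)
  t_trans <- translation4(c(pose$x, pose$y, z_mm))
  out <- twd %*% t_trans %*% tdw %*% t_rot
  # guard against numerical drift in long compositions
  out[4, ] <- c(0, 0, 0, 1)
  out
}

#' Project 3D points onto the fluoroscopic image
#'
#' Applies the cone-beam projection `F_proj(p, T) = T_proj . T_det<-w . T . p`
#' with homogeneous normalization. Points must lie strictly on the detector
#' side of the X-ray source (positive depth).
#'
#' @param p Length-3 numeric point (mm, vessel-tree frame).
#' @param transform Either a 4x4 rigid matrix or a [pose_5dof()].
#' @param geometry A [projection_geometry()].
#' @return For `project_point()`, a length-2 numeric (mm, image frame). For
#'   `project_path()`, a tibble with columns `x_mm`, `y_mm`, one row per
#'   input point, order preserved.
#' @examples
#' geom <- projection_geometry(sid_mm = 1200, sod_mm = 800)
#' project_point(c(10, 0, 0), diag(4), geom)  # magnified by 1200/800 = 1.5
#' @export
project_point <- function(p, transform, geometry) {
  stopifnot(length(p) == 3)
  out <- project_matrix(matrix(as.numeric(p), nrow = 1), transform, geometry)
  as.numeric(out)
}

#' @param points An n x 3 matrix or a data frame with columns `x_mm`, `y_mm`,
#'   `z_mm`; ordered points of a path.
#' @rdname project_point
#' @export
project_path <- function(points, transform, geometry) {
  pts <- as_points3(points)
  out <- project_matrix(pts, transform, geometry)
  tibble::tibble(x_mm = out[, 1], y_mm = out[, 2])
}

# n x 3 matrix in -> n x 2 matrix out; errors on non-positive depth with the
# offending row index.
project_matrix <- function(pts, transform, geometry) {
  if (inherits(transform, "pose_5dof")) {
    transform <- compose_pose(transform, geometry)
  } else {
    transform <- as_rigid_transform(transform, what = "transform")
  }
  if (nrow(pts) == 0) {
    return(matrix(numeric(0), ncol = 2))
  }
  m <- projection_chain(transform, geometry)
  hom <- m %*% rbind(t(pts), 1)
  depth <- hom[3, ]
  bad <- which(depth <= 1e-9)
  if (length(bad) > 0) {
    stop(sprintf(
      "degenerate projection: point %d at or behind the X-ray source plane",
      bad[1]), call. = FALSE)
  }
  cbind(hom[1, ] / depth, hom[2, ] / depth)
}

# Coerce a path argument to an n x 3 numeric matrix.
as_points3 <- function(points) {
  if (is.data.frame(points)) {
    need <- c("x_mm", "y_mm", "z_mm")
    if (!all(need %in% names(points))) {
      stop("3D points need columns x_mm, y_mm, z_mm", call. = FALSE)
    }
    pts <- as.matrix(points[, need])
  } else {
    pts <- as.matrix(points)
  }
  if (length(pts) == 0) {
    return(matrix(numeric(0), ncol = 3))
  }
  stopifnot(ncol(pts) == 3, is.numeric(pts))
  dimnames(pts) <- NULL
  pts
}

# Coerce a 2D polyline argument to an n x 2 numeric matrix.
as_points2 <- function(points) {
  if (is.data.frame(points)) {
    need <- c("x_mm", "y_mm")
    if (!all(need %in% names(points))) {
      stop("2D points need columns x_mm, y_mm", call. = FALSE)
    }
    pts <- as.matrix(points[, need])
  } else {
    pts <- as.matrix(points)
  }
  if (length(pts) == 0) {
    return(matrix(numeric(0), ncol = 2))
  }
  stopifnot(ncol(pts) == 2, is.numeric(pts))
  dimnames(pts) <- NULL
  pts
}
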