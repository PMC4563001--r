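#' Tangent-based shape similarity between catheter and projected vessel
#'
#' Scores how well a candidate vessel path, projected under the *identity*
#' pose, matches the catheter shape: the integral over the catheter arc of
#' the dot product between the catheter's unit tangent and the projected
#' vessel's unit tangent at the same arc length from the candidate tip,
#' discretized as a sum over catheter segments. Because only tangents enter,
#' the score is insensitive to the distance between the two centerlines; its
#' maximum is the catheter length `C_l` (identical shape), and antiparallel
#' geometry scores negative. Catheter arcs beyond the projected vessel's
#' length contribute zero, penalizing too-short candidates.
#'
#' The catheter is used at its given sampling; resample it first (see
#' [resample_centerline()]) to control the discretization.
#'
#' @param catheter A catheter centerline (data frame with `x_mm`, `y_mm`,
#'   tip first).
#' @param path A 3D vessel path, tip first (data frame with `x_mm`, `y_mm`,
#'   `z_mm` or an n x 3 matrix), e.g. from [path_to_root()].
#' @param geometry A [projection_geometry()].
#' @return Similarity in mm, within `[-C_l, C_l]`.
#' @examples
#' geom <- projection_geometry()
#' path <- data.frame(x_mm = c(0, 30), y_mm = c(0, 0), z_mm = 0)
#' cath <- project_path(path, diag(4), geom)
#' shape_similarity(cath, path, geom)  # equals the catheter length
#' @export
shape_similarity <- function(catheter, path, geometry) {
  cath <- as_points2(catheter)
  pts <- as_points3(path)
  if (nrow(cath) < 2 || nrow(pts) < 1) {
    stop("shape_similarity needs a catheter with >= 2 points and a non-empty path",
         call. = FALSE)
  }
  proj <- project_matrix(pts, diag(4), geometry)
  shape_similarity_2d(cath, proj)
}

# Core similarity between a 2D catheter polyline and a 2D projected vessel
# polyline (both tip-first).
shape_similarity_2d <- function(cath, vproj) {
  cseg <- segment_tangents(cath)
  if (length(cseg$lengths) == 0) return(0)
  if (nrow(vproj) < 2) return(0)
  vseg <- segment_tangents(vproj)
  if (length(vseg$lengths) == 0) return(0)
  u_mid <- cseg$arc0 + cseg$lengths / 2
  varc <- c(vseg$arc0, vseg$arc0[length(vseg$arc0)] + vseg$lengths[length(vseg$lengths)])
  k <- findInterval(u_mid, varc)         # 0 never occurs (u_mid > 0)
  inside <- k >= 1 & k <= length(vseg$lengths)
  if (!any(inside)) return(0)
  dots <- rowSums(cseg$tangents[inside, , drop = FALSE] *
                    vseg$tangents[k[inside], , drop = FALSE])
  sum(dots * cseg$lengths[inside])
}

#' Best similarity along a leaf path
#'
#' For one leaf, scans every node `p` of the root-ward leaf path as a
#' candidate catheter-tip location and returns the maximum shape similarity
#' `S_max(l) = max_{p in V(l)} S(p)`, with the attaining node. Ties break
#' toward the node closer to the leaf.
#'
#' @param catheter A catheter centerline (resampled; tip first).
#' @param tree A [vessel_tree()].
#' @param leaf_id A leaf node id.
#' @param geometry A [projection_geometry()].
#' @return A one-row tibble: `leaf_id`, `s_max`, `argmax_node`.
#' @export
leaf_max_similarity <- function(catheter, tree, leaf_id, geometry) {
  stopifnot(inherits(tree, "vessel_tree"))
  leaf_id <- as.character(leaf_id)
  if (!leaf_id %in% tree_leaves(tree)) {
    stop(sprintf("'%s' is not a leaf of the tree", leaf_id), call. = FALSE)
  }
  cath <- as_points2(catheter)
  if (nrow(cath) < 2) stop("catheter needs >= 2 points", call. = FALSE)
  path <- path_to_root(tree, leaf_id)
  proj <- project_matrix(as_points3(path), diag(4), geometry)
  scores <- suffix_similarities(cath, proj)
  best <- which.max(scores)   # first max = node closest to the leaf
  tibble::tibble(leaf_id = leaf_id, s_max = scores[best],
                 argmax_node = path$id[best])
}

# S(p) for every suffix of the projected leaf path (p = each node, walking
# root-ward from it). Vectorized: the projection under the identity pose is
# shared by all suffixes, only the arc origin shifts.
suffix_similarities <- function(cath, vproj) {
  n <- nrow(vproj)
  cseg <- segment_tangents(cath)
  if (length(cseg$lengths) == 0) return(rep(0, n))
  varc <- cum_arc(vproj)
  vseg_d <- vproj[-1, , drop = FALSE] - vproj[-n, , drop = FALSE]
  vlen <- sqrt(rowSums(vseg_d^2))
  ok <- vlen > 1e-12
  # tangent per (possibly degenerate) segment; degenerate ones never matched
  tvx <- ifelse(ok, vseg_d[, 1] / vlen, 0)
  tvy <- ifelse(ok, vseg_d[, 2] / vlen, 0)
  u_mid <- cseg$arc0 + cseg$lengths / 2
  scores <- numeric(n)
  # arc positions of each catheter segment midpoint, offset per start node
  u_all <- outer(varc, u_mid, "+")       # n x n_cseg
  k <- matrix(findInterval(u_all, varc), nrow = n)
  k[k >= n] <- NA                        # beyond the vessel end -> 0
  kk <- k
  valid <- !is.na(kk)
  kk[!valid] <- 1L
  dot <- (matrix(tvx[kk], nrow = n) * rep(cseg$tangents[, 1], each = n) +
            matrix(tvy[kk], nrow = n) * rep(cseg$tangents[, 2], each = n))
  dot[!valid] <- 0
  as.numeric(dot %*% cseg$lengths)
}

#' Select candidate leaf paths by shape similarity
#'
#' Ranks all leaves by `S_max`, removes duplicates that share the same
#' common part with the catheter (leaf paths whose node sequences, truncated
#' at their best tip node and spanning one catheter length of projected arc,
#' are identical keep only the highest-scoring representative), and returns
#' up to `k` candidates.
#'
#' @inheritParams leaf_max_similarity
#' @param k Maximum number of candidates (default 5).
#' @return A tibble ordered by decreasing `s_max`: `leaf_id`, `s_max`,
#'   `argmax_node`, `rank`.
#' @export
select_candidates <- function(catheter, tree, geometry, k = 5) {
  stopifnot(inherits(tree, "vessel_tree"), k >= 1)
  leaves <- tree_leaves(tree)
  cand <- purrr::map_dfr(leaves, function(l)
    leaf_max_similarity(catheter, tree, l, geometry))
  cand <- cand[order(-cand$s_max, cand$leaf_id), ]
  cath_len <- centerline_length(as_points2(catheter))
  key <- vapply(seq_len(nrow(cand)), function(i) {
    path <- path_to_root(tree, cand$argmax_node[i])
    proj <- project_matrix(as_points3(path), diag(4), geometry)
    arc <- cum_arc(proj)
    keep <- arc <= cath_len + 1e-9
    paste(path$id[keep], collapse = "|")
  }, character(1))
  cand <- cand[!duplicated(key), ]
  cand <- utils::head(cand, k)
  cand$rank <- seq_len(nrow(cand))
  cand
}
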