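#' Directed vessel-tree centerline
#'
#' A 3D arterial centerline tree: nodes with coordinates (mm) and directed
#' child-to-parent edges toward a single root (the aortic end). Every
#' algorithm here walks root-ward, so edges are stored as a `parent_id`
#' column; the root is the unique node with `parent_id = NA`.
#'
#' @param nodes A data frame with columns `id`, `x_mm`, `y_mm`, `z_mm`,
#'   `parent_id` (`NA` for the root). Ids are coerced to character and must
#'   be unique.
#' @return An object of class `vessel_tree` (list with a `nodes` tibble).
#' @examples
#' chain <- vessel_tree(data.frame(
#'   id = 1:3, x_mm = c(0, 0, 0), y_mm = c(0, 10, 20), z_mm = 0,
#'   parent_id = c(NA, 1, 2)))
#' tree_leaves(chain)
#' @export
vessel_tree <- function(nodes) {
  stopifnot(is.data.frame(nodes))
  need <- c("id", "x_mm", "y_mm", "z_mm", "parent_id")
  if (!all(need %in% names(nodes))) {
    stop("tree nodes need columns id, x_mm, y_mm, z_mm, parent_id", call. = FALSE)
  }
  nodes <- tibble::as_tibble(nodes[, need])
  nodes$id <- as.character(nodes$id)
  nodes$parent_id <- as.character(nodes$parent_id)
  if (anyDuplicated(nodes$id)) {
    stop(sprintf("duplicate node id: %s",
                 nodes$id[duplicated(nodes$id)][1]), call. = FALSE)
  }
  root <- which(is.na(nodes$parent_id))
  if (length(root) != 1) {
    stop(sprintf("a vessel tree needs exactly one root, found %d",
                 length(root)), call. = FALSE)
  }
  missing_parent <- setdiff(nodes$parent_id[!is.na(nodes$parent_id)], nodes$id)
  if (length(missing_parent) > 0) {
    stop(sprintf("unknown parent id: %s", missing_parent[1]), call. = FALSE)
  }
  tree <- structure(list(nodes = nodes, root_id = nodes$id[root]),
                    class = "vessel_tree")
  # connectivity / acyclicity: every node must reach the root
  depth <- node_depths(tree)
  if (anyNA(depth)) {
    stop(sprintf("node %s does not reach the root (cycle or disconnection)",
                 names(depth)[which(is.na(depth))[1]]), call. = FALSE)
  }
  tree
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("<vessel_tree> %d nodes, %d leaves, root '%s'\n",
              nrow(x$nodes), length(tree_leaves(x)), x$root_id))
  invisible(x)
}

# Named parent lookup (character, NA for root).
parent_map <- function(tree) {
  stats::setNames(tree$nodes$parent_id, tree$nodes$id)
}

# Depth of each node (root = 0); NA marks nodes that never reach the root.
node_depths <- function(tree) {
  parents <- parent_map(tree)
  n <- length(parents)
  depth <- stats::setNames(rep(NA_real_, n), names(parents))
  depth[tree$root_id] <- 0
  for (id in names(parents)) {
    if (!is.na(depth[id])) next
    chain <- character(0)
    cur <- id
    steps <- 0
    while (is.na(depth[cur])) {
      chain <- c(chain, cur)
      cur <- parents[[cur]]
      steps <- steps + 1
      if (is.na(cur) || steps > n) break
    }
    if (!is.na(cur) && !is.na(depth[cur])) {
      depth[rev(chain)] <- depth[cur] + seq_along(chain)
    }
  }
  depth
}

#' Leaves of a vessel tree
#'
#' @param tree A [vessel_tree()].
#' @return Character vector of node ids with no children.
#' @export
tree_leaves <- function(tree) {
  stopifnot(inherits(tree, "vessel_tree"))
  setdiff(tree$nodes$id, tree$nodes$parent_id[!is.na(tree$nodes$parent_id)])
}

#' Root-ward vessel path from a node
#'
#' The vessel centerline `V(p)`: the ordered points from `node_id` along the
#' directed edges to the root. For the root itself this is a single-point
#' path.
#'
#' @param tree A [vessel_tree()].
#' @param node_id Node id (coerced to character).
#' @return A tibble with columns `id`, `x_mm`, `y_mm`, `z_mm`, first row the
#'   start node, last row the root.
#' @export
path_to_root <- function(tree, node_id) {
  stopifnot(inherits(tree, "vessel_tree"))
  node_id <- as.character(node_id)
  if (!node_id %in% tree$nodes$id) {
    stop(sprintf("unknown node id: %s", node_id), call. = FALSE)
  }
  parents <- parent_map(tree)
  ids <- character(0)
  cur <- node_id
  while (!is.na(cur)) {
    ids <- c(ids, cur)
    cur <- parents[[cur]]
  }
  idx <- match(ids, tree$nodes$id)
  tree$nodes[idx, c("id", "x_mm", "y_mm", "z_mm")]
}

#' Resample a vessel tree at a fixed arc-length spacing
#'
#' Resamples every unbranched run of the tree (leaf/junction to the next
#' junction or root) at `spacing_mm`, so every root-ward path in the output
#' is, up to the retained junction vertices, the arc-length resampling of
#' the corresponding input path. Branch points are preserved exactly:
#' merging them would change which leaves share a common trunk.
#'
#' @inheritParams path_to_root
#' @param spacing_mm Target spacing in mm (> 0).
#' @return A new [vessel_tree()]. Anchor nodes (root, junctions, leaves)
#'   keep their ids; interior resampled nodes get derived ids.
#' @export
resample_tree <- function(tree, spacing_mm) {
  stopifnot(inherits(tree, "vessel_tree"),
            is.numeric(spacing_mm), length(spacing_mm) == 1, spacing_mm > 0)
  nodes <- tree$nodes
  parents <- parent_map(tree)
  kids <- table(nodes$parent_id[!is.na(nodes$parent_id)])
  n_children <- stats::setNames(rep(0L, nrow(nodes)), nodes$id)
  n_children[names(kids)] <- as.integer(kids)
  anchors <- nodes$id[n_children != 1L | nodes$id == tree$root_id]
  coords <- as.matrix(nodes[, c("x_mm", "y_mm", "z_mm")])
  rownames(coords) <- nodes$id

  out_id <- character(0); out_xyz <- NULL; out_parent <- character(0)
  add_node <- function(id, xyz, parent) {
    out_id <<- c(out_id, id)
    out_xyz <<- rbind(out_xyz, xyz)
    out_parent <<- c(out_parent, parent)
  }
  add_node(tree$root_id, coords[tree$root_id, ], NA_character_)

  for (start in setdiff(anchors, tree$root_id)) {
    # walk root-ward to the nearest anchor (exclusive of start)
    ids <- start
    cur <- parents[[start]]
    while (!(cur %in% anchors)) {
      ids <- c(ids, cur)
      cur <- parents[[cur]]
    }
    end <- cur                       # anchor on the root side
    run <- coords[c(ids, end), , drop = FALSE]
    seg <- sqrt(rowSums((run[-1, , drop = FALSE] - run[-nrow(run), , drop = FALSE])^2))
    if (any(seg <= 0)) {
      stop(sprintf("degenerate (zero-length) edge at node %s",
                   ids[which(seg <= 0)[1]]), call. = FALSE)
    }
    res <- as.matrix(resample_centerline(run, spacing_mm)[, c("x_mm", "y_mm", "z_mm")])
    # rows: start ... end; rebuild child->parent chain from the end upward
    m <- nrow(res)
    prev <- end
    if (m > 2) {
      for (j in seq(m - 1, 2)) {
        nid <- sprintf("%s..%d", start, j - 1)
        add_node(nid, res[j, ], prev)
        prev <- nid
      }
    }
    add_node(start, res[1, ], prev)
  }
  vessel_tree(tibble::tibble(
    id = out_id, x_mm = as.numeric(out_xyz[, 1]),
    y_mm = as.numeric(out_xyz[, 2]), z_mm = as.numeric(out_xyz[, 3]),
    parent_id = out_parent))
}

#' Bounding-box centroid of a vessel tree
#'
#' The default rotation center of the pose search: rotating about a
#' tree-local center decouples rotation from translation.
#'
#' @param tree A [vessel_tree()].
#' @return Length-3 numeric (mm).
#' @export
tree_bbox_center <- function(tree) {
  xyz <- as.matrix(tree$nodes[, c("x_mm", "y_mm", "z_mm")])
  as.numeric((apply(xyz, 2, min) + apply(xyz, 2, max)) / 2)
}
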