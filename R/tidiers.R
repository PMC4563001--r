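#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-candidate table of a registration
#'
#' One row per evaluated candidate leaf path: shape-similarity rank and
#' score, optimized metric, and the estimated pose parameters.
#'
#' @param x A `catheter_registration` from [register_catheter()].
#' @param ... Unused.
#' @return A tibble with columns `leaf_id`, `rank`, `s_max`, `argmax_node`,
#'   `metric_mm`, `alpha`, `beta`, `gamma`, `x`, `y`, `selected`.
#' @export
tidy.catheter_registration <- function(x, ...) {
  out <- x$candidates[, c("leaf_id", "rank", "s_max", "argmax_node",
                          "metric_mm", "alpha", "beta", "gamma", "x", "y")]
  out$selected <- out$leaf_id == x$best_leaf_id
  out
}

#' One-row summary of a registration
#'
#' @inheritParams tidy.catheter_registration
#' @return A one-row tibble: winning leaf, metric, pose parameters,
#'   optimizer, candidate count and convergence flag.
#' @export
glance.catheter_registration <- function(x, ...) {
  obj <- x
  tibble::tibble(best_leaf_id = obj$best_leaf_id,
                 metric_mm = obj$metric_mm,
                 alpha = obj$pose$alpha, beta = obj$pose$beta,
                 gamma = obj$pose$gamma, x = obj$pose$x, y = obj$pose$y,
                 optimizer = obj$optimizer,
                 n_candidates = nrow(obj$candidates),
                 converged = isTRUE(obj$converged))
}
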