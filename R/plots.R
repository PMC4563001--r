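#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Overlay plot of a registration result
#'
#' Draws the catheter (black), the winning projected vessel path under the
#' estimated pose (solid color), and the remaining candidates under their
#' own optimized poses (dashed grey). Axes are fluoroscopic image mm; the
#' y axis is reversed to match image convention.
#'
#' @param object A `catheter_registration` from [register_catheter()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.catheter_registration <- function(object, ...) {
  cath <- tibble::as_tibble(as.data.frame(as_points2(object$catheter)))
  names(cath) <- c("x_mm", "y_mm")
  layers <- purrr::map_dfr(seq_len(nrow(object$candidates)), function(i) {
    pose <- pose_5dof(object$candidates$alpha[i], object$candidates$beta[i],
                      object$candidates$gamma[i], object$candidates$x[i],
                      object$candidates$y[i],
                      rotation_center = object$pose$rotation_center)
    path <- path_to_root(object$tree, object$candidates$argmax_node[i])
    proj <- project_path(path, pose, object$geometry)
    proj$leaf_id <- object$candidates$leaf_id[i]
    proj$selected <- object$candidates$leaf_id[i] == object$best_leaf_id
    proj
  })
  ggplot2::ggplot() +
    ggplot2::geom_path(data = layers[!layers$selected, ],
                       ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                                    group = .data$leaf_id),
                       color = "grey60", linetype = "dashed") +
    ggplot2::geom_path(data = layers[layers$selected, ],
                       ggplot2::aes(x = .data$x_mm, y = .data$y_mm),
                       color = "#D55E00", linewidth = 1) +
    ggplot2::geom_path(data = cath, ggplot2::aes(x = .data$x_mm, y = .data$y_mm),
                       color = "black", linewidth = 0.8) +
    ggplot2::geom_point(data = cath[1, ], ggplot2::aes(x = .data$x_mm, y = .data$y_mm),
                        shape = 21, fill = "white", size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm, image)", y = "y (mm, image)",
                  title = sprintf("Registered leaf '%s' (M = %.2f mm, %s)",
                                  object$best_leaf_id, object$metric_mm,
                                  object$optimizer)) +
    ggplot2::theme_minimal()
}

#' Tip-error boxplots of a simulation experiment
#'
#' Boxplots of the Euclidean, longitudinal and orthogonal projected tip
#' errors, grouped by perturbation set and faceted by optimizer.
#'
#' @param object A `roadmap_experiment` tibble from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roadmap_experiment <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[is.na(df$error), ]
  long <- tidyr_pivot_errors(df)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$set_name, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~optimizer) +
    ggplot2::labs(x = "perturbation set", y = "tip error (mm)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

# Minimal long-format reshape of the three error columns (avoids a tidyr
# dependency for one call).
tidyr_pivot_errors <- function(df) {
  purrr::map_dfr(c(e_d = "e_d_mm", l_d = "l_d_mm", o_d = "o_d_mm"),
                 function(col) {
                   tibble::tibble(set_name = df$set_name,
                                  optimizer = df$optimizer,
                                  value = df[[col]])
                 }, .id = "metric")
}

#' Plot the tip-centered metric weight
#'
#' @param lambda,sigma Weight parameters (see [tip_weight()]).
#' @param max_arc_mm Upper end of the plotted arc range.
#' @return A ggplot object.
#' @export
plot_tip_weight <- function(lambda = 0.2, sigma = 20, max_arc_mm = 150) {
  x <- seq(0, max_arc_mm, length.out = 301)
  df <- tibble::tibble(x = x, w = tip_weight(x, lambda, sigma))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$w)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "arc length from tip (mm)", y = "weight W(x)") +
    ggplot2::theme_minimal()
}
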