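#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_ribbon
#'   geom_raster labs theme_minimal scale_fill_viridis_c coord_equal
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @export
tidy.evaluation_report <- function(x, ...) x$rows

#' @export
glance.evaluation_report <- function(x, ...) x$summary

#' @export
tidy.convergence_curve <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
tidy.wilcoxon_signed_rank <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, n = x$n, p_value = x$p_value,
                 method = x$method, degenerate = x$degenerate)
}

#' Precision-vs-accuracy plot of an evaluation report
#'
#' Reproduces the standard template-comparison view: mean metric on the x
#' axis against the inverse standard error of the mean on the y axis, one
#' point per template — templates that are both accurate (right) and precise
#' (top) dominate.
#'
#' @param object an `evaluation_report` (possibly built from several atlases
#'   by row-binding summaries).
#' @param metric which metric to display (`"dice"`, `"msd_um"`,
#'   `"hausdorff_um"`).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_report <- function(object, metric = "dice", ...) {
  s <- object$summary
  mcol <- paste0(metric, "_mean")
  scol <- paste0(metric, "_sem")
  if (!mcol %in% names(s)) {
    af_stop(sprintf("metric '%s' not present in this report", metric), "argument")
  }
  ggplot(s, aes(x = .data[[mcol]], y = 1 / .data[[scol]],
                label = .data$template)) +
    geom_point(size = 2) +
    ggplot2::geom_text(aes(label = .data$template), vjust = -0.8, size = 3) +
    labs(x = sprintf("mean %s", metric), y = "1 / s.e.m.",
         title = sprintf("%s task", object$task)) +
    theme_minimal()
}

#' Convergence curve plot
#'
#' Mean Dice against atlas size, one line per task, with a +/- s.e.m. ribbon.
#'
#' @param object a `convergence_curve`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.convergence_curve <- function(object, ...) {
  d <- tibble::as_tibble(unclass(object))
  ggplot(d, aes(x = .data$n, y = .data$mean_dice, colour = .data$task,
                fill = .data$task)) +
    geom_ribbon(aes(ymin = .data$mean_dice - .data$sem,
                    ymax = .data$mean_dice + .data$sem),
                alpha = 0.2, colour = NA) +
    geom_line() + geom_point() +
    labs(x = "number of brains in atlas", y = "mean Dice coefficient") +
    theme_minimal()
}

#' Plot one axial slice of an image
#'
#' @param img a `scalar_image` or `label_image`.
#' @param z 1-based slice index (default: middle slice).
#' @return A ggplot raster of the slice in world coordinates.
#' @export
plot_slice <- function(img, z = NULL) {
  d <- img_dims(img)
  if (is.null(z)) z <- ceiling(d[3] / 2)
  sl <- img$values[, , z]
  df <- tidyr::expand_grid(
    j = seq_len(d[2]), i = seq_len(d[1])) |>
    mutate(x = img$origin[1] + (.data$i - 1) * img$spacing[1],
           y = img$origin[2] + (.data$j - 1) * img$spacing[2],
           value = as.vector(sl[cbind(.data$i, .data$j)]))
  ggplot(df, aes(.data$x, .data$y, fill = .data$value)) +
    geom_raster() + coord_equal() + scale_fill_viridis_c() +
    labs(x = "x (um)", y = "y (um)",
         fill = if (inherits(img, "label_image")) "label" else "intensity") +
    theme_minimal()
}
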