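# broom-style accessors and plots for fitted adjustments.

#' @export
print.fluoro_calib <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<self-calibrating bundle adjustment%s>\n",
              if (x$fix_iop) " (interior model fixed)" else ""))
  cat(sprintf("  %d observations, %d images, %d points; redundancy %d\n",
              nrow(x$residuals), nrow(x$network$images),
              nrow(x$network$points), x$dof))
  cat(sprintf("  %s in %d iteration(s)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  cat(sprintf("  variance factor %.4f; image RMS (x, y) = (%.4f, %.4f) px\n",
              g$variance_factor, g$rms_x, g$rms_y))
  if (length(x$active_terms))
    cat("  distortion terms:", paste(x$active_terms, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy the estimated parameters of an adjustment
#'
#' @param x A `fluoro_calib`.
#' @param block `"iop"` (default) for the interior block, `"eop"`, `"points"`
#'   or `"all"`.
#' @param ... Unused.
#' @return Tibble with `parameter`, `class`, `estimate`, `std.error` and
#'   `statistic` (estimate / std.error).
#' @export
tidy.fluoro_calib <- function(x, block = c("iop", "eop", "points", "all"),
                              ...) {
  block <- match.arg(block)
  pt <- x$param_table
  keep <- switch(block,
    all = rep(TRUE, nrow(pt)),
    iop = pt$class %in% c("px", "coef"),
    eop = grepl("^(Xc|Yc|Zc|omega|phi|kappa)\\[", pt$parameter),
    points = grepl("^[XYZ]\\[", pt$parameter))
  out <- pt[keep, ]
  tibble::tibble(parameter = out$parameter, class = out$class,
                 estimate = out$estimate, std.error = out$sigma,
                 statistic = ifelse(out$sigma > 0,
                                    abs(out$estimate) / out$sigma, NA_real_))
}

#' One-row summary of an adjustment
#'
#' @param x A `fluoro_calib`.
#' @param ... Unused.
#' @return Tibble with the variance factor, redundancy, per-axis image
#'   residual RMS, iteration count, convergence flag and term count.
#' @export
glance.fluoro_calib <- function(x, ...) {
  r <- image_rms(x$residuals)
  tibble::tibble(variance_factor = x$variance_factor, dof = x$dof,
                 rms_x = r[["rms_x"]], rms_y = r[["rms_y"]],
                 n_iterations = x$n_iterations, converged = x$converged,
                 n_terms = length(x$active_terms))
}

#' Observations augmented with fitted values and residuals
#'
#' @param x A `fluoro_calib`.
#' @param ... Unused.
#' @return The observation tibble with `.fitted_x`, `.fitted_y`, `.resid_x`,
#'   `.resid_y` columns appended.
#' @export
augment.fluoro_calib <- function(x, ...) {
  obs <- x$network$observations
  dplyr::mutate(obs,
                .resid_x = x$residuals$vx,
                .resid_y = x$residuals$vy,
                .fitted_x = .data$x - x$residuals$vx,
                .fitted_y = .data$y - x$residuals$vy)
}

#' Residual quiver plot of a fitted adjustment
#'
#' Arrows from the fitted to the observed image positions, exaggerated for
#' visibility; the classic diagnostic for leftover systematic distortion.
#'
#' @param object A `fluoro_calib`.
#' @param exaggerate Arrow length multiplier.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fluoro_calib <- function(object, exaggerate = 50, ...) {
  a <- augment(object)
  ggplot2::ggplot(a, ggplot2::aes(x = .data$.fitted_x, y = .data$.fitted_y)) +
    ggplot2::geom_segment(ggplot2::aes(
      xend = .data$.fitted_x + exaggerate * .data$.resid_x,
      yend = .data$.fitted_y + exaggerate * .data$.resid_y),
      linewidth = 0.2,
      arrow = ggplot2::arrow(length = ggplot2::unit(1, "mm"))) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = sprintf("Image residuals (x%g)", exaggerate)) +
    ggplot2::theme_minimal()
}

#' Magnitude map of a distortion field
#'
#' @param object A `distortion_field`.
#' @param ... Unused.
#' @return A ggplot of per-pixel shift magnitude (px).
#' @export
autoplot.distortion_field <- function(object, ...) {
  dims <- dim(object$dx)
  g <- expand.grid(row0 = 0:(dims[1] - 1), col0 = 0:(dims[2] - 1))
  cc <- raster_to_centered(g$row0, g$col0, dims)
  df <- tibble::tibble(x = cc$x, y = cc$y,
                       magnitude = sqrt(as.vector(object$dx)^2 +
                                          as.vector(object$dy)^2))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$magnitude)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = "shift (px)") +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
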