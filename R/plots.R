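#' Plot a survivor curve
#'
#' Step plot of the empirical survivor function, optionally on a log10
#' abscissa (the usual choice for traits spanning orders of magnitude).
#'
#' @param x a `"deb_survivor"` object.
#' @param log_x logical; log10 abscissa (default `TRUE`).
#' @param add logical; add to an existing plot.
#' @param ... further arguments passed to [graphics::plot()] /
#'   [graphics::lines()].
#' @return `x`, invisibly.
#' @export
plot.deb_survivor <- function(x, log_x = TRUE, add = FALSE, ...) {
  v <- x$values
  S <- x$S(v)
  xs <- c(v[1], v)
  ys <- c(1, S)
  if (add) graphics::lines(xs, ys, type = "s", ...)
  else graphics::plot(xs, ys, type = "s", log = if (log_x) "x" else "",
                      xlab = "trait value", ylab = "fraction exceeding",
                      ylim = c(0, 1), ...)
  invisible(x)
}

#' Plot an MDS embedding
#'
#' Scatter of the first two axes of a [classical_mds()] embedding, colored
#' by a grouping factor (typically taxon).
#'
#' @param x a `"deb_mds"` object.
#' @param groups optional factor/character vector aligned with the embedded
#'   species (e.g. `table$taxon`).
#' @param axes which two axes to show.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.deb_mds <- function(x, groups = NULL, axes = c(1, 2), ...) {
  pts <- x$points[, axes, drop = FALSE]
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  graphics::plot(pts, col = col, pch = 16,
                 xlab = colnames(pts)[1], ylab = colnames(pts)[2], ...)
  if (!is.null(groups))
    graphics::legend("topright", legend = levels(factor(groups)),
                     col = seq_along(levels(factor(groups))), pch = 16,
                     bty = "n")
  invisible(x)
}

#' Add an un-fitted reference line of fixed slope to a log-log plot
#'
#' Draws a line of given slope through the geometric-median point of the
#' cloud on an existing log10-log10 plot. Reference slopes (such as -1/4,
#' -1 or +1) are conventions for visual comparison, never fitted and never
#' reported as estimates.
#'
#' @param x,y positive data defining the anchor point.
#' @param slope fixed slope on the log10 scale.
#' @param ... further arguments passed to [graphics::abline()].
#' @return Invisibly, the `c(intercept, slope)` used (log10 scale).
#' @export
reference_line <- function(x, y, slope, ...) {
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  x0 <- stats::median(log10(x[ok]))
  y0 <- stats::median(log10(y[ok]))
  intercept <- y0 - slope * x0
  graphics::abline(intercept, slope, ...)
  invisible(c(intercept = intercept, slope = slope))
}
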