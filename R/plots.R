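# Base-graphics displays mirroring the original environment's figures:
# density band with the real-data density overlaid, chi-squared QQ display of
# the quadratic forms, Kaplan-Meier step curves with censoring ticks, and a
# correlation heatmap. All draw to the active device (PNG/SVG via the usual
# device functions).

#' @export
plot.density_band_result <- function(x, ...) {
  ylim <- range(0, x$band_upper, x$density_real)
  graphics::plot(x$grid, x$density_real, type = "n", ylim = ylim,
                 xlab = "value", ylab = "density",
                 main = sprintf("Bootstrap %d%% density band (B = %d)",
                                round(100 * x$level), x$B), ...)
  graphics::polygon(c(x$grid, rev(x$grid)),
                    c(x$band_lower, rev(x$band_upper)),
                    col = "grey85", border = NA)
  graphics::lines(x$grid, x$density_virtual, col = "steelblue", lwd = 1.5)
  graphics::lines(x$grid, x$density_real, col = "firebrick", lwd = 2)
  graphics::legend("topright", bty = "n",
                   legend = c("real", "virtual", "bootstrap band"),
                   col = c("firebrick", "steelblue", "grey85"),
                   lwd = c(2, 1.5, 8))
  invisible(x)
}

#' @export
plot.quadratic_form_result <- function(x, ...) {
  graphics::plot(x$qq_pairs[, "real"], x$qq_pairs[, "virtual"],
                 xlab = "real quadratic-form quantiles",
                 ylab = "virtual quadratic-form quantiles",
                 main = sprintf("QQ comparison (p = %d, df = %d)", x$p, x$df),
                 ...)
  graphics::abline(0, 1, col = "grey50", lty = 2)
  invisible(x)
}

#' @export
plot.km_estimate <- function(x, xlab = "time", col = "black", add = FALSE, ...) {
  tmax <- max(c(x$event_times, x$censoring_times, 0))
  sx <- c(0, rep(x$event_times, each = 2), tmax)
  sy <- c(1, 1, rep(x$survival, each = 2))[seq_along(sx)]
  if (!add)
    graphics::plot(sx, sy, type = "l", ylim = c(0, 1), xlab = xlab,
                   ylab = "survival probability", col = col,
                   main = "Kaplan-Meier estimate", ...)
  else graphics::lines(sx, sy, col = col, ...)
  if (length(x$censoring_times))
    graphics::points(x$censoring_times,
                     km_survival_at(x, x$censoring_times),
                     pch = 3, col = col)
  invisible(x)
}

#' Correlation heatmap of a Spearman comparison
#'
#' Draws the real, virtual, or difference matrix of a
#' [spearman_matrices()] result as an image with a diverging palette.
#'
#' @param x A `correlation_result`.
#' @param which `"real"`, `"virtual"` or `"difference"`.
#' @param ... Passed to [graphics::image()].
#' @export
plot_correlation_heatmap <- function(x, which = c("real", "virtual",
                                                  "difference"), ...) {
  which <- match.arg(which)
  m <- switch(which, real = x$real_matrix, virtual = x$virtual_matrix,
              difference = x$difference_matrix)
  p <- ncol(m)
  pal <- grDevices::hcl.colors(41, "Blue-Red 3")
  graphics::image(seq_len(p), seq_len(p), t(m[p:1, , drop = FALSE]),
                  zlim = c(-1, 1), col = pal, axes = FALSE,
                  xlab = "", ylab = "",
                  main = sprintf("Spearman correlations (%s)", which), ...)
  graphics::axis(1, at = seq_len(p), labels = colnames(m), las = 2)
  graphics::axis(2, at = seq_len(p), labels = rev(rownames(m)), las = 2)
  invisible(x)
}
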