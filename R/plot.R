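#' Plot a hybrid trajectory
#'
#' Draws the three molecule levels against physical time, with the binary
#' gene state as a step function underneath (scaled to the level axis).
#'
#' @param x an `ifs_trajectory`.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.ifs_trajectory <- function(x, ...) {
  old <- graphics::par(mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  ylim <- range(x$xi1, x$xi2, x$xi3, 0)
  graphics::matplot(x$t, cbind(x$xi1, x$xi2, x$xi3), type = "l", lty = 1,
                    col = c("#1b9e77", "#d95f02", "#7570b3"),
                    xlab = "time", ylab = "level", ylim = ylim, ...)
  graphics::lines(x$t, x$i * 0.05 * diff(ylim) + ylim[1], type = "s",
                  col = "grey40")
  graphics::legend("topright",
                   legend = c("pre-mRNA", "mRNA", "protein", "gene state"),
                   col = c("#1b9e77", "#d95f02", "#7570b3", "grey40"),
                   lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

#' Plot a point cloud as coordinate-plane projections
#'
#' @param x a [point_cloud()].
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.point_cloud <- function(x, ...) {
  m <- .cloud_matrix(x)
  old <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  pairs_idx <- list(c(1, 2), c(1, 3), c(2, 3))
  labs <- colnames(m)
  for (p in pairs_idx)
    graphics::plot(m[, p[1]], m[, p[2]], pch = ".", cex = 0.6,
                   xlab = labs[p[1]], ylab = labs[p[2]], ...)
  invisible(x)
}
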