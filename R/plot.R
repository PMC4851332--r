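#' Plot a calibrated density
#'
#' @param x a `cal_density`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cal_density <- function(x, ...) {
  graphics::plot(x$calbp, x$prob, type = "h", xlim = rev(range(x$calbp)),
                 xlab = "cal BP", ylab = "probability", col = "grey40", ...)
  invisible(x)
}

#' Plot an SPD, optionally with its rolling mean
#'
#' @param x an `spd`.
#' @param smooth rolling-mean window in years drawn as a thick line
#'   (`NULL` to omit).
#' @param ... passed to [graphics::plot()].
#' @export
plot.spd <- function(x, smooth = 200, ...) {
  graphics::plot(x$grid, x$density, type = "l", col = "grey50",
                 xlim = rev(range(x$grid)), xlab = "cal BP",
                 ylab = "summed probability", ...)
  if (!is.null(smooth))
    graphics::lines(x$grid, rolling_mean(x, smooth)$density, lwd = 2)
  invisible(x)
}

# shade significant intervals and draw the envelope band for one set
draw_envelope <- function(grid, obs_z, lo, hi, pos, neg, main) {
  graphics::plot(grid, obs_z, type = "n", xlim = rev(range(grid)),
                 ylim = range(c(obs_z, lo, hi), finite = TRUE),
                 xlab = "cal BP", ylab = "local z-score", main = main)
  shade <- function(iv, col) {
    if (nrow(iv))
      graphics::rect(iv$start, graphics::par("usr")[3L], iv$end,
                     graphics::par("usr")[4L], col = col, border = NA)
  }
  shade(pos, grDevices::adjustcolor("firebrick", 0.25))
  shade(neg, grDevices::adjustcolor("steelblue", 0.25))
  graphics::polygon(c(grid, rev(grid)), c(lo, rev(hi)),
                    col = "grey85", border = NA)
  graphics::lines(grid, obs_z, lwd = 1.5)
}

#' Plot a Monte-Carlo null-model test result
#'
#' Observed z-scored SPD over the simulated 95% envelope, with significant
#' positive (red) and negative (blue) intervals shaded.
#'
#' @param x an `envelope_result` from [model_test()].
#' @param ... unused.
#' @export
plot.envelope_result <- function(x, ...) {
  draw_envelope(x$grid, x$obs_z, x$lo, x$hi, x$pos_intervals,
                x$neg_intervals,
                sprintf("%s null (p = %.4g)", x$kind, x$pvalue))
  invisible(x)
}

#' Plot a permutation test result
#'
#' One panel per set: observed z-scored SPD against the permutation 95%
#' envelope.
#'
#' @param x a `perm_test_result` from [perm_test()].
#' @param ... unused.
#' @export
plot.perm_test_result <- function(x, ...) {
  k <- length(x$sets)
  old <- graphics::par(mfrow = c(1, k))
  on.exit(graphics::par(old))
  for (nm in names(x$sets)) {
    s <- x$sets[[nm]]
    draw_envelope(x$grid, s$obs_z, s$lo, s$hi, s$pos_intervals,
                  s$neg_intervals, sprintf("%s (p = %.4g)", nm, s$pvalue))
  }
  invisible(x)
}
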