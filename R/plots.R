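#' ENc-plot: observed ENc against GC3s with the expected curve
#'
#' @param enc_points data.frame from [enc_plot_points()] (or a
#'   `cp_analysis`, whose `enc_plot` component is used).
#' @param ... passed to [graphics::plot()].
#' @return the input, invisibly.
#' @export
plot_enc <- function(enc_points, ...) {
  if (inherits(enc_points, "cp_analysis")) enc_points <- enc_points$enc_plot
  graphics::plot(enc_points$gc3s, enc_points$enc, xlim = c(0, 1),
                 ylim = c(20, 62), xlab = "GC3s", ylab = "ENc", pch = 19,
                 col = grDevices::adjustcolor("darkorange3", 0.7), ...)
  s <- seq(0.001, 0.999, length.out = 200)
  graphics::lines(s, enc_expected(s), col = "grey30", lwd = 2)
  invisible(enc_points)
}

#' PR2-bias plot
#'
#' @param pr2 data.frame from [pr2_points()] (or a `cp_analysis`).
#' @param ... passed to [graphics::plot()].
#' @return the input, invisibly.
#' @export
plot_pr2 <- function(pr2, ...) {
  if (inherits(pr2, "cp_analysis")) pr2 <- pr2$pr2
  ok <- pr2$defined
  graphics::plot(pr2$x[ok], pr2$y[ok], xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "G3/(G3+C3)", ylab = "A3/(A3+T3)", pch = 19,
                 col = grDevices::adjustcolor("seagreen4", 0.7), ...)
  graphics::abline(h = 0.5, v = 0.5, lty = 2, col = "grey50")
  invisible(pr2)
}
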