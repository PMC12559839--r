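#' Plot a time-frequency map
#'
#' Base-graphics image of a (possibly thresholded) dB map with a
#' log-frequency axis and a vertical line at speech onset (t = 0).
#'
#' @param x a `tf_map` or `thresholded_tf_map`.
#' @param zlim color limits, dB; default symmetric about 0.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @export
plot_tf_map <- function(x, zlim = NULL, main = NULL, ...) {
  if (inherits(x, "thresholded_tf_map")) {
    power <- x$masked_power
    map <- x$map
    if (is.null(main)) main <- sprintf("thresholded (p < %g)", x$alpha)
  } else {
    stopifnot(inherits(x, "tf_map"))
    power <- x$power
    map <- x
    if (is.null(main) && !is.na(x$condition)) main <- x$condition
  }
  if (is.null(zlim)) {
    r <- max(abs(power), 1e-6)
    zlim <- c(-r, r)
  }
  pal <- grDevices::hcl.colors(65, "RdBu", rev = TRUE)
  graphics::image(map$time_ms, log2(map$freqs), t(power), zlim = zlim,
                  col = pal, xlab = "time (ms)", ylab = "frequency (Hz)",
                  yaxt = "n", main = main %||% "", ...)
  at <- c(1, 2, 4, 8, 16, 32, 50)
  at <- at[at >= min(map$freqs) & at <= max(map$freqs)]
  graphics::axis(2, at = log2(at), labels = at)
  graphics::abline(v = 0, lwd = 2)
  invisible(x)
}
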