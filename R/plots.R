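#' Write a kymograph PNG
#'
#' Renders a position-by-time intensity map of one channel to a PNG file.
#' Plot output is optional everywhere in the pipeline; analysis results
#' never depend on it.
#'
#' @param movie A [cell_movie()].
#' @param channel Channel name.
#' @param path Output PNG path.
#' @param width,height Device size in pixels.
#' @return `path`, invisibly.
#' @export
kymograph_png <- function(movie, channel, path, width = 480, height = 360) {
  ky <- kymograph(movie, channel)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::image(x = attr(ky, "times"), y = attr(ky, "positions"),
                  z = t(ky), xlab = "time (min)",
                  ylab = "position (um)",
                  main = paste(channel, "kymograph"),
                  col = grDevices::gray.colors(256, start = 0, end = 1))
  invisible(path)
}
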