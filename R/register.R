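#' Estimate the subpixel shift aligning one image to a reference
#'
#' Integer-pixel cross-correlation search over `±max_shift` followed by a
#' continuous refinement that maximizes the Pearson correlation of the
#' Fourier-shifted image with the reference. Returns the shift `c(dx, dy)`
#' (pixels) that, applied to `img` via [shift_image()], best aligns it to
#' `ref`.
#'
#' @param ref,img Numeric matrices of identical shape.
#' @param max_shift Search bound in pixels; inter-plane instrumental shifts
#'   are subpixel, so the default is deliberately tight.
#' @return Numeric `c(dx, dy)`; attribute `correlation` holds the achieved
#'   correlation. `NULL` (with a warning) for a featureless image.
#' @export
estimate_shift <- function(ref, img, max_shift = 3) {
  if (stats::sd(img) == 0 || stats::sd(ref) == 0) {
    warning("featureless channel: registration skipped", call. = FALSE)
    return(NULL)
  }
  score <- function(s) stats::cor(as.vector(ref),
                                  as.vector(shift_image(img, s[1], s[2])))
  grid <- expand.grid(dx = -max_shift:max_shift, dy = -max_shift:max_shift)
  ints <- apply(grid, 1, score)
  best <- as.numeric(grid[which.max(ints), ])
  opt <- stats::optim(best, function(s) -score(s), method = "L-BFGS-B",
                      lower = best - 1, upper = best + 1,
                      control = list(factr = 1e4))
  structure(opt$par, correlation = -opt$value, names = c("dx", "dy"))
}

#' Register all channels of a movie to a reference channel
#'
#' Estimates one constant offset per channel from the time-averaged frames
#' (inter-plane shifts are instrumental, not dynamic) and applies it to
#' every frame. The phase channel is intensity-inverted before correlation:
#' phase contrast is anti-correlated with fluorescence (bright background,
#' dark cell), so correlating it directly would drive the alignment away
#' from the cell.
#'
#' @param movie A [cell_movie()] with at least two channels.
#' @param reference_channel Channel name used as the fixed reference.
#' @param max_shift Search bound in pixels.
#' @return The movie with channels aligned; applied offsets are recorded in
#'   `meta$registration` (reference offset is exactly c(0, 0)).
#' @export
register_channels <- function(movie, reference_channel = "dapi",
                              max_shift = 3) {
  chans <- names(movie$channels)
  if (length(chans) < 2) stop_user("registration needs at least 2 channels")
  if (!reference_channel %in% chans) {
    stop_user("reference channel '", reference_channel, "' not present")
  }
  mean_frame <- function(ch) {
    a <- movie$channels[[ch]]
    img <- apply(a, c(1, 2), mean)
    if (ch == "phase") max(img) - img else img
  }
  ref <- mean_frame(reference_channel)
  offsets <- list()
  offsets[[reference_channel]] <- c(dx = 0, dy = 0)
  for (ch in setdiff(chans, reference_channel)) {
    s <- estimate_shift(ref, mean_frame(ch), max_shift = max_shift)
    if (is.null(s)) {
      offsets[[ch]] <- c(dx = 0, dy = 0)
      next
    }
    offsets[[ch]] <- s
    if (max(abs(s)) > 1e-3) {
      a <- movie$channels[[ch]]
      for (t in seq_len(dim(a)[3])) {
        a[, , t] <- shift_image(a[, , t], s[1], s[2])
      }
      movie$channels[[ch]] <- a
    }
  }
  movie$meta$registration <- lapply(offsets, function(s) {
    s <- as.numeric(s)
    names(s) <- c("dx", "dy")
    s
  })
  movie
}
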