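#' Position of the septal ring along the long axis
#'
#' The dominant peak of the background-subtracted longitudinal ring-label
#' profile, refined to subpixel. When two bands are present the brighter
#' one wins.
#'
#' @param gfp_long_profile Background-subtracted [line_profile()] of the
#'   ring channel along the long axis.
#' @param min_peak Absolute intensity a peak must exceed; profiles whose
#'   interior maximum is at or below this return the absent sentinel.
#' @return Position in um, or `NA_real_` when no ring is present.
#' @export
ring_position <- function(gfp_long_profile, min_peak = 0) {
  me <- gfp_long_profile$mask_extent
  inside <- which(gfp_long_profile$positions >= me[1] &
                    gfp_long_profile$positions <= me[2])
  if (length(inside) < 3) return(NA_real_)
  vals <- gfp_long_profile$values[inside]
  i <- which.max(vals)
  if (vals[i] <= min_peak) return(NA_real_)
  gfp_long_profile$positions[inside][i] +
    parabolic_refine(vals, i) * gfp_long_profile$pixel_size
}

#' Ring width along the short axis, by two estimators
#'
#' `width_gauss` is twice the fitted standard deviation of a least-squares
#' Gaussian-plus-offset fit; `width_moment` is twice the square root of the
#' second central moment of the background-subtracted non-negative profile
#' treated as a density. On an exact Gaussian both agree (2 sigma); on a
#' top-hat of full width `w` the moment estimator gives `w / sqrt(3)`.
#'
#' @param gfp_short_profile Background-subtracted [line_profile()] across
#'   the cell short axis at the ring position.
#' @return List with `width_gauss`, `width_moment` (um) and
#'   `gauss_converged`; `width_gauss` is `NA` with a flag when the fit does
#'   not converge.
#' @export
ring_width <- function(gfp_short_profile) {
  x <- gfp_short_profile$positions
  p <- pmax(gfp_short_profile$values, 0)
  if (sum(p) <= 0) {
    return(list(width_gauss = NA_real_, width_moment = NA_real_,
                gauss_converged = FALSE))
  }
  mu <- sum(p * x) / sum(p)
  m2 <- sum(p * (x - mu)^2) / sum(p)
  width_moment <- 2 * sqrt(m2)

  fit <- tryCatch({
    df <- data.frame(x = x, v = gfp_short_profile$values)
    stats::nls(v ~ a * exp(-(x - m)^2 / (2 * s^2)) + c0, data = df,
        start = list(a = max(p), m = mu, s = max(sqrt(m2), 1e-3), c0 = 0),
        # scaleOffset keeps nls well-posed on (near-)zero-residual data
        control = stats::nls.control(maxiter = 100, warnOnly = FALSE,
                                     scaleOffset = 1))
  }, error = function(e) NULL)
  if (is.null(fit)) {
    list(width_gauss = NA_real_, width_moment = width_moment,
         gauss_converged = FALSE)
  } else {
    list(width_gauss = 2 * abs(stats::coef(fit)[["s"]]),
         width_moment = width_moment, gauss_converged = TRUE)
  }
}

# Perpendicular profile through the point at axial position x, long enough
# to cross the full cell width plus background margins on both sides.
short_axis_profile <- function(movie, channel, axis, x, frame,
                               half_um = NULL, width_px = 3) {
  v <- axis$direction
  u <- c(-v[2], v[1])
  if (is.null(half_um)) {
    # half the raster height is a safe default for a centered cell
    half_um <- nrow(movie$cell_mask) * movie$pixel_size / 2 -
      2 * movie$pixel_size
  }
  p <- axis$p0 + x * v
  # approximate local half-width of the mask for the extent interval
  hw <- mask_half_width(movie$cell_mask, movie$pixel_size, p, u, half_um)
  perp <- structure(list(
    p0 = p - half_um * u, p1 = p + half_um * u, direction = u,
    mask_extent = c(half_um - hw, half_um + hw)
  ), class = "cell_axis")
  line_profile(movie$channels[[channel]][, , frame], perp,
               movie$pixel_size, width_px)
}

mask_half_width <- function(mask, pixel_size, p, u, half_um) {
  s <- seq(-half_um, half_um, by = pixel_size)
  inside <- bilinear_sample(mask * 1, (p[1] + s * u[1]) / pixel_size + 0.5,
                            (p[2] + s * u[2]) / pixel_size + 0.5) > 0.5
  if (!any(inside)) return(pixel_size)
  max(abs(s[inside])) + pixel_size / 2
}

#' Track the septal ring through a movie
#'
#' Per frame: ring position and peak intensity from the background-
#' subtracted longitudinal profile, then both width estimators from the
#' short-axis profile at that position. The `present` flag compares the
#' peak intensity with a fraction of its early-movie baseline, is smoothed
#' by a 3-frame majority filter, and is forced to be a prefix (once the
#' ring is gone it stays gone).
#'
#' @param movie A [cell_movie()].
#' @param channel Ring channel name.
#' @param axis Optional oriented axis.
#' @param baseline_frames Frames defining the pre-dissociation baseline.
#' @param dissoc_threshold Presence threshold as a fraction of baseline.
#' @param width_px Longitudinal profile averaging width.
#' @return Data frame of class `zring_trace` with columns `frame`,
#'   `time_min`, `position_um`, `peak_intensity`, `width_gauss_um`,
#'   `width_moment_um`, `present`; attribute `t_dissoc`.
#' @export
ring_trace <- function(movie, channel = "zipa", axis = NULL,
                       baseline_frames = 5, dissoc_threshold = 0.2,
                       width_px = 9) {
  if (!channel %in% names(movie$channels)) {
    stop_user("ring channel '", channel, "' not present")
  }
  if (is.null(axis)) axis <- long_axis(movie$cell_mask, movie$pixel_size)
  nt <- movie$n_frames
  arr <- movie$channels[[channel]]
  pos <- peak <- wg <- wm <- rep(NA_real_, nt)
  for (t in seq_len(nt)) {
    pr <- subtract_background(
      line_profile(arr[, , t], axis, movie$pixel_size, width_px))
    me <- pr$mask_extent
    inside <- pr$positions >= me[1] & pr$positions <= me[2]
    peak[t] <- max(pr$values[inside])
    pos[t] <- ring_position(pr)
    if (is.finite(pos[t])) {
      sp <- subtract_background(
        short_axis_profile(movie, channel, axis, pos[t], t))
      w <- ring_width(sp)
      wg[t] <- w$width_gauss
      wm[t] <- w$width_moment
    }
  }
  baseline <- stats::median(peak[seq_len(min(baseline_frames, nt))])
  present <- peak > dissoc_threshold * baseline
  if (nt >= 3) present <- stats::runmed(present * 1L, 3) > 0.5
  gone <- which(!present)
  if (length(gone)) present[gone[1]:nt] <- FALSE

  trace <- structure(data.frame(
    frame = seq_len(nt),
    time_min = movie$times,
    position_um = pos,
    peak_intensity = peak,
    width_gauss_um = ifelse(present, wg, NA_real_),
    width_moment_um = ifelse(present, wm, NA_real_),
    present = present
  ), class = c("zring_trace", "data.frame"),
  baseline_peak = baseline, baseline_frames = baseline_frames)
  attr(trace, "t_dissoc") <- dissociation_time(trace, dissoc_threshold,
                                               baseline_frames)
  trace
}

#' Ring dissociation time
#'
#' The first time the peak ring intensity falls to or below
#' `threshold * baseline` (baseline = median peak over the early frames)
#' and stays below for the rest of the movie. The returned time is the
#' midpoint between the last frame above and the first frame below, since
#' dissociation occurred somewhere in that interval; it defines t = 0 for
#' all relative timing.
#'
#' @param trace A [ring_trace()] data frame.
#' @param threshold Fraction of the pre-dissociation baseline.
#' @param baseline_frames Frames defining the baseline.
#' @return Time in min, or `NA_real_` if the ring never dissociates (or
#'   was never present).
#' @export
dissociation_time <- function(trace, threshold = 0.2, baseline_frames = 5) {
  peak <- trace$peak_intensity
  nt <- length(peak)
  baseline <- stats::median(peak[seq_len(min(baseline_frames, nt))])
  if (!is.finite(baseline) || baseline <= 0) return(NA_real_)
  below <- peak <= threshold * baseline
  if (all(below)) return(trace$time_min[1])
  if (!below[nt]) return(NA_real_)
  # first index from which 'below' holds through the end
  i <- max(which(!below)) + 1L
  dt <- trace$time_min[2] - trace$time_min[1]
  trace$time_min[i] - dt / 2
}

#' Translocation timing relative to ring dissociation
#'
#' @param result A [quantify()] result (refined event times).
#' @param t_dissoc Dissociation time, min.
#' @return List with `start_offset` and `end_offset` in minutes
#'   (`t_start - t_dissoc`, `t_end - t_dissoc`); NAs when either side is
#'   undefined.
#' @export
timing_relative <- function(result, t_dissoc) {
  if (!is.finite(t_dissoc) || !is.finite(result$t_start)) {
    return(list(start_offset = NA_real_, end_offset = NA_real_))
  }
  list(start_offset = result$t_start - t_dissoc,
       end_offset = result$t_end - t_dissoc)
}

#' Constriction width normalized to the unconstricted ring
#'
#' Width at time `t` (nearest frame, moment or Gaussian estimator) divided
#' by the median width over the first `baseline_frames` ring-present
#' frames — the unconstricted reference.
#'
#' @param trace A [ring_trace()].
#' @param t Time, min.
#' @param baseline_frames Frames defining the unconstricted width.
#' @param estimator `"moment"` (default; never fails to converge) or
#'   `"gauss"`.
#' @return Width fraction, or `NA_real_` without a baseline or when the
#'   ring is absent at `t`.
#' @export
normalized_constriction_width <- function(trace, t, baseline_frames = 5,
                                          estimator = c("moment", "gauss")) {
  estimator <- match.arg(estimator)
  col <- if (estimator == "moment") "width_moment_um" else "width_gauss_um"
  w <- trace[[col]]
  ok <- which(trace$present & is.finite(w))
  if (length(ok) < 3) return(NA_real_)
  base <- stats::median(w[ok[seq_len(min(baseline_frames, length(ok)))]])
  i <- which.min(abs(trace$time_min - t))
  if (!trace$present[i] || !is.finite(w[i]) || base <= 0) return(NA_real_)
  w[i] / base
}
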