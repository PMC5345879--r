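#' Long axis of a cell mask
#'
#' The axis is the principal direction of the mask pixel coordinates,
#' through the mask centroid, extended a fixed distance beyond each pole so
#' line profiles include background on both sides. Near-isotropic masks
#' (aspect ratio below `min_aspect`) raise a degenerate-geometry error:
#' cells are rods, anything else signals bad segmentation.
#'
#' @param mask Logical matrix, a single connected component.
#' @param pixel_size um/px.
#' @param extend_um Extension beyond each pole, um.
#' @param min_aspect Minimum sqrt(eigenvalue ratio) accepted as a rod.
#' @return Object of class `cell_axis`: endpoints `p0`/`p1` (um, raster
#'   coordinates), unit `direction`, profile-coordinate `mask_extent`
#'   (um interval covered by the mask along the axis), and `mask_length_um`.
#' @export
long_axis <- function(mask, pixel_size, extend_um = 0.7, min_aspect = 1.2) {
  if (!any(mask)) stop_user("empty mask")
  lab <- label_components(mask)
  if (max(lab) > 1L) stop_user("mask has multiple connected components")
  idx <- which(mask, arr.ind = TRUE)
  xy <- cbind(x = (idx[, 2] - 0.5) * pixel_size,
              y = (idx[, 1] - 0.5) * pixel_size)
  ctr <- colMeans(xy)
  cv <- stats::cov(xy)
  eig <- eigen(cv, symmetric = TRUE)
  if (sqrt(eig$values[1] / max(eig$values[2], 1e-12)) < min_aspect) {
    stop_user("degenerate geometry: mask has no dominant long axis")
  }
  v <- eig$vectors[, 1]
  if (v[1] < 0 || (v[1] == 0 && v[2] < 0)) v <- -v
  proj <- (xy[, 1] - ctr[1]) * v[1] + (xy[, 2] - ctr[2]) * v[2]
  # half a pixel on each side accounts for pixel extent beyond the centers
  t0 <- min(proj) - pixel_size / 2
  t1 <- max(proj) + pixel_size / 2
  structure(list(
    center = ctr,
    direction = v,
    p0 = ctr + (t0 - extend_um) * v,
    p1 = ctr + (t1 + extend_um) * v,
    mask_extent = c(extend_um, extend_um + (t1 - t0)),
    mask_length_um = t1 - t0,
    extend_um = extend_um
  ), class = "cell_axis")
}

#' Reverse the orientation of a cell axis
#'
#' Swaps the endpoints so position 0 moves to the opposite pole. Used to
#' enforce the convention that position 0 lies at the pole of the smaller
#' daughter compartment.
#'
#' @param axis A `cell_axis`.
#' @return The flipped `cell_axis`.
#' @export
axis_flip <- function(axis) {
  len <- sqrt(sum((axis$p1 - axis$p0)^2))
  structure(list(
    center = axis$center,
    direction = -axis$direction,
    p0 = axis$p1,
    p1 = axis$p0,
    mask_extent = sort(len - axis$mask_extent),
    mask_length_um = axis$mask_length_um,
    extend_um = axis$extend_um
  ), class = "cell_axis")
}

#' Axial line profile of an image
#'
#' Samples the image along the axis at one-pixel spacing; each sample is
#' the mean of `width_px` bilinear samples taken perpendicular to the axis
#' (the standard "9 pixels wide," about 1 um, averaging band).
#'
#' @param image Numeric matrix.
#' @param axis A [long_axis()] result (or compatible list with `p0`, `p1`,
#'   `direction`, `mask_extent`).
#' @param pixel_size um/px.
#' @param width_px Odd integer averaging width.
#' @return Object of class `line_profile` with `positions` (um from `p0`),
#'   `values`, `mask_extent`, `width_px`, and a `background_subtracted`
#'   flag.
#' @export
line_profile <- function(image, axis, pixel_size, width_px = 9) {
  if (width_px %% 2 != 1) stop_user("width_px must be odd")
  v <- axis$direction
  u <- c(-v[2], v[1])
  len <- sqrt(sum((axis$p1 - axis$p0)^2))
  if (len <= 0) stop_user("axis has zero length")
  positions <- seq(0, len, by = pixel_size)
  offs <- (seq_len(width_px) - (width_px + 1) / 2) * pixel_size
  pts_x <- outer(axis$p0[1] + positions * v[1], offs * u[1], `+`)
  pts_y <- outer(axis$p0[2] + positions * v[2], offs * u[2], `+`)
  # raster coordinates: pixel centers at integers, position (i-0.5)*px
  samp <- bilinear_sample(image, pts_x / pixel_size + 0.5,
                          pts_y / pixel_size + 0.5)
  vals <- rowMeans(matrix(samp, length(positions), width_px))
  if (!all(is.finite(vals))) stop_user("axis leaves the raster")
  structure(list(
    positions = positions,
    values = vals,
    mask_extent = axis$mask_extent,
    width_px = as.integer(width_px),
    pixel_size = pixel_size,
    background_subtracted = FALSE,
    background = NA_real_
  ), class = "line_profile")
}

#' Subtract the exterior background from a line profile
#'
#' The background is the median of samples outside the mask extent (robust
#' to stray fluorescent debris); samples within `gap_um` of the poles are
#' excluded because the point-spread-function tail of the cell signal
#' still reaches them. After subtraction, negative residuals are clipped
#' at zero so downstream integrals are non-negative.
#'
#' @param profile A [line_profile()].
#' @param mask_extent Optional interval (um) overriding the profile's own.
#' @param gap_um Guard band beyond the poles excluded from the background.
#' @return The background-subtracted profile (flag set).
#' @export
subtract_background <- function(profile, mask_extent = profile$mask_extent,
                                gap_um = 0.25) {
  outside <- profile$positions < mask_extent[1] - gap_um |
    profile$positions > mask_extent[2] + gap_um
  if (!any(outside)) {
    outside <- profile$positions < mask_extent[1] |
      profile$positions > mask_extent[2]
  }
  if (!any(outside)) stop_user("profile has no samples outside the cell")
  bg <- stats::median(profile$values[outside])
  profile$values <- pmax(profile$values - bg, 0)
  profile$background_subtracted <- TRUE
  profile$background <- bg
  profile
}

# Linear interpolation of a profile at position x (um).
profile_value_at <- function(profile, x) {
  stats::approx(profile$positions, profile$values, xout = x, rule = 2)$y
}

# Local maxima (strict left, non-strict right) with a simple prominence:
# height above the higher of the two flanking minima bounded by the next
# higher point on each side.
find_peaks <- function(vals) {
  n <- length(vals)
  if (n < 3) return(data.frame(i = integer(0), prominence = numeric(0)))
  cand <- which(vals[2:(n - 1)] > vals[1:(n - 2)] &
                  vals[2:(n - 1)] >= vals[3:n]) + 1L
  prom <- vapply(cand, function(i) {
    lmin <- vals[i]; j <- i
    while (j > 1 && vals[j] <= vals[i]) { j <- j - 1; lmin <- min(lmin, vals[j]) }
    if (vals[j] <= vals[i]) lmin <- min(vals[seq_len(i)])
    rmin <- vals[i]; j <- i
    while (j < n && vals[j] <= vals[i]) { j <- j + 1; rmin <- min(rmin, vals[j]) }
    if (vals[j] <= vals[i]) rmin <- min(vals[i:n])
    vals[i] - max(lmin, rmin)
  }, numeric(1))
  data.frame(i = cand, prominence = prom)
}

#' Locate the constriction on a phase-contrast profile
#'
#' The septum appears as a bright bump interior to the (phase-dark) cell
#' body. Among interior local maxima above a prominence threshold, the one
#' nearest `prior_position` is chosen when a prior is given, otherwise the
#' most prominent; the position is refined to subpixel by a parabolic fit.
#' The prominence threshold scales with the cell's phase depth (exterior
#' background minus interior minimum), so an unconstricted cell returns the
#' no-constriction sentinel rather than a noise peak.
#'
#' @param phase_profile A [line_profile()] of the phase channel (raw or
#'   background-subtracted).
#' @param prior_position Optional prior position, um.
#' @param prominence_frac Minimum prominence as a fraction of phase depth.
#' @param interior_margin um excluded at each pole.
#' @return Position in um, or `NA_real_` if no constriction is found.
#' @export
constriction_position <- function(phase_profile, prior_position = NULL,
                                  prominence_frac = 0.1,
                                  interior_margin = 0.3) {
  me <- phase_profile$mask_extent
  inside <- phase_profile$positions > me[1] + interior_margin &
    phase_profile$positions < me[2] - interior_margin
  if (sum(inside) < 3) return(NA_real_)
  vals <- phase_profile$values[inside]
  pos <- phase_profile$positions[inside]
  outside <- phase_profile$positions < me[1] |
    phase_profile$positions > me[2]
  bg <- if (any(outside)) {
    stats::median(phase_profile$values[outside])
  } else {
    max(phase_profile$values)
  }
  depth <- bg - min(vals)
  if (depth <= 0) return(NA_real_)
  peaks <- find_peaks(vals)
  peaks <- peaks[peaks$prominence >= prominence_frac * depth, , drop = FALSE]
  if (!nrow(peaks)) return(NA_real_)
  pick <- if (!is.null(prior_position) && is.finite(prior_position)) {
    peaks$i[which.min(abs(pos[peaks$i] - prior_position))]
  } else {
    peaks$i[which.max(peaks$prominence)]
  }
  pos[pick] + parabolic_refine(vals, pick) * phase_profile$pixel_size
}

#' Phase-contrast modulation of the septum
#'
#' Quantifies how far the septal bump has risen from the cell interior
#' toward the exterior background: `m = (P(x_c) - S) / (B - S)` where `S`
#' is the mean of the two flanking interior minima within `flank_um` of the
#' constriction and `B` the exterior background. `m` is clipped to [0, 1]
#' and approaches 1 as the septum closes; it is invariant under affine
#' rescaling of the image intensities.
#'
#' @param phase_profile A raw phase [line_profile()].
#' @param x_c Constriction position, um.
#' @param flank_um Search window for the flanking minima.
#' @return Modulation in [0, 1], or `NA_real_` if undefined (`B <= S`).
#' @export
phase_modulation <- function(phase_profile, x_c, flank_um = 0.5) {
  if (!is.finite(x_c)) return(NA_real_)
  me <- phase_profile$mask_extent
  pos <- phase_profile$positions
  vals <- phase_profile$values
  outside <- pos < me[1] | pos > me[2]
  if (!any(outside)) return(NA_real_)
  b <- stats::median(vals[outside])
  left <- vals[pos >= x_c - flank_um & pos < x_c & pos > me[1]]
  right <- vals[pos > x_c & pos <= x_c + flank_um & pos < me[2]]
  if (!length(left) || !length(right)) return(NA_real_)
  s <- mean(c(min(left), min(right)))
  if (b <= s) return(NA_real_)
  clamp((profile_value_at(phase_profile, x_c) - s) / (b - s), 0, 1)
}

#' Kymograph of one channel
#'
#' Column `t` is the axial line profile at frame `t`; with a static mask
#' all columns share one axis, so positions align across frames by
#' construction.
#'
#' @param movie A [cell_movie()].
#' @param channel Channel name.
#' @param axis Optional precomputed axis (e.g. an oriented one).
#' @param width_px Profile averaging width.
#' @return Matrix `positions x frames` with attributes `positions` (um)
#'   and `times` (min).
#' @export
kymograph <- function(movie, channel, axis = NULL, width_px = 9) {
  if (!channel %in% names(movie$channels)) {
    stop_user("channel '", channel, "' not present")
  }
  if (is.null(axis)) axis <- long_axis(movie$cell_mask, movie$pixel_size)
  arr <- movie$channels[[channel]]
  cols <- lapply(seq_len(dim(arr)[3]), function(t) {
    tryCatch(line_profile(arr[, , t], axis, movie$pixel_size,
                          width_px)$values,
             error = function(e) NULL)
  })
  npos <- max(vapply(cols, function(x) if (is.null(x)) 0L else length(x),
                     1L))
  out <- vapply(cols, function(x) {
    if (is.null(x)) rep(NA_real_, npos) else x
  }, numeric(npos))
  ref <- line_profile(arr[, , 1], axis, movie$pixel_size, width_px)
  structure(out, positions = ref$positions, times = movie$times)
}
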