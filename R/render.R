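#' Multi-channel time-lapse movie container
#'
#' A `cell_movie` holds named channels as `[ny, nx, nt]` arrays sharing one
#' raster, a static binary cell mask, and the physical metadata every
#' downstream stage needs (pixel size in um/px, frame interval in min).
#'
#' @param channels Named list of numeric arrays `[ny, nx, nt]`.
#' @param pixel_size um per pixel.
#' @param frame_interval Minutes between frames.
#' @param cell_mask Logical matrix `[ny, nx]`.
#' @param meta Optional metadata list (seed, registration offsets, ...).
#' @return An object of class `cell_movie`.
#' @export
cell_movie <- function(channels, pixel_size, frame_interval, cell_mask,
                       meta = list()) {
  if (!length(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop_user("channels must be a non-empty named list")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L)) {
    stop_user("every channel must be a [ny, nx, nt] array")
  }
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    stop_user("all channels must share raster shape and frame count")
  }
  if (pixel_size <= 0) stop_user("pixel_size must be positive")
  d <- dims[[1]]
  if (!all(dim(cell_mask) == d[1:2])) {
    stop_user("cell_mask shape must match the channel rasters")
  }
  structure(list(
    channels = channels,
    pixel_size = pixel_size,
    frame_interval = frame_interval,
    cell_mask = matrix(as.logical(cell_mask), d[1], d[2]),
    n_frames = d[3],
    times = seq.int(0L, d[3] - 1L) * frame_interval,
    meta = meta
  ), class = "cell_movie")
}

#' @export
print.cell_movie <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<cell_movie> %d x %d px, %d frames, %.3f um/px, dt %g min\n",
              d[2], d[1], d[3], x$pixel_size, x$frame_interval))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

# Fractional pixel coverage of the rod cell (rectangle with semicircular
# caps): linear anti-aliasing of the signed distance to the cell outline.
rod_coverage <- function(nx, ny, px, x0, x1, yc, half_width) {
  xs <- (seq_len(nx) - 0.5) * px
  ys <- (seq_len(ny) - 0.5) * px
  ax <- pmin(pmax(xs, x0 + half_width), x1 - half_width)
  dx <- outer(rep(1, ny), xs - ax)
  dy <- outer(ys - yc, rep(1, nx))
  d <- sqrt(dx^2 + dy^2)
  matrix(clamp((half_width - d) / px + 0.5, 0, 1), ny, nx)
}

# Overlap length of interval [a, b] with [lo, hi], vectorized over a/b.
interval_overlap <- function(a, b, lo, hi) {
  pmax(0, pmin(b, hi) - pmax(a, lo))
}

#' Render a synthetic division movie
#'
#' Turns a ground truth and its trace into a multi-channel image stack:
#' nucleoid channels (`dapi`, `hupa`, `sytox`) place a piecewise-uniform
#' axial DNA density split at the division plane according to the trace
#' fractions; the ring channel (`zipa`) is a narrow band at the plane whose
#' short-axis extent follows the septum diameter and which vanishes at
#' closure; the phase channel is a stylized phase-contrast image (bright
#' background, dark cell) with a bright septal bump whose amplitude grows
#' as the septum closes. All channels are blurred with the optics PSF and
#' carry Poisson noise unless `optics$gain == 0`.
#'
#' The cell axis is horizontal with the smaller compartment on the left;
#' analysis code must not rely on this and discovers orientation from the
#' images.
#'
#' @param truth A [cell_truth()].
#' @param trace The matching [simulate_trace()] output.
#' @param optics An [optics_model()].
#' @param seed Integer seed for the noise draws.
#' @param channels Channels to render (subset of
#'   `c("phase", "dapi", "hupa", "sytox", "zipa")`).
#' @param margin_um Background margin around the cell, um.
#' @return A [cell_movie()].
#' @export
render_movie <- function(truth, trace, optics = optics_model(), seed,
                         channels = c("phase", "dapi", "hupa", "sytox",
                                      "zipa"),
                         margin_um = 1.0) {
  if (missing(seed)) stop_user("render_movie() requires a seed")
  channels <- match.arg(channels, several.ok = TRUE)
  px <- optics$pixel_size
  L <- truth$cell_length
  W <- truth$cell_width
  nx <- as.integer(ceiling((L + 2 * margin_um) / px))
  ny <- as.integer(ceiling((W + 2 * margin_um) / px))
  if (nx < 8L || ny < 8L) stop_user("raster too small to contain the cell")
  x0 <- (nx * px - L) / 2
  x1 <- x0 + L
  yc <- ny * px / 2
  xp <- x0 + truth$plane_frac * L
  sigma_px <- optics$psf_sigma / px

  cov <- rod_coverage(nx, ny, px, x0, x1, yc, W / 2)
  mask <- cov >= 0.5

  xs_lo <- (seq_len(nx) - 1) * px
  xs_hi <- seq_len(nx) * px
  ys_lo <- (seq_len(ny) - 1) * px
  ys_hi <- seq_len(ny) * px
  xs_mid <- (seq_len(nx) - 0.5) * px

  # The nucleoid is compact: constant transverse extent, slightly narrower
  # than the cell, independent of the axial position (no pole-cap taper).
  wn <- 0.8 * W
  gy_dna <- interval_overlap(ys_lo, ys_hi, yc - wn / 2, yc + wn / 2) / px
  gy_dna <- gy_dna / sum(gy_dna)

  # Axial mass landing in each pixel column for given compartment fractions.
  dna_column_mass <- function(frac_small, total) {
    small <- interval_overlap(xs_lo, xs_hi, x0, xp) / (xp - x0)
    large <- interval_overlap(xs_lo, xs_hi, xp, x1) / (x1 - xp)
    total * (frac_small * small + (1 - frac_small) * large)
  }

  nt <- optics$n_frames
  set.seed(seed)
  out <- lapply(channels, function(ch) array(0, c(ny, nx, nt)))
  names(out) <- channels

  add_noise <- function(img) {
    if (optics$gain <= 0) return(img)
    g <- optics$gain
    matrix(stats::rpois(length(img), pmax(img, 0) / g) * g,
           nrow(img), ncol(img))
  }

  gx_ring <- exp(-(xs_mid - xp)^2 / (2 * 0.05^2))
  sigma_bump <- 0.10
  gx_bump <- exp(-(xs_mid - xp)^2 / (2 * sigma_bump^2))
  # pre-compensate the PSF attenuation of the narrow bump so the rendered
  # septal peak reaches the background level at full closure (modulation 1)
  bump_comp <- sqrt(sigma_bump^2 + optics$psf_sigma^2) / sigma_bump

  for (t in seq_len(nt)) {
    fr <- trace[t, ]
    for (ch in channels) {
      img <- switch(ch,
        dapi = outer(gy_dna,
                     dna_column_mass(fr$frac_small_dapi,
                                     optics$dna_photons)),
        hupa = outer(gy_dna,
                     dna_column_mass(fr$frac_small_hupa,
                                     optics$dna_photons)),
        sytox = {
          # the stripped share leaves the cell's total label content
          tot <- optics$dna_photons *
            (1 - (1 - truth$sytox_retention) *
               moved_fraction(truth, fr$time_min))
          outer(gy_dna, dna_column_mass(fr$frac_small_sytox, tot))
        },
        zipa = {
          if (isTRUE(fr$ring_present)) {
            d_eff <- max(fr$septum_diameter_um, 0.05)
            gy <- interval_overlap(ys_lo, ys_hi,
                                   yc - d_eff / 2, yc + d_eff / 2) / px
            band <- outer(gy, gx_ring)
            band * (optics$ring_photons / max(sum(band), 1e-12))
          } else {
            matrix(0, ny, nx)
          }
        },
        phase = {
          depth <- optics$phase_background - optics$phase_interior
          base <- optics$phase_background - depth * cov
          bump_amp <- depth * (1 - fr$septum_diameter_um / W) * bump_comp
          base + bump_amp * cov * outer(rep(1, ny), gx_bump)
        }
      )
      if (ch == "phase") {
        img <- blur_gaussian(img, sigma_px, edge = "replicate")
      } else {
        img <- blur_gaussian(img, sigma_px, edge = "zero") +
          optics$background_level
      }
      out[[ch]][, , t] <- add_noise(img)
    }
  }

  cell_movie(out, pixel_size = px, frame_interval = optics$frame_interval,
             cell_mask = mask,
             meta = list(seed = seed, margin_um = margin_um))
}

#' Simulate one complete division movie
#'
#' Convenience wrapper drawing a truth, integrating its trace, and
#' rendering the movie. The truth/trace draw and the rendering noise use
#' seeds derived deterministically from `seed`.
#'
#' @inheritParams make_cell_truth
#' @inheritParams render_movie
#' @return A list with elements `movie`, `truth`, `trace`.
#' @export
simulate_division <- function(seed, population = default_population(),
                              optics = optics_model(),
                              channels = c("phase", "dapi", "hupa",
                                           "sytox", "zipa")) {
  truth <- make_cell_truth(population, seed = seed, optics = optics)
  trace <- suppressWarnings(simulate_trace(truth, optics))
  movie <- render_movie(truth, trace, optics, seed = seed + 500000L,
                        channels = channels)
  list(movie = movie, truth = truth, trace = trace)
}
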