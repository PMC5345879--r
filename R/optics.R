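#' Imaging model for the synthetic microscope
#'
#' Bundles the optical and acquisition parameters used both to render
#' synthetic movies and to interpret real ones. Defaults follow standard
#' wide-field imaging of E. coli: 0.111 um pixels (so a 9-pixel profile
#' width spans about 1 um), a diffraction-limited point spread function of
#' 0.25 um FWHM, and a 4-minute frame interval (an 8-minute pause spans two
#' frames).
#'
#' @param pixel_size Pixel size in um/px. Must be positive.
#' @param psf_fwhm Full width at half maximum of the isotropic Gaussian
#'   point spread function, in um.
#' @param background_level Fluorescence camera background, counts per pixel.
#' @param gain Poisson-equivalent gain of the noise model. Rendered
#'   intensities are drawn as `gain * Poisson(expected / gain)`; `gain = 0`
#'   disables noise entirely (useful for ground-truth fixtures).
#' @param frame_interval Time between frames, minutes.
#' @param n_frames Number of frames per movie.
#' @param dna_photons Expected integrated photon count per nucleoid label
#'   per frame.
#' @param ring_photons Expected integrated photon count of the septal ring
#'   label per frame while present.
#' @param phase_background Phase-contrast background level (bright), counts.
#' @param phase_interior Phase-contrast level inside the cell (dark), counts.
#'
#' @return An object of class `optics_model`.
#' @export
optics_model <- function(pixel_size = 0.111,
                         psf_fwhm = 0.25,
                         background_level = 100,
                         gain = 1,
                         frame_interval = 4,
                         n_frames = 25,
                         dna_photons = 2e5,
                         ring_photons = 2e4,
                         phase_background = 600,
                         phase_interior = 150) {
  if (pixel_size <= 0) stop_user("pixel_size must be positive")
  if (psf_fwhm <= 0) stop_user("psf_fwhm must be positive")
  if (frame_interval <= 0) stop_user("frame_interval must be positive")
  if (n_frames < 2) stop_user("need at least 2 frames")
  if (gain < 0) stop_user("gain must be >= 0")
  structure(list(
    pixel_size = pixel_size,
    psf_fwhm = psf_fwhm,
    psf_sigma = psf_fwhm / (2 * sqrt(2 * log(2))),
    background_level = background_level,
    gain = gain,
    frame_interval = frame_interval,
    n_frames = as.integer(n_frames),
    dna_photons = dna_photons,
    ring_photons = ring_photons,
    phase_background = phase_background,
    phase_interior = phase_interior
  ), class = "optics_model")
}

#' @export
print.optics_model <- function(x, ...) {
  cat("<optics_model>\n")
  cat(sprintf("  pixel size     %.3f um/px\n", x$pixel_size))
  cat(sprintf("  PSF FWHM       %.3f um (sigma %.3f um)\n",
              x$psf_fwhm, x$psf_sigma))
  cat(sprintf("  frame interval %g min, %d frames\n",
              x$frame_interval, x$n_frames))
  cat(sprintf("  noise gain     %g (0 = noise-free)\n", x$gain))
  invisible(x)
}

frame_times <- function(optics) {
  seq.int(0L, optics$n_frames - 1L) * optics$frame_interval
}
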