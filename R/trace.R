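#' Simulate the ground-truth label traces for one dividing cell
#'
#' Integrates the pump model on the movie's frame grid. The conserved label
#' (DAPI-like) follows the pump integral exactly: between `t_start` and
#' `t_end` the DNA fraction in the smaller compartment changes at
#' `v_true / (n_genomes * genome_size)` per second, frozen during pauses,
#' monotone, never reversing. The stripped-and-frozen label (HupA-like)
#' tracks the conserved label until septal closure `t_close` and is exactly
#' constant afterwards. The partially stripped label (SYTOX-like) loses a
#' fraction `1 - sytox_retention` of the label on every piece of DNA that
#' crosses the septum.
#'
#' @param truth A [cell_truth()].
#' @param optics An [optics_model()]; defines the frame grid.
#' @return A data frame of class `true_trace` with columns `frame`,
#'   `time_min`, `frac_small_dapi`, `frac_small_hupa`, `frac_small_sytox`,
#'   `septum_diameter_um`, `ring_present`.
#' @export
simulate_trace <- function(truth, optics = optics_model()) {
  times <- frame_times(optics)
  if (truth$t_end > max(times)) {
    warning("translocation event truncated by movie end",
            call. = FALSE)
  }

  moved <- moved_fraction(truth, times)
  dir_sign <- sign(truth$final_frac_small - truth$init_frac_small)

  dapi <- truth$init_frac_small + dir_sign * moved
  dapi_at_close <- truth$init_frac_small +
    dir_sign * moved_fraction(truth, truth$t_close)
  hupa <- ifelse(times < truth$t_close, dapi, dapi_at_close)

  r <- truth$sytox_retention
  # Label bookkeeping: of the moved DNA, only a fraction r arrives with its
  # label; the stripped share (1 - r) leaves the total.
  s_small <- if (dir_sign >= 0) {
    truth$init_frac_small + r * moved
  } else {
    truth$init_frac_small - moved
  }
  s_total <- 1 - (1 - r) * moved
  sytox <- clamp(s_small / s_total, 0, 1)

  structure(data.frame(
    frame = seq_along(times),
    time_min = times,
    frac_small_dapi = dapi,
    frac_small_hupa = hupa,
    frac_small_sytox = sytox,
    septum_diameter_um = truth$septum_diameter,
    ring_present = times < truth$t_close
  ), class = c("true_trace", "data.frame"))
}

# Fraction of total DNA that has crossed the plane by time t (vectorized):
# the pump integral v * active_time / (n * genome_size), with pauses
# excluded and the integral capped at the drawn final amount.
moved_fraction <- function(truth, t) {
  t_eff <- pmin(pmax(t, truth$t_start), truth$t_end)
  active <- t_eff - truth$t_start
  if (nrow(truth$pauses)) {
    for (i in seq_len(nrow(truth$pauses))) {
      a <- truth$pauses$onset[i]
      b <- a + truth$pauses$duration[i]
      active <- active - pmax(0, pmin(t_eff, b) - pmin(t_eff, a))
    }
  }
  m <- truth$v_true * active * 60 /
    (truth$n_genomes * truth$genome_size * 1e6)
  pmin(m, abs(truth$final_frac_small - truth$init_frac_small))
}
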