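#' Generate a fixed-cell calibration dataset
#'
#' Emulates a snapshot of fixed, permeabilized, DNA-stained cells used to
#' calibrate DNA amount against cell length. Lengths are drawn over the
#' stated range with a deliberate enrichment of cells carrying two fully
#' replicated chromosomes (a tight length cluster where the linear law
#' gives 2 genome units), so the total-intensity histogram shows the
#' dominant 2-genome peak the calibration relies on. True DNA amounts
#' follow `slope * (L - intercept)` with multiplicative noise, and
#' intensities are DNA amount times a fixed scale.
#'
#' @param n_cells Number of cells (>= 50).
#' @param truth_law Numeric `c(slope, intercept)` of the generating law,
#'   genome units per um and um.
#' @param noise_cv Coefficient of variation of the multiplicative intensity
#'   noise; must be < 1.
#' @param seed Integer seed.
#' @param frac_2n Fraction of cells drawn from the 2-genome cluster.
#' @param intensity_scale Arbitrary-units intensity per genome unit.
#' @param length_range Length range of the background population, um.
#' @return Data frame with columns `cell_id`, `cell_length_um`,
#'   `total_intensity`; the generating scale and law are attached as
#'   attributes `intensity_scale` and `truth_law`.
#' @export
make_fixed_cell_dataset <- function(n_cells = 321,
                                    truth_law = c(0.92, 0.53),
                                    noise_cv = 0.15,
                                    seed,
                                    frac_2n = 0.6,
                                    intensity_scale = 1000,
                                    length_range = c(2, 8)) {
  if (missing(seed)) stop_user("make_fixed_cell_dataset() requires a seed")
  if (n_cells < 50) stop_user("need at least 50 cells")
  if (noise_cv >= 1 || noise_cv < 0) stop_user("noise_cv must be in [0, 1)")
  slope <- truth_law[1]
  intercept <- truth_law[2]
  if (slope <= 0) stop_user("truth_law slope must be positive")

  set.seed(seed)
  # length at which the law yields exactly two genome units
  l_2n <- 2 / slope + intercept
  from_peak <- stats::runif(n_cells) < frac_2n
  lengths <- ifelse(
    from_peak,
    rnorm_trunc(n_cells, l_2n, 0.35,
                lower = max(length_range[1], intercept + 0.2)),
    stats::runif(n_cells, length_range[1], length_range[2])
  )
  lengths <- clamp(lengths, max(length_range[1], intercept + 0.05),
                   length_range[2])

  dna <- slope * (lengths - intercept)
  if (noise_cv > 0) {
    dna <- pmax(dna * (1 + noise_cv * stats::rnorm(n_cells)), 0.01)
  }
  structure(data.frame(
    cell_id = seq_len(n_cells),
    cell_length_um = lengths,
    total_intensity = dna * intensity_scale
  ), intensity_scale = intensity_scale, truth_law = truth_law)
}
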