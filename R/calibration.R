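#' Locate the 2-genome peak of a total-intensity distribution
#'
#' Kernel-density mode of the per-cell total DAPI intensities of fixed
#' cells. The dominant peak corresponds to cells with two fully replicated
#' chromosomes; its location anchors the intensity-to-genome scaling. If a
#' second peak reaches within `co_dominance` of the dominant one the
#' distribution is ambiguous and an error lists the candidates.
#'
#' @param total_intensities Numeric vector (>= 50 cells).
#' @param bw Bandwidth rule passed to [stats::density()].
#' @param co_dominance Peaks taller than this fraction of the dominant peak
#'   trigger the ambiguity error.
#' @return Intensity (a.u.) of the dominant peak.
#' @export
find_2n_peak <- function(total_intensities, bw = "nrd0",
                         co_dominance = 0.95) {
  x <- total_intensities[is.finite(total_intensities)]
  if (length(x) < 50) stop_user("need at least 50 cells")
  if (diff(range(x)) == 0) return(x[1])
  den <- stats::density(x, bw = bw)
  pk <- find_peaks(den$y)
  if (!nrow(pk)) return(den$x[which.max(den$y)])
  heights <- den$y[pk$i]
  top <- which.max(heights)
  co <- which(heights >= co_dominance * heights[top])
  if (length(co) > 1) {
    stop_user("ambiguous intensity distribution: co-dominant peaks at ",
              paste(signif(den$x[pk$i[co]], 4), collapse = ", "))
  }
  den$x[pk$i[top]]
}

#' Convert total intensities to DNA amounts
#'
#' The 2-genome peak intensity anchors the linear scale:
#' `amount_i = 2 * intensity_i / peak_2n` genome units.
#'
#' @param total_intensities Numeric vector, a.u.
#' @param peak_2n Intensity of the 2-genome peak (positive).
#' @return DNA amounts in genome units.
#' @export
calibrate_amounts <- function(total_intensities, peak_2n) {
  if (!is.finite(peak_2n) || peak_2n <= 0) {
    stop_user("peak_2n must be positive")
  }
  2 * total_intensities / peak_2n
}

#' Fit the DNA-amount versus cell-length law
#'
#' Unweighted ordinary least squares of amount on length,
#' `amount = m * L + c`, reported in the x-intercept form
#' `amount = slope * (L - intercept)` with `slope = m` and
#' `intercept = -c / m`.
#'
#' @param lengths Cell lengths, um (>= 10 points spanning > 1 um).
#' @param amounts DNA amounts, genome units.
#' @return Object of class `calibration_fit`: `slope` (genome units/um),
#'   `intercept` (um), `r_value`, `n_cells`, plus the raw OLS coefficients.
#' @export
fit_dna_length <- function(lengths, amounts) {
  ok <- is.finite(lengths) & is.finite(amounts)
  lengths <- lengths[ok]
  amounts <- amounts[ok]
  if (length(lengths) < 10) stop_user("need at least 10 points")
  if (diff(range(lengths)) <= 1) {
    stop_user("degenerate length spread (need > 1 um)")
  }
  if (stats::sd(amounts) == 0) {
    stop_user("constant amounts: intercept undefined")
  }
  fit <- stats::lm(amounts ~ lengths)
  m <- unname(stats::coef(fit)[2])
  c0 <- unname(stats::coef(fit)[1])
  if (m <= 0) stop_user("non-positive slope: calibration invalid")
  structure(list(
    slope = m,
    intercept = -c0 / m,
    r_value = stats::cor(lengths, amounts),
    n_cells = length(lengths),
    ols_intercept = c0,
    peak_intensity_2n = NA_real_
  ), class = "calibration_fit")
}

#' Full calibration chain on a fixed-cell table
#'
#' Peak finding, intensity-to-amount conversion, and the length-law fit in
#' one call.
#'
#' @param cells Data frame with columns `cell_length_um` and
#'   `total_intensity` (as produced by [make_fixed_cell_dataset()]).
#' @return A `calibration_fit` with `peak_intensity_2n` filled in and the
#'   per-cell `amounts` attached as an attribute.
#' @export
calibrate_dataset <- function(cells) {
  need <- c("cell_length_um", "total_intensity")
  if (!all(need %in% names(cells))) {
    stop_user("cells must have columns ", paste(need, collapse = ", "))
  }
  peak <- find_2n_peak(cells$total_intensity)
  amounts <- calibrate_amounts(cells$total_intensity, peak)
  fit <- fit_dna_length(cells$cell_length_um, amounts)
  fit$peak_intensity_2n <- peak
  attr(fit, "amounts") <- amounts
  fit
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit>\n")
  cat(sprintf("  DNA amount = %.3f (L - %.3f) genome units (R = %.3f)\n",
              x$slope, x$intercept, x$r_value))
  cat(sprintf("  n = %d cells", x$n_cells))
  if (is.finite(x$peak_intensity_2n)) {
    cat(sprintf("; 2n peak at %.4g a.u.", x$peak_intensity_2n))
  }
  cat("\n")
  invisible(x)
}
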