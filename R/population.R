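#' Exponential growth rate and doubling time
#'
#' Least squares on log(size) versus time: `mu` is the slope (1/min) and
#' the doubling time is `ln(2) / mu`, rounded to the nearest minute in
#' report tables.
#'
#' @param sizes Positive sizes (length, area, or a.u.).
#' @param times Times, min.
#' @return List with `mu` (1/min), `T_d` (min, `Inf` for non-growing
#'   cells), and `T_d_reported` (rounded).
#' @export
growth_rate <- function(sizes, times) {
  if (length(sizes) < 3) stop_user("need at least 3 observations")
  if (length(sizes) != length(times)) stop_user("length mismatch")
  if (any(sizes <= 0)) stop_user("sizes must be positive")
  mu <- unname(stats::coef(stats::lm(log(sizes) ~ times))[2])
  t_d <- if (mu <= 0) Inf else log(2) / mu
  list(mu = mu, T_d = t_d,
       T_d_reported = if (is.finite(t_d)) round(t_d) else Inf)
}

#' Expected final normalized intensity for whole-chromosome partitions
#'
#' A division ending with `k` complete chromosomes in the smaller daughter
#' out of `n` total settles at a normalized intensity of `100 * k / n`
#' percent: 0 (anucleate minicell), 25 (1 of 4), 33 (1 of 3), or 50
#' (1 of 2). Report tables round to integer percent; the exact value is
#' returned so that `value * n / 100` is always the integer `k`.
#'
#' @param k Chromosomes ending in the smaller daughter (`k <= n - k`, by
#'   definition of "smaller").
#' @param n Total chromosomes (2, 3, or 4).
#' @return Percent (exact, unrounded).
#' @export
expected_final_intensity <- function(k, n) {
  if (!n %in% 2:4) stop_user("n must be 2, 3, or 4")
  if (k < 0 || k > n || k != round(k)) stop_user("k must be an integer in [0, n]")
  if (k > n - k) {
    stop_user("k > n - k: the smaller daughter cannot hold the majority")
  }
  100 * k / n
}

#' Genome units to megabases
#'
#' One genome unit is one fully replicated E. coli chromosome (4.6 Mb).
#'
#' @param u Amount in genome units (>= 0).
#' @return Amount in Mb.
#' @export
genome_units_to_mb <- function(u) {
  if (any(u < 0)) stop_user("genome units must be non-negative")
  u * GENOME_MB
}

#' Population summary of translocation results
#'
#' Means and standard deviations of speeds and timing offsets, the
#' fraction of cells with at least one detected pause, the total reversal
#' count, a genome-unit amount histogram, and the OLS relation between
#' translocation start time and speed.
#'
#' @param results Data frame with one row per cell; recognized columns:
#'   `speed_bps`, `start_offset`, `end_offset`, `n_pauses`, `reversals`,
#'   `amount_genome` (missing columns are simply skipped).
#' @return List of class `population_summary`.
#' @export
summarize_population <- function(results) {
  if (!nrow(results)) stop_user("need at least one result")
  col <- function(name) {
    if (name %in% names(results)) results[[name]] else rep(NA_real_,
                                                           nrow(results))
  }
  mstat <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) return(c(mean = NA_real_, sd = NA_real_, n = 0))
    c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else NA_real_,
      n = length(x))
  }
  speed <- mstat(col("speed_bps"))
  start <- mstat(col("start_offset"))
  end <- mstat(col("end_offset"))
  npause <- col("n_pauses")
  amount <- col("amount_genome")
  amount <- amount[is.finite(amount)]

  tvs <- list(slope = NA_real_, intercept = NA_real_, r_value = NA_real_)
  ok <- is.finite(col("speed_bps")) & is.finite(col("start_offset"))
  if (sum(ok) >= 3) {
    fit <- stats::lm(col("speed_bps")[ok] ~ col("start_offset")[ok])
    tvs <- list(slope = unname(stats::coef(fit)[2]),
                intercept = unname(stats::coef(fit)[1]),
                r_value = stats::cor(col("start_offset")[ok],
                                     col("speed_bps")[ok]))
  }
  structure(list(
    n = nrow(results),
    speed_mean = speed[["mean"]], speed_sd = speed[["sd"]],
    speed_n = speed[["n"]],
    start_offset_mean = start[["mean"]], start_offset_sd = start[["sd"]],
    end_offset_mean = end[["mean"]],
    pause_fraction = if (all(is.na(npause))) NA_real_ else {
      mean(npause >= 1, na.rm = TRUE)
    },
    reversal_count = sum(col("reversals"), na.rm = TRUE),
    amount_histogram = if (length(amount)) {
      h <- graphics::hist(amount, breaks = seq(0, ceiling(max(amount) * 4) /
                                                 4 + 0.25, by = 0.25),
                          plot = FALSE)
      data.frame(mid = h$mids, count = h$counts)
    } else {
      data.frame(mid = numeric(0), count = integer(0))
    },
    timing_vs_speed = tvs
  ), class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat("<population_summary>\n")
  cat(sprintf("  n = %d cells (%d with speed estimates)\n",
              x$n, x$speed_n))
  if (is.finite(x$speed_mean)) {
    cat(sprintf("  speed %.0f +/- %.0f bp/s\n", x$speed_mean,
                ifelse(is.finite(x$speed_sd), x$speed_sd, 0)))
  }
  if (is.finite(x$start_offset_mean)) {
    cat(sprintf("  start %+.1f min, end %+.1f min vs ring dissociation\n",
                x$start_offset_mean, x$end_offset_mean))
  }
  if (is.finite(x$pause_fraction)) {
    cat(sprintf("  pause fraction %.0f%%; reversals %d\n",
                100 * x$pause_fraction, x$reversal_count))
  }
  invisible(x)
}
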