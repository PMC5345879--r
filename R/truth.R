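#' Default population parameters for the synthetic division movies
#'
#' The defaults encode the population this package's synthetic cells are
#' drawn from: translocation speeds Normal(1700, 800) bp/s truncated at
#' 200 bp/s, a 10% per-cell pause incidence with pauses of 8-12 minutes,
#' translocation starting on average 8 minutes before septal (ring)
#' closure with a 10-minute spread, two chromosomes in cells up to 4.5 um
#' and four above, and pumping directed toward the compartment already
#' holding the chromosome majority with probability 0.8.
#'
#' @param ... Named overrides of individual parameters.
#' @return A named list of class `population_params`.
#' @export
default_population <- function(...) {
  p <- list(
    length_range = c(2.5, 7.5),    # um, uniform
    cell_width = 0.9,              # um
    plane_frac_range = c(0.2, 0.45),
    init_jitter_sd = 0.03,         # jitter of initial DNA fraction
    genome_size = 4.6,             # Mb per fully replicated chromosome
    n_genomes_threshold = 4.5,     # um; <=: 2 genomes, >: 4
    v_mean = 1700,                 # bp/s
    v_sd = 800,
    v_min = 200,
    pause_prob = 0.10,             # per-cell incidence
    pause_duration_range = c(8, 12),  # min
    close_offset_mean = 8,         # t_close - t_start, min
    close_offset_sd = 10,
    close_offset_min = -20,
    t_close_mean = 48,             # min
    t_close_sd = 8,
    t_close_range = c(24, 80),
    constriction_duration = 32,    # min of linear septum closure
    p_toward_larger = 0.8,
    sytox_retention = 0.5          # fraction of label surviving passage
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) {
    stop_user("unknown population parameter(s): ",
              paste(unknown, collapse = ", "))
  }
  p[names(ov)] <- ov
  validate_population(structure(p, class = "population_params"))
}

validate_population <- function(p) {
  if (any(unlist(p[c("cell_width", "genome_size", "v_mean")]) <= 0) ||
      p$v_sd < 0 || p$v_min <= 0) {
    stop_user("invalid population parameters: scales must be positive")
  }
  if (p$pause_prob < 0 || p$pause_prob > 1 ||
      p$p_toward_larger < 0 || p$p_toward_larger > 1 ||
      p$sytox_retention < 0 || p$sytox_retention > 1) {
    stop_user("invalid population parameters: probabilities must be in [0,1]")
  }
  if (diff(p$length_range) < 0 || p$length_range[1] <= 0 ||
      p$plane_frac_range[1] <= 0 || p$plane_frac_range[2] > 0.5) {
    stop_user("invalid population parameters: geometry ranges")
  }
  if (diff(p$pause_duration_range) < 0 || p$pause_duration_range[1] <= 0) {
    stop_user("invalid population parameters: pause durations")
  }
  p
}

#' Construct a fully specified division ground truth
#'
#' Low-level constructor used both by the random generator
#' [make_cell_truth()] and by tests that need hand-built scenarios. All
#' times are minutes from the start of the movie; `plane_frac` measures the
#' division plane position from the pole of the smaller compartment.
#'
#' @param cell_length,cell_width Cell dimensions, um.
#' @param plane_frac Division plane position as a fraction of cell length
#'   (0 < plane_frac <= 0.5; the smaller compartment side).
#' @param n_genomes Total fully replicated chromosomes (2 or 4).
#' @param genome_size Chromosome size in Mb (4.6 for E. coli).
#' @param init_frac_small Initial fraction of total DNA in the smaller
#'   compartment.
#' @param final_frac_small Final fraction; `final_frac_small * n_genomes`
#'   must be an integer (whole chromosomes end up on each side).
#' @param v_true True pumping speed, bp/s.
#' @param t_start,t_end Translocation start and end, min.
#' @param t_close Septal closure = ring dissociation time, min.
#' @param pauses Data frame with columns `onset` (min) and `duration` (min),
#'   or NULL.
#' @param sytox_retention Fraction of membrane-impermeant label retained on
#'   DNA that crosses the septum, in [0, 1].
#' @param optics An [optics_model()]; defines the frame grid on which the
#'   septum diameter trajectory is tabulated.
#' @param constriction_duration Minutes over which the septum diameter
#'   closes linearly before `t_close`.
#' @return An object of class `cell_truth`.
#' @export
cell_truth <- function(cell_length, cell_width = 0.9, plane_frac,
                       n_genomes, genome_size = 4.6,
                       init_frac_small, final_frac_small,
                       v_true, t_start, t_end, t_close,
                       pauses = NULL, sytox_retention = 0.5,
                       optics = optics_model(),
                       constriction_duration = 32) {
  if (is.null(pauses)) {
    pauses <- data.frame(onset = numeric(0), duration = numeric(0))
  }
  times <- frame_times(optics)
  onset <- t_close - constriction_duration
  d <- ifelse(times < onset, cell_width,
              ifelse(times >= t_close, 0,
                     cell_width * (t_close - times) / constriction_duration))
  truth <- structure(list(
    cell_length = cell_length,
    cell_width = cell_width,
    plane_frac = plane_frac,
    n_genomes = as.integer(n_genomes),
    genome_size = genome_size,
    init_frac_small = init_frac_small,
    final_frac_small = final_frac_small,
    v_true = v_true,
    t_start = t_start,
    t_end = t_end,
    t_close = t_close,
    pauses = pauses,
    sytox_retention = sytox_retention,
    septum_diameter = d,
    times = times,
    truncated = t_end > max(times)
  ), class = "cell_truth")
  validate_cell_truth(truth)
}

validate_cell_truth <- function(truth) {
  with(truth, {
    if (cell_length <= 0 || cell_width <= 0) {
      stop_user("cell dimensions must be positive")
    }
    if (plane_frac <= 0 || plane_frac > 0.5) {
      stop_user("plane_frac must lie in (0, 0.5]")
    }
    if (init_frac_small < 0 || init_frac_small > 1 ||
        final_frac_small < 0 || final_frac_small > 1) {
      stop_user("DNA fractions must lie in [0, 1]")
    }
    k <- final_frac_small * n_genomes
    if (abs(k - round(k)) > 1e-9) {
      stop_user("final_frac_small * n_genomes must be an integer")
    }
    if (t_start >= t_end) stop_user("t_start must precede t_end")
    if (v_true < 0) stop_user("v_true must be non-negative")
    if (nrow(pauses)) {
      if (any(pauses$onset < t_start - 1e-9) ||
          any(pauses$onset + pauses$duration > t_end + 1e-9)) {
        stop_user("pauses must lie within [t_start, t_end]")
      }
    }
    if (any(diff(septum_diameter) > 1e-9)) {
      stop_user("septum diameter must be non-increasing")
    }
  })
  truth
}

#' Draw one division ground truth from a population
#'
#' Samples cell geometry, chromosome number, pumping speed, pause
#' structure, and event timing from the stated population distributions
#' (see [default_population()]). The translocation end time follows from
#' the amount of DNA that must move and the drawn speed; events that would
#' outlast the movie are truncated at the final frame with a warning flag
#' on the returned truth (`$truncated`).
#'
#' @param population A [default_population()] list.
#' @param seed Integer seed; required so every truth is reproducible.
#' @param optics An [optics_model()].
#' @return A `cell_truth` object.
#' @export
make_cell_truth <- function(population = default_population(), seed,
                            optics = optics_model()) {
  if (missing(seed)) stop_user("make_cell_truth() requires a seed")
  p <- validate_population(population)
  set.seed(seed)

  L <- stats::runif(1, p$length_range[1], p$length_range[2])
  plane <- stats::runif(1, p$plane_frac_range[1], p$plane_frac_range[2])
  n <- if (L <= p$n_genomes_threshold) 2L else 4L
  init <- clamp(plane + stats::rnorm(1, 0, p$init_jitter_sd), 0.05, 0.499)

  toward_larger <- stats::runif(1) < p$p_toward_larger
  k <- if (toward_larger) floor(init * n) else ceiling(init * n)
  final <- k / n

  v <- rnorm_trunc(1, p$v_mean, p$v_sd, lower = p$v_min)

  t_close <- rnorm_trunc(1, p$t_close_mean, p$t_close_sd,
                         lower = p$t_close_range[1],
                         upper = p$t_close_range[2])
  offset <- rnorm_trunc(1, p$close_offset_mean, p$close_offset_sd,
                        lower = p$close_offset_min)
  dt <- optics$frame_interval
  t_start <- max(t_close - offset, 2 * dt)

  pump_min <- abs(final - init) * n * p$genome_size * 1e6 / v / 60

  # Pauses are defined at the acquisition time resolution (a pause is an
  # interval over which the sampled trace is flat for two or more frames),
  # so onsets sit on the frame grid; sub-frame pause phase is not part of
  # the generated world.
  pauses <- data.frame(onset = numeric(0), duration = numeric(0))
  if (stats::runif(1) < p$pause_prob && pump_min > 2 * dt) {
    dur <- stats::runif(1, p$pause_duration_range[1],
                        p$pause_duration_range[2])
    onset <- t_start + stats::runif(1, 0.15, 0.7) * pump_min
    onset <- round(onset / dt) * dt
    if (onset <= t_start) onset <- t_start + dt
    pauses <- data.frame(onset = onset, duration = dur)
  }
  t_end <- t_start + pump_min + sum(pauses$duration)
  if (t_end <= t_start) t_end <- t_start + dt / 10

  cell_truth(
    cell_length = L, cell_width = p$cell_width, plane_frac = plane,
    n_genomes = n, genome_size = p$genome_size,
    init_frac_small = init, final_frac_small = final,
    v_true = v, t_start = t_start, t_end = t_end, t_close = t_close,
    pauses = pauses, sytox_retention = p$sytox_retention,
    optics = optics, constriction_duration = p$constriction_duration
  )
}

#' @export
print.cell_truth <- function(x, ...) {
  cat("<cell_truth>\n")
  cat(sprintf("  L = %.2f um, W = %.2f um, plane at %.2f L\n",
              x$cell_length, x$cell_width, x$plane_frac))
  cat(sprintf("  %d genomes of %.1f Mb; DNA fraction %.3f -> %.3f\n",
              x$n_genomes, x$genome_size,
              x$init_frac_small, x$final_frac_small))
  cat(sprintf("  v = %.0f bp/s; pump %.1f -> %.1f min; closure %.1f min\n",
              x$v_true, x$t_start, x$t_end, x$t_close))
  if (nrow(x$pauses)) {
    cat(sprintf("  %d pause(s), total %.1f min\n",
                nrow(x$pauses), sum(x$pauses$duration)))
  }
  if (x$truncated) cat("  [event truncated by movie end]\n")
  invisible(x)
}
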