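GENOME_MB <- 4.6  # one fully replicated E. coli chromosome, Mb

#' Normalized intensity
#'
#' The fraction (in percent) of total nucleoid-label fluorescence on the
#' smaller-daughter side of the division plane: `100 * I1 / (I1 + I2)`.
#'
#' @param I1 Integrated intensity on the smaller-daughter side.
#' @param I2 Integrated intensity on the larger side.
#' @return Percent in [0, 100]; `NA_real_` where both integrals are zero.
#' @export
normalized_intensity <- function(I1, I2) {
  if (any(c(I1, I2) < 0, na.rm = TRUE)) {
    stop_user("intensities must be non-negative")
  }
  tot <- I1 + I2
  ifelse(tot > 0, 100 * I1 / tot, NA_real_)
}

#' Per-frame intensity partition for one label
#'
#' For each frame, extracts the background-subtracted axial profile of the
#' label and splits its integral at the constriction position into `I1`
#' (smaller-daughter side, position 0 side of the axis) and `I2`.
#'
#' Diffraction blur mixes mass across the division plane, which biases a
#' plain split toward 50% when the two compartments differ in density. The
#' default `split = "apportion"` therefore assigns the mass inside a
#' `+- zone_um` window around the plane to the two sides in proportion to
#' the flanking far-field densities (unbiased when the axial density is
#' locally uniform on each side); `split = "plain"` divides exactly at the
#' plane, fractionally weighting the straddling sample.
#'
#' Frames with a missing constriction position inherit the nearest
#' available one and are flagged in the `gap` column.
#'
#' @param movie A [cell_movie()].
#' @param label Channel name of the nucleoid label.
#' @param constriction_track Numeric vector of per-frame constriction
#'   positions (um along the axis; NAs allowed).
#' @param axis Oriented [long_axis()] (position 0 at the smaller
#'   compartment pole). Computed from the mask when NULL.
#' @param width_px Profile averaging width.
#' @param split `"apportion"` (default) or `"plain"`, see Details.
#' @param zone_um Half-width of the plane zone for `"apportion"`; the
#'   default is the optical resolution limit.
#' @return Data frame of class `intensity_series` with columns `frame`,
#'   `time_min`, `x_c`, `I1`, `I2`, `NI`, `gap`.
#' @export
intensity_series <- function(movie, label, constriction_track,
                             axis = NULL, width_px = 9,
                             split = c("apportion", "plain"),
                             zone_um = 0.25) {
  split <- match.arg(split)
  if (!label %in% names(movie$channels)) {
    stop_user("label channel '", label, "' not present")
  }
  if (is.null(axis)) axis <- long_axis(movie$cell_mask, movie$pixel_size)
  nt <- movie$n_frames
  if (length(constriction_track) != nt) {
    stop_user("constriction track length must equal frame count")
  }
  xc <- fill_track(constriction_track)
  gap <- !is.finite(constriction_track)
  if (all(is.na(xc))) stop_user("no constriction position in any frame")

  arr <- movie$channels[[label]]
  I1 <- I2 <- numeric(nt)
  for (t in seq_len(nt)) {
    pr <- subtract_background(
      line_profile(arr[, , t], axis, movie$pixel_size, width_px))
    pos <- pr$positions
    v <- pr$values
    if (split == "plain") {
      w <- clamp((xc[t] - pos) / movie$pixel_size + 0.5, 0, 1)
      I1[t] <- sum(v * w)
      I2[t] <- sum(v * (1 - w))
    } else {
      zone <- abs(pos - xc[t]) <= zone_um
      lflank <- pos < xc[t] - zone_um & pos >= xc[t] - 3 * zone_um
      rflank <- pos > xc[t] + zone_um & pos <= xc[t] + 3 * zone_um
      rho_l <- if (any(lflank)) mean(v[lflank]) else 0
      rho_r <- if (any(rflank)) mean(v[rflank]) else 0
      share <- if (rho_l + rho_r > 0) rho_l / (rho_l + rho_r) else 0.5
      I1[t] <- sum(v[pos < xc[t] - zone_um]) + share * sum(v[zone])
      I2[t] <- sum(v[pos > xc[t] + zone_um]) + (1 - share) * sum(v[zone])
    }
  }
  structure(data.frame(
    frame = seq_len(nt),
    time_min = movie$times,
    x_c = xc,
    I1 = I1,
    I2 = I2,
    NI = normalized_intensity(I1, I2),
    gap = gap
  ), class = c("intensity_series", "data.frame"),
  label = label, frame_interval = movie$frame_interval)
}

# Fill NAs in a track with the nearest finite value (forward then backward).
fill_track <- function(x) {
  ok <- which(is.finite(x))
  if (!length(ok)) return(x)
  idx <- findInterval(seq_along(x), ok)
  filled <- x[ok[pmax(idx, 1L)]]
  # entries before the first finite value take that first value
  filled[idx == 0L] <- x[ok[1L]]
  filled
}

#' Detect translocation start, end, pauses, and reversals
#'
#' Threshold-on-derivative detector: the noise level `sigma` is the
#' standard deviation of the normalized intensity over the first
#' `baseline_frames` frames; after 3-frame median smoothing, the event
#' starts at the first frame opening two consecutive steps with
#' `|dNI| > k_sigma * sigma` and ends after the last such pair. Pauses are
#' maximal runs of two or more intra-event steps with `|dNI| <= sigma`;
#' reversals are runs of two or more intra-event steps against the
#' dominant direction accumulating more than `reversal_k * sigma`.
#'
#' Detected endpoints sit on the frame grid and straddle the true event
#' (the boundary steps are only partially filled with pumping), so
#' subframe-refined `t_start_refined` / `t_end_refined` are also returned,
#' obtained by scaling each boundary step's size against the interior step
#' size to estimate its filled fraction; [quantify()] and
#' [timing_relative()] use the refined times.
#'
#' @param series An [intensity_series()].
#' @param baseline_frames Frames used to estimate sigma (>= 3).
#' @param k_sigma Start/end threshold in units of sigma.
#' @param pause_k Pause threshold in units of sigma.
#' @param reversal_k Cumulative reversal threshold in units of sigma.
#' @return List of class `translocation_events`: `t_start`, `t_end` (frame
#'   grid, min), `t_start_refined`, `t_end_refined`, `pauses` (data frame
#'   onset/duration), `pause_time` (min), `reversals`, `direction_sign`,
#'   `sigma`, and frame indices `i_start`, `i_end`. All-NA with
#'   `direction_sign = 0` when no event is found.
#' @export
detect_events <- function(series, baseline_frames = 5, k_sigma = 2,
                          pause_k = 1, reversal_k = 4) {
  ni <- series$NI
  times <- series$time_min
  n <- length(ni)
  if (baseline_frames < 3) stop_user("need at least 3 baseline frames")
  if (n < baseline_frames + 3) stop_user("series too short")
  dt <- times[2] - times[1]

  y <- stats::runmed(ni, 3)
  d <- diff(y)
  # sigma is the frame-to-frame noise of NI (both thresholds compare
  # steps, so the step scale is the relevant one), estimated from the
  # baseline in two passes: if the detected event starts after the
  # declared baseline, re-estimate from the whole pre-event segment (a
  # handful of baseline diffs is too variable to set thresholds reliably).
  step_sd <- function(k) max(stats::sd(diff(ni[seq_len(k)])), 1e-9)
  sigma <- step_sd(baseline_frames)
  qual <- integer(0)
  for (pass in 1:2) {
    big <- abs(d) > k_sigma * sigma
    qual <- which(big[-length(big)] & big[-1])
    if (!length(qual)) break
    pre <- min(qual)
    if (pass == 1 && pre > baseline_frames + 1L) {
      sigma <- step_sd(pre - 1L)
    } else {
      break
    }
  }

  null_events <- list(
    t_start = NA_real_, t_end = NA_real_,
    t_start_refined = NA_real_, t_end_refined = NA_real_,
    pauses = data.frame(onset = numeric(0), duration = numeric(0)),
    pause_time = 0, reversals = 0L, direction_sign = 0L,
    sigma = sigma, i_start = NA_integer_, i_end = NA_integer_
  )
  class(null_events) <- "translocation_events"
  if (!length(qual)) return(null_events)

  i0 <- min(qual)            # first step of the event
  i1 <- max(qual) + 1L       # last step of the event
  t_start <- times[i0]
  t_end <- times[i1 + 1L]
  dir_sign <- sign(y[i1 + 1L] - y[i0])

  # Boundary fill fractions: the first and last steps of the detected
  # window cover the true event only partially; their size relative to the
  # interior (full) steps estimates the covered fraction, refining the
  # endpoints to subframe precision. Two-step events carry no interior
  # reference and are taken as fully filled.
  interior <- d[setdiff(seq.int(i0, i1), c(i0, i1))]
  interior <- interior[abs(interior) > k_sigma * sigma]
  ref_step <- if (length(interior)) {
    stats::median(abs(interior))
  } else {
    max(abs(d[c(i0, i1)]))
  }
  fill0 <- clamp(abs(d[i0]) / ref_step, 0, 1)
  fill1 <- clamp(abs(d[i1]) / ref_step, 0, 1)

  steps <- d[i0:i1]
  flat <- abs(steps) <= pause_k * sigma
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 2L
  pauses <- data.frame(
    onset = times[i0 + starts[keep] - 1L],
    duration = r$lengths[keep] * dt
  )

  against <- !flat & sign(steps) == -dir_sign
  rr <- rle(against)
  rends <- cumsum(rr$lengths)
  rstarts <- rends - rr$lengths + 1L
  reversals <- 0L
  for (j in which(rr$values & rr$lengths >= 2L)) {
    if (abs(sum(steps[rstarts[j]:rends[j]])) > reversal_k * sigma) {
      reversals <- reversals + 1L
    }
  }

  t_start_ref <- t_start + (1 - fill0) * dt
  t_end_ref <- t_end - (1 - fill1) * dt
  structure(list(
    t_start = t_start, t_end = t_end,
    t_start_refined = t_start_ref,
    t_end_refined = max(t_end_ref, t_start_ref + dt / 2),
    pauses = pauses,
    pause_time = sum(pauses$duration),
    reversals = reversals,
    direction_sign = as.integer(dir_sign),
    sigma = sigma,
    i_start = i0, i_end = i1 + 1L
  ), class = "translocation_events")
}

#' Total DNA content of a cell
#'
#' `integer_genomes`: two fully replicated chromosomes up to 4.5 um cell
#' length and four above (slow-growth regime, replication completed before
#' division). `length_based`: the fixed-cell calibration law
#' `0.92 * (L - 0.53)` genome units.
#'
#' @param cell_length um.
#' @param mode `"integer_genomes"` or `"length_based"`.
#' @param law Numeric `c(slope, intercept)` for the length-based mode.
#' @param threshold Length threshold for the integer mode, um.
#' @return DNA amount in genome units.
#' @export
total_dna <- function(cell_length,
                      mode = c("integer_genomes", "length_based"),
                      law = c(0.92, 0.53), threshold = 4.5) {
  mode <- match.arg(mode)
  if (cell_length <= 0) stop_user("cell_length must be positive")
  if (mode == "integer_genomes") {
    if (cell_length <= threshold) 2 else 4
  } else {
    if (cell_length <= law[2]) {
      stop_user("length-based DNA estimate undefined for L <= ", law[2],
                " um")
    }
    law[1] * (cell_length - law[2])
  }
}

#' Quantify a detected translocation event
#'
#' Converts the normalized-intensity change between the detected endpoints
#' into DNA amount (genome units, Mb, bp) and pumping speed. The speed
#' divides the translocated base pairs by the pause-excluded active
#' duration between the refined endpoints; a pause-included speed is also
#' reported for comparison.
#'
#' @param series The [intensity_series()] the events were detected on.
#' @param events A [detect_events()] result.
#' @param total_dna_units Total DNA in the cell, genome units
#'   (see [total_dna()]).
#' @param genome_size_mb Mb per genome unit.
#' @return List of class `translocation_result` with fields `t_start`,
#'   `t_end` (refined, min), `t_start_frame`, `t_end_frame`, `pauses`,
#'   `reversals`, `delta_NI` (percent), `total_dna` (genome units),
#'   `amount_genome`, `amount_mb`, `amount_bp`, `duration_s`,
#'   `active_duration_s`, `speed_bps`, `speed_incl_pauses_bps`,
#'   `direction` (one of `"into_smaller"`, `"out_of_smaller"`, `"none"`).
#' @export
quantify <- function(series, events, total_dna_units,
                     genome_size_mb = GENOME_MB) {
  empty <- structure(list(
    t_start = NA_real_, t_end = NA_real_,
    t_start_frame = NA_real_, t_end_frame = NA_real_,
    pauses = events$pauses, pause_time = events$pause_time,
    reversals = events$reversals,
    delta_NI = NA_real_, total_dna = total_dna_units,
    amount_genome = NA_real_, amount_mb = NA_real_, amount_bp = NA_real_,
    duration_s = NA_real_, active_duration_s = NA_real_,
    speed_bps = NA_real_, speed_incl_pauses_bps = NA_real_,
    sigma = events$sigma, direction = "none"
  ), class = "translocation_result")
  if (!is.finite(events$t_start)) return(empty)

  ni <- series$NI
  delta <- ni[events$i_end] - ni[events$i_start]
  amount_genome <- abs(delta) / 100 * total_dna_units
  amount_bp <- amount_genome * genome_size_mb * 1e6
  duration_s <- (events$t_end_refined - events$t_start_refined) * 60
  active_s <- duration_s - events$pause_time * 60
  speed <- if (active_s > 0) amount_bp / active_s else NA_real_
  speed_incl <- if (duration_s > 0) amount_bp / duration_s else NA_real_
  direction <- if (delta > 0) {
    "into_smaller"
  } else if (delta < 0) {
    "out_of_smaller"
  } else {
    "none"
  }
  structure(list(
    t_start = events$t_start_refined, t_end = events$t_end_refined,
    t_start_frame = events$t_start, t_end_frame = events$t_end,
    pauses = events$pauses, pause_time = events$pause_time,
    reversals = events$reversals,
    delta_NI = delta, total_dna = total_dna_units,
    amount_genome = amount_genome, amount_mb = amount_genome * genome_size_mb,
    amount_bp = amount_bp,
    duration_s = duration_s, active_duration_s = active_s,
    speed_bps = speed, speed_incl_pauses_bps = speed_incl,
    sigma = events$sigma, direction = direction
  ), class = "translocation_result")
}

#' @export
print.translocation_result <- function(x, ...) {
  cat("<translocation_result>\n")
  if (x$direction == "none" && !is.finite(x$t_start)) {
    cat("  no event detected\n")
    return(invisible(x))
  }
  cat(sprintf("  %.1f -> %.1f min; dNI %.1f%%; %s\n",
              x$t_start, x$t_end, x$delta_NI, x$direction))
  cat(sprintf("  amount %.2g genome units (%.2g Mb); speed %.0f bp/s\n",
              x$amount_genome, x$amount_mb, x$speed_bps))
  if (nrow(x$pauses)) {
    cat(sprintf("  %d pause(s), %.0f min total\n",
                nrow(x$pauses), x$pause_time))
  }
  invisible(x)
}
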