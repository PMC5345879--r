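# Normalized intensity, event detection, DNA amounts and speeds.

test_that("normalized intensity is the percent split of the total", {
  expect_equal(normalized_intensity(5, 5), 50)
  expect_equal(normalized_intensity(0, 7), 0)
  expect_equal(normalized_intensity(0.15, 0.85), 15)
  expect_true(is.na(normalized_intensity(0, 0)))
  expect_error(normalized_intensity(-1, 2), "non-negative")
})

test_that("intensity series tracks the generator truth", {
  op <- quiet_optics()
  tru <- simple_truth(op, init_frac_small = 0.35, final_frac_small = 0,
                      v_true = 1500)
  trace <- simulate_trace(tru, op)
  mv <- render_movie(tru, trace, op, seed = 3,
                     channels = c("phase", "dapi"))
  an <- analyze_movie(mv, fast_config(register = FALSE))
  s <- an$series$dapi
  expect_identical(nrow(s), mv$n_frames)
  # conserved label: NI follows frac_small within ~1.5 NI points
  # (symmetric PSF leakage across the plane biases slightly toward 50)
  expect_lt(max(abs(s$NI - 100 * trace$frac_small_dapi)), 1.5)
  # total intensity conserved to < 0.1% noise-free
  tot <- s$I1 + s$I2
  expect_lt(diff(range(tot)) / mean(tot), 1e-3)
})

test_that("a symmetric cell with a midcell plane reads 50 percent", {
  op <- quiet_optics()
  tru <- simple_truth(op, plane_frac = 0.5, init_frac_small = 0.5,
                      final_frac_small = 0.5, v_true = 1e-9, t_start = 40,
                      t_end = 80)
  mv <- render_movie(tru, simulate_trace(tru, op), op, seed = 1,
                     channels = c("phase", "dapi"))
  an <- analyze_movie(mv, fast_config(register = FALSE))
  expect_true(all(abs(an$series$dapi$NI - 50) < 0.6))
})

test_that("total intensity is conserved within 3% under shot noise", {
  sim <- simulate_division(31, channels = c("phase", "dapi"))
  an <- analyze_movie(sim$movie, fast_config())
  tot <- an$series$dapi$I1 + an$series$dapi$I2
  expect_lt(diff(range(tot)) / mean(tot), 0.03)
})

test_that("detect_events reads ramps, pauses, and empty series correctly", {
  # noise-free ramp frames 5 -> 15: t_start frame 5, t_end frame 15
  ni <- c(rep(20, 4), seq(20, 50, by = 3), rep(50, 6))
  s <- series_from_ni(ni)
  ev <- detect_events(s)
  expect_equal(ev$t_start, s$time_min[5])
  expect_equal(ev$t_end, s$time_min[15])
  expect_identical(nrow(ev$pauses), 0L)
  expect_identical(ev$reversals, 0L)
  expect_identical(ev$direction_sign, 1L)

  # 2-frame flat insert -> exactly one pause of 8 minutes
  nip <- c(rep(20, 5), 23, 26, 29, 29, 29, 32, 35, 38, rep(38, 5))
  evp <- detect_events(series_from_ni(nip))
  expect_identical(nrow(evp$pauses), 1L)
  expect_equal(evp$pauses$duration, 8)
  expect_equal(evp$pause_time, 8)

  # featureless series -> null result, direction none
  ev0 <- detect_events(series_from_ni(rep(30, 20)))
  expect_true(is.na(ev0$t_start))
  expect_identical(ev0$direction_sign, 0L)
  expect_error(detect_events(series_from_ni(rep(1, 4))), "too short")
})

test_that("the detector never hallucinates reversals on monotone traces", {
  op <- optics_model()
  count <- 0L
  for (seed in 1:200) {
    tru <- make_cell_truth(seed = seed, optics = op)
    trace <- suppressWarnings(simulate_trace(tru, op))
    ni <- 100 * trace$frac_small_dapi
    ev <- detect_events(series_from_ni(ni))
    count <- count + ev$reversals
  }
  expect_identical(count, 0L)
})

test_that("total DNA follows the threshold rule and the length law", {
  expect_equal(total_dna(4.0, "integer_genomes"), 2)
  expect_equal(total_dna(5.0, "integer_genomes"), 4)
  expect_equal(total_dna(2.7, "length_based"), 0.92 * (2.7 - 0.53))
  expect_error(total_dna(0.5, "length_based"), "undefined")
  expect_error(total_dna(-1), "positive")
})

test_that("quantify converts intensity change to amount and speed", {
  # arithmetic oracle: dNI 25, 2 genomes, 20 min, no pauses -> 1917 bp/s
  s <- series_from_ni(c(15, 20, 25, 30, 35, 40))
  ev <- list(t_start = 0, t_end = 20, t_start_refined = 0,
             t_end_refined = 20,
             pauses = data.frame(onset = numeric(0), duration = numeric(0)),
             pause_time = 0, reversals = 0L, direction_sign = 1L,
             sigma = 0.1, i_start = 1L, i_end = 6L)
  class(ev) <- "translocation_events"
  res <- quantify(s, ev, total_dna_units = 2)
  expect_equal(res$delta_NI, 25)
  expect_equal(res$amount_mb, 2.3)
  expect_equal(res$speed_bps, 0.25 * 2 * 4.6e6 / 1200, tolerance = 1e-9)
  expect_identical(res$direction, "into_smaller")

  # 0.8 genome units = 3.68 Mb (3.7 at 2 s.f.)
  expect_equal(genome_units_to_mb(0.8), 3.68)
  expect_equal(signif(genome_units_to_mb(0.8), 2), 3.7)

  # no event -> all-null result with direction none
  res0 <- quantify(s, detect_events(series_from_ni(rep(30, 20))), 2)
  expect_identical(res0$direction, "none")
  expect_true(is.na(res0$speed_bps))
})

test_that("pipeline speed recovery meets its error budget", {
  # noise-free single-cell movie: within 5% of v_true
  op0 <- quiet_optics()
  tru <- simple_truth(op0, v_true = 1500, t_start = 41.3)
  mv <- render_movie(tru, simulate_trace(tru, op0), op0, seed = 7,
                     channels = c("phase", "dapi"))
  an <- analyze_movie(mv, fast_config(register = FALSE))
  expect_lt(abs(an$result$speed_bps / 1500 - 1), 0.05)

  # default shot noise, clean mid-range scenarios: within 15%
  op <- optics_model()
  for (seed in 1:3) {
    tru <- simple_truth(op, v_true = 900 + 400 * seed,
                        t_start = 38 + seed, cell_length = 5.5,
                        n_genomes = 4, init_frac_small = 0.4)
    mv <- suppressWarnings(
      render_movie(tru, simulate_trace(tru, op), op, seed = seed,
                   channels = c("phase", "dapi")))
    an <- analyze_movie(mv, fast_config())
    expect_lt(abs(an$result$speed_bps / tru$v_true - 1), 0.15)
  }
})

test_that("HupA normalized intensity freezes at septal closure", {
  op <- optics_model()
  tru <- simple_truth(op, v_true = 1200, t_start = 28, t_close = 52,
                      init_frac_small = 0.4)
  mv <- render_movie(tru, simulate_trace(tru, op), op, seed = 13,
                     channels = c("phase", "dapi", "hupa"))
  an <- analyze_movie(mv, default_config(ring = FALSE,
                                         labels = c("dapi", "hupa")))
  hupa <- an$series$hupa
  post <- hupa$time_min > tru$t_close
  ref <- hupa$NI[which(post)[1]]
  sigma <- an$events$sigma
  expect_true(all(abs(hupa$NI[post] - ref) < 2 * max(sigma, 0.3)))
  # while DAPI keeps moving after closure
  dapi <- an$series$dapi
  expect_gt(abs(dapi$NI[mv$n_frames] - dapi$NI[which(post)[1]]), 2)
})
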