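# Generator: ground truths, traces, rendering, fixed-cell datasets.

test_that("random truths satisfy their invariants across seeds", {
  for (seed in 1:40) {
    tr <- make_cell_truth(seed = seed)
    expect_s3_class(tr, "cell_truth")
    expect_gt(tr$plane_frac, 0)
    expect_lte(tr$plane_frac, 0.5)
    k <- tr$final_frac_small * tr$n_genomes
    expect_equal(k, round(k))
    expect_lt(tr$t_start, tr$t_end)
    expect_true(all(diff(tr$septum_diameter) <= 1e-9))
    if (nrow(tr$pauses)) {
      expect_true(all(tr$pauses$onset >= tr$t_start))
      expect_true(all(tr$pauses$onset + tr$pauses$duration <=
                        tr$t_end + 1e-9))
    }
    expect_true(tr$n_genomes %in% c(2L, 4L))
  }
})

test_that("population distributions are honoured", {
  # zero-variance speed draw pins v_true at the mean
  p0 <- default_population(v_sd = 0)
  expect_equal(make_cell_truth(p0, seed = 3)$v_true, 1700)
  # chromosome number follows the 4.5 um threshold
  long <- default_population(length_range = c(5, 5))
  expect_identical(make_cell_truth(long, seed = 1)$n_genomes, 4L)
  short <- default_population(length_range = c(4, 4))
  expect_identical(make_cell_truth(short, seed = 1)$n_genomes, 2L)
  # invalid parameters are rejected
  expect_error(default_population(pause_prob = 1.5), "probabilities")
  expect_error(default_population(v_mean = -10), "positive")
})

test_that("200-truth sample mean speed is consistent with the population", {
  v <- vapply(1:200, function(s) make_cell_truth(seed = s)$v_true, 0)
  se <- 800 / sqrt(length(v))
  # truncation at 200 bp/s shifts the mean up by ~57 bp/s, well inside 3 SE
  expect_lt(abs(mean(v) - 1700), 3 * se)
})

test_that("generation is deterministic under a fixed seed", {
  op <- optics_model(n_frames = 8)
  a <- simulate_division(11, optics = op, channels = c("phase", "dapi"))
  b <- simulate_division(11, optics = op, channels = c("phase", "dapi"))
  expect_identical(a$truth, b$truth)
  expect_identical(a$trace, b$trace)
  expect_identical(a$movie$channels, b$movie$channels)
})

test_that("trace follows the pump integral", {
  op <- optics_model()
  # (effectively) no pump: constant fractions
  t0 <- simple_truth(op, v_true = 1e-9, init_frac_small = 0.35,
                     final_frac_small = 0.5, t_end = 90)
  expect_equal(simulate_trace(t0, op)$frac_small_dapi,
               rep(0.35, op$n_frames), tolerance = 1e-9)
  # hand integral: 1917 bp/s, 2 genomes, 20 min -> delta 0.25
  t1 <- simple_truth(op, v_true = 1917, init_frac_small = 0.25,
                     final_frac_small = 0.5, t_start = 20, t_close = 48)
  expect_equal(t1$t_end - t1$t_start, 0.25 * 2 * 4.6e6 / 1917 / 60,
               tolerance = 1e-12)
  tr1 <- simulate_trace(t1, op)
  expect_equal(max(tr1$frac_small_dapi) - min(tr1$frac_small_dapi), 0.25,
               tolerance = 1e-3)
  # monotone, within [0,1], direction = sign of final - init
  expect_true(all(diff(tr1$frac_small_dapi) >= 0))
  expect_true(all(tr1$frac_small_dapi >= 0 & tr1$frac_small_dapi <= 1))
})

test_that("label-specific retention rules hold exactly", {
  op <- optics_model()
  tr <- simple_truth(op, sytox_retention = 1)
  trace <- simulate_trace(tr, op)
  expect_equal(trace$frac_small_sytox, trace$frac_small_dapi)
  # HupA equals DAPI before closure, frozen at the closure value after
  pre <- trace$time_min < tr$t_close
  expect_equal(trace$frac_small_hupa[pre], trace$frac_small_dapi[pre])
  post <- trace$frac_small_hupa[!pre]
  expect_true(all(post == post[1]))
  # partial retention strips label from the moved DNA
  tr2 <- simple_truth(op, sytox_retention = 0.5)
  trace2 <- simulate_trace(tr2, op)
  n <- nrow(trace2)
  expect_lt(trace2$frac_small_sytox[n], trace2$frac_small_dapi[n] + 1e-12)
})

test_that("rendering conserves label mass and places structures correctly", {
  op <- quiet_optics()
  tru <- simple_truth(op)
  trace <- simulate_trace(tru, op)
  mv <- render_movie(tru, trace, op, seed = 5,
                     channels = c("phase", "dapi", "zipa"))
  # noise-free: integrated DAPI constant over time within 0.1%
  tot <- apply(mv$channels$dapi, 3, sum) -
    op$background_level * prod(dim(mv$cell_mask))
  expect_lt(diff(range(tot)) / mean(tot), 1e-3)
  # ring band absent after closure, present before
  ring_mass <- apply(mv$channels$zipa, 3, sum) -
    op$background_level * prod(dim(mv$cell_mask))
  expect_true(all(ring_mass[mv$times < tru$t_close] > 1e3))
  expect_true(all(abs(ring_mass[mv$times >= tru$t_close]) < 1))
  # phase bump sits at the plane (+- 1 px) in a constricted frame
  ax <- long_axis(mv$cell_mask, mv$pixel_size)
  pr <- line_profile(mv$channels$phase[, , op$n_frames], ax, mv$pixel_size)
  xc <- constriction_position(pr)
  x0 <- (ncol(mv$cell_mask) * mv$pixel_size - tru$cell_length) / 2
  true_x <- x0 + tru$plane_frac * tru$cell_length - ax$p0[1]
  expect_lt(abs(xc - true_x), mv$pixel_size)
})

test_that("renderer rejects rasters too small for the cell", {
  op <- optics_model(pixel_size = 2)
  tru <- simple_truth(op)
  expect_error(render_movie(tru, simulate_trace(tru, op), op, seed = 1),
               "raster too small")
})

test_that("fixed-cell dataset matches its generating law", {
  d <- make_fixed_cell_dataset(n_cells = 321, seed = 4)
  expect_identical(nrow(d), 321L)
  # noise-free: every row satisfies DNA = 0.92 (L - 0.53) exactly
  d0 <- make_fixed_cell_dataset(noise_cv = 0, seed = 4)
  dna <- d0$total_intensity / attr(d0, "intensity_scale")
  expect_equal(dna, 0.92 * (d0$cell_length_um - 0.53), tolerance = 1e-12)
  expect_error(make_fixed_cell_dataset(n_cells = 20, seed = 1),
               "at least 50")
  expect_error(make_fixed_cell_dataset(noise_cv = 1, seed = 1), "noise_cv")
  expect_error(make_fixed_cell_dataset(), "seed")
})
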