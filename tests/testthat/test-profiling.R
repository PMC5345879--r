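# Axis extraction, line profiles, background, constriction, modulation.

test_that("long_axis finds the principal axis of rod masks", {
  px <- 0.111
  m <- rod_mask()
  ax <- long_axis(m, px)
  expect_lt(abs(atan2(ax$direction[2], ax$direction[1])) * 180 / pi, 1)
  expect_equal(ax$mask_length_um, 45 * px, tolerance = 0.05)

  # rotated rod: rotate coordinates of a generated rod by 30 degrees
  th <- 30 * pi / 180
  n <- 101
  mm <- matrix(FALSE, n, n)
  ctr <- (n + 1) / 2
  for (t in seq(-28, 28, by = 0.25)) {
    for (o in seq(-3.8, 3.8, by = 0.25)) {
      x <- round(ctr + t * cos(th) - o * sin(th))
      y <- round(ctr + t * sin(th) + o * cos(th))
      mm[y, x] <- TRUE
    }
  }
  ax2 <- long_axis(mm, px)
  ang <- atan2(ax2$direction[2], ax2$direction[1]) * 180 / pi
  expect_lt(abs(ang - 30), 1)
})

test_that("degenerate masks are rejected", {
  sq <- matrix(FALSE, 30, 30)
  sq[10:20, 10:20] <- TRUE
  expect_error(long_axis(sq, 0.1), "degenerate")
  expect_error(long_axis(matrix(FALSE, 5, 5), 0.1), "empty")
  two <- matrix(FALSE, 20, 40)
  two[9:11, 3:12] <- TRUE
  two[9:11, 25:35] <- TRUE
  expect_error(long_axis(two, 0.1), "multiple connected")
})

test_that("line_profile averages a perpendicular band and is linear", {
  px <- 0.111
  m <- rod_mask()
  ax <- long_axis(m, px)
  # uniform image -> constant profile
  u <- matrix(3.5, nrow(m), ncol(m))
  pu <- line_profile(u, ax, px)
  expect_true(all(abs(pu$values - 3.5) < 1e-9))
  # linearity: profile(aX + bY) = a profile(X) + b profile(Y)
  set.seed(1)
  X <- matrix(rnorm(length(m), 10), nrow(m))
  Y <- matrix(rnorm(length(m), 5), nrow(m))
  pX <- line_profile(X, ax, px)$values
  pY <- line_profile(Y, ax, px)$values
  pZ <- line_profile(2 * X + 3 * Y, ax, px)$values
  expect_equal(pZ, 2 * pX + 3 * pY, tolerance = 1e-10)
  expect_error(line_profile(u, ax, px, width_px = 8), "odd")
})

test_that("width_px = 1 along a pixel row reproduces the raw row", {
  px <- 0.111
  ny <- 21
  img <- matrix(rep(1:41, each = ny), ny, 41)
  # horizontal axis through a pixel-center row
  ax <- structure(list(
    p0 = c(2 * px, 10.5 * px), p1 = c(38 * px, 10.5 * px),
    direction = c(1, 0), mask_extent = c(0, 36 * px)
  ), class = "cell_axis")
  pr <- line_profile(img, ax, px, width_px = 1)
  expect_equal(pr$values, seq(2.5, 38.5, by = 1), tolerance = 1e-9)
})

test_that("background subtraction recovers offset-free integrals", {
  px <- 0.111
  m <- rod_mask()
  ax <- long_axis(m, px)
  sig <- matrix(0, nrow(m), ncol(m))
  sig[10:18, 20:50] <- 40
  p_clean <- line_profile(sig, ax, px)
  p_off <- line_profile(sig + 100, ax, px)
  sub <- subtract_background(p_off)
  expect_true(sub$background_subtracted)
  expect_equal(sub$background, 100, tolerance = 1e-6)
  expect_equal(sum(sub$values), sum(p_clean$values), tolerance = 0.01)
  # all-background profile integrates to ~0, and subtraction is idempotent
  pb <- subtract_background(line_profile(matrix(100, nrow(m), ncol(m)),
                                         ax, px))
  expect_lt(sum(pb$values), 1e-6)
  twice <- subtract_background(sub)
  expect_equal(twice$values, sub$values, tolerance = 1e-9)
})

test_that("constriction localization is subpixel on synthetic bumps", {
  px <- 0.111
  positions <- seq(0, 6, by = px)
  mk <- function(center) {
    vals <- ifelse(positions > 0.5 & positions < 5.5, 150, 600)
    vals <- vals + 300 * exp(-(positions - center)^2 / (2 * 0.15^2))
    structure(list(positions = positions, values = vals,
                   mask_extent = c(0.5, 5.5), width_px = 9L,
                   pixel_size = px, background_subtracted = FALSE,
                   background = NA_real_), class = "line_profile")
  }
  expect_equal(constriction_position(mk(3.0)), 3.0, tolerance = 0.05)
  # flat interior -> sentinel
  flat <- mk(3.0)
  flat$values <- ifelse(positions > 0.5 & positions < 5.5, 150, 600)
  expect_true(is.na(constriction_position(flat)))
  # two bumps: prior selects the nearer, otherwise the most prominent wins
  two <- mk(2.0)
  two$values <- two$values + 250 * exp(-(positions - 4)^2 / (2 * 0.15^2))
  expect_equal(constriction_position(two, prior_position = 4), 4,
               tolerance = 0.06)
  expect_equal(constriction_position(two), 2, tolerance = 0.06)
})

test_that("constriction error stays below 0.5 px over 100 random planes", {
  op <- quiet_optics()
  errs <- vapply(1:100, function(i) {
    set.seed(i)
    pf <- stats::runif(1, 0.15, 0.48)
    L <- stats::runif(1, 3, 7)
    tru <- simple_truth(op, cell_length = L, plane_frac = pf,
                        init_frac_small = pf, final_frac_small = 0.5,
                        v_true = 1000, t_start = 10, t_close = 48)
    mv <- render_movie(tru, simulate_trace(tru, op), op, seed = i,
                       channels = "phase")
    ax <- long_axis(mv$cell_mask, mv$pixel_size)
    pr <- line_profile(mv$channels$phase[, , op$n_frames], ax,
                       mv$pixel_size)
    x0 <- (ncol(mv$cell_mask) * mv$pixel_size - L) / 2
    abs(constriction_position(pr) - (x0 + pf * L - ax$p0[1])) /
      mv$pixel_size
  }, 0)
  expect_lt(max(errs), 0.5)
})

test_that("phase modulation rises from 0 to 1 and ignores intensity scale", {
  op <- quiet_optics()
  tru <- simple_truth(op)
  mv <- render_movie(tru, simulate_trace(tru, op), op, seed = 2,
                     channels = "phase")
  ax <- long_axis(mv$cell_mask, mv$pixel_size)
  pr_first <- line_profile(mv$channels$phase[, , 1], ax, mv$pixel_size)
  pr_last <- line_profile(mv$channels$phase[, , op$n_frames], ax,
                          mv$pixel_size)
  xc <- constriction_position(pr_last)
  # unconstricted frame: modulation ~ 0; fully closed septum: ~ 1
  expect_lt(phase_modulation(pr_first, xc), 0.1)
  expect_gt(phase_modulation(pr_last, xc), 0.9)
  # affine intensity invariance
  pr_scaled <- pr_last
  pr_scaled$values <- 3.7 * pr_last$values + 55
  expect_equal(phase_modulation(pr_scaled, xc),
               phase_modulation(pr_last, xc), tolerance = 1e-9)
  # monotone (within tolerance) as the rendered septum closes
  mods <- vapply(seq_len(op$n_frames), function(t) {
    phase_modulation(line_profile(mv$channels$phase[, , t], ax,
                                  mv$pixel_size), xc)
  }, 0)
  expect_true(all(diff(mods) > -0.03))
})

test_that("kymographs stack per-frame profiles column-wise", {
  op <- optics_model(n_frames = 6)
  sim <- simulate_division(9, optics = op, channels = c("phase", "dapi"))
  ky <- kymograph(sim$movie, "dapi")
  expect_identical(ncol(ky), 6L)
  expect_identical(length(attr(ky, "times")), 6L)
  # static image repeated -> identical columns
  mv2 <- sim$movie
  for (t in 2:6) mv2$channels$dapi[, , t] <- mv2$channels$dapi[, , 1]
  ky2 <- kymograph(mv2, "dapi")
  expect_equal(ky2[, 3], ky2[, 1], tolerance = 1e-12)
  expect_error(kymograph(sim$movie, "nope"), "not present")
})
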