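# Shared numeric helpers for the imaging and analysis code. Everything here
# operates on plain matrices (row = y, column = x); pixel centers sit at
# integer 1-based matrix coordinates, and physical positions are in microns.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_user <- function(...) {
  stop(errorCondition(paste0(...), class = c("septrack_user_error", "error")))
}

gauss_kernel <- function(sigma_px) {
  r <- max(1L, as.integer(ceiling(4 * sigma_px)))
  k <- stats::dnorm(seq.int(-r, r), sd = sigma_px)
  k / sum(k)
}

# Dense banded matrix performing zero-padded 1D convolution on length-n
# signals. Images here are tens of pixels on a side, so the O(n^2) product
# is cheaper and simpler than FFT bookkeeping.
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  idx <- outer(seq_len(n), seq_len(n), function(i, j) i - j + r + 1L)
  m <- matrix(0, n, n)
  ok <- idx >= 1L & idx <= length(kernel)
  m[ok] <- kernel[idx[ok]]
  m
}

# Separable Gaussian blur. edge = "zero" conserves interior mass exactly
# (used for fluorescence, where signal sits >= 4 sigma from the border);
# edge = "replicate" avoids darkening at the raster border (used for phase
# contrast, whose background is bright everywhere).
blur_gaussian <- function(img, sigma_px, edge = c("zero", "replicate")) {
  edge <- match.arg(edge)
  if (sigma_px <= 0) return(img)
  k <- gauss_kernel(sigma_px)
  r <- (length(k) - 1L) %/% 2L
  if (edge == "replicate") {
    img <- img[c(rep(1L, r), seq_len(nrow(img)), rep(nrow(img), r)),
               c(rep(1L, r), seq_len(ncol(img)), rep(ncol(img), r)),
               drop = FALSE]
  }
  out <- conv_matrix(nrow(img), k) %*% img %*% t(conv_matrix(ncol(img), k))
  if (edge == "replicate") {
    out <- out[(r + 1L):(nrow(out) - r), (r + 1L):(ncol(out) - r),
               drop = FALSE]
  }
  out
}

# Bilinear interpolation at continuous matrix coordinates (x = column,
# y = row, pixel centers at integers). Points outside the raster read 0.
bilinear_sample <- function(img, x, y) {
  ny <- nrow(img)
  nx <- ncol(img)
  x0 <- floor(x)
  y0 <- floor(y)
  fx <- x - x0
  fy <- y - y0
  grab <- function(yy, xx) {
    v <- numeric(length(xx))
    ok <- xx >= 1 & xx <= nx & yy >= 1 & yy <= ny
    v[ok] <- img[cbind(yy[ok], xx[ok])]
    v
  }
  grab(y0, x0) * (1 - fx) * (1 - fy) +
    grab(y0, x0 + 1) * fx * (1 - fy) +
    grab(y0 + 1, x0) * (1 - fx) * fy +
    grab(y0 + 1, x0 + 1) * fx * fy
}

# Subpixel translation via the Fourier shift theorem. Content moves by
# (+dx, +dy) pixels toward larger column/row indices; wrap-around touches
# only the uniform-background margins of our rasters.
shift_image <- function(img, dx, dy) {
  ny <- nrow(img)
  nx <- ncol(img)
  wx <- 0:(nx - 1)
  wx[wx > nx / 2] <- wx[wx > nx / 2] - nx
  wy <- 0:(ny - 1)
  wy[wy > ny / 2] <- wy[wy > ny / 2] - ny
  ph <- exp(-2i * pi * outer(wy * dy / ny, wx * dx / nx, `+`))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / (nx * ny)
}

# Three-point parabolic peak refinement; returns the subpixel offset of the
# extremum around index i, clamped to half a sample.
parabolic_refine <- function(y, i) {
  if (i <= 1L || i >= length(y)) return(0)
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (denom == 0) return(0)
  clamp(0.5 * (y[i - 1L] - y[i + 1L]) / denom, -0.5, 0.5)
}

# 4-connected component labelling by flood fill; masks here are a few
# thousand pixels so a plain stack is fine.
label_components <- function(mask) {
  ny <- nrow(mask)
  nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    stack <- s
    lab[s] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- ((p - 1L) %% ny) + 1L
      j <- ((p - 1L) %/% ny) + 1L
      for (q in c(if (i > 1L) p - 1L, if (i < ny) p + 1L,
                  if (j > 1L) p - ny, if (j < nx) p + ny)) {
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          stack <- c(stack, q)
        }
      }
    }
  }
  lab
}

# Truncated-normal draws by rejection; truncation points in this package sit
# far in the body of the distribution so the loop terminates fast.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) stop_user("negative standard deviation")
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop_user("degenerate truncated normal outside its support")
    }
    return(rep(mean, n))
  }
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}
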