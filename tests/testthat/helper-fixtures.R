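# Shared fixtures: every synthetic object is built in code at test time.

# Noise-free optics for ground-truth geometry checks.
quiet_optics <- function(...) optics_model(gain = 0, ...)

# A fully specified mid-range division truth; override any field.
simple_truth <- function(optics = optics_model(), ...) {
  # length below the 4.5 um threshold so the integer-genome rule agrees
  # with the declared n_genomes
  args <- utils::modifyList(list(
    cell_length = 4.0, plane_frac = 0.33, n_genomes = 2,
    init_frac_small = 0.35, final_frac_small = 0,
    v_true = 1500, t_start = 40, t_end = NULL, t_close = 48,
    optics = optics
  ), list(...))
  if (is.null(args$t_end)) {
    args$t_end <- args$t_start +
      abs(args$final_frac_small - args$init_frac_small) *
        args$n_genomes * 4.6e6 / args$v_true / 60
  }
  do.call(cell_truth, args)
}

# Build an intensity_series-shaped data frame from an NI vector.
series_from_ni <- function(ni, dt = 4) {
  structure(data.frame(
    frame = seq_along(ni),
    time_min = (seq_along(ni) - 1) * dt,
    x_c = 2, I1 = ni, I2 = 100 - ni, NI = ni, gap = FALSE
  ), class = c("intensity_series", "data.frame"),
  label = "dapi", frame_interval = dt)
}

# Analysis configuration used in most pipeline tests (DAPI only, no ring).
fast_config <- function(...) {
  default_config(ring = FALSE, labels = "dapi", ...)
}

# Axis-aligned rod mask for profiling tests.
rod_mask <- function(ny = 27, nx = 63, half_width = 4, len = 45,
                     cy = 14, cx0 = 10) {
  m <- matrix(FALSE, ny, nx)
  m[(cy - half_width):(cy + half_width), cx0:(cx0 + len - 1)] <- TRUE
  m
}
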