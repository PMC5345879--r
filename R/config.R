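#' Default run configuration
#'
#' One nested list drives simulation and analysis: the seed, optics
#' parameters, population parameters, detection thresholds (the k*sigma
#' start/end threshold, the pause threshold, the ring dissociation
#' threshold), the total-DNA mode, and channel roles. The structure
#' round-trips losslessly through [write_config()] / [read_config()].
#'
#' @param ... Named overrides; nested lists are replaced wholesale.
#' @return A list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    schema_version = 1L,
    seed = 1L,
    optics = unclass(optics_model())[
      c("pixel_size", "psf_fwhm", "background_level", "gain",
        "frame_interval", "n_frames", "dna_photons", "ring_photons",
        "phase_background", "phase_interior")],
    population = unclass(default_population()),
    detection = list(
      baseline_frames = 5L,
      k_sigma = 2,
      pause_k = 1,
      reversal_k = 4,
      width_px = 9L,
      prominence_frac = 0.1,
      constriction_mode = "static_median"
    ),
    dissociation = list(threshold = 0.2, baseline_frames = 5L),
    total_dna_mode = "integer_genomes",
    labels = c("dapi", "hupa", "sytox"),
    primary_label = "dapi",
    ring = TRUE,
    ring_channel = "zipa",
    register = TRUE,
    reference_channel = "dapi",
    out_dir = "."
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) {
    stop_user("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(ov)] <- ov
  validate_config(structure(cfg, class = "run_config"))
}

validate_config <- function(cfg) {
  d <- cfg$detection
  if (d$k_sigma <= 0 || d$pause_k <= 0 || d$reversal_k <= 0 ||
      cfg$dissociation$threshold < 0) {
    stop_user("detection thresholds must be positive")
  }
  if (!cfg$total_dna_mode %in% c("integer_genomes", "length_based")) {
    stop_user("total_dna_mode must be integer_genomes or length_based")
  }
  cfg
}

#' Serialize / restore a run configuration
#'
#' @param config A [default_config()] list.
#' @param path JSON file path.
#' @return `path` (writer) or the restored `run_config` (reader).
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  for (nm in names(raw)) {
    if (!nm %in% names(cfg)) {
      stop_user("unknown config field in file: ", nm)
    }
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(raw[[nm]])) {
      utils::modifyList(cfg[[nm]], raw[[nm]])
    } else {
      raw[[nm]]
    }
  }
  validate_config(structure(cfg, class = "run_config"))
}

# Build the typed parameter objects from a config list.
config_optics <- function(cfg) do.call(optics_model, cfg$optics)
config_population <- function(cfg) do.call(default_population, cfg$population)
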