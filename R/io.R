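# Minimal baseline TIFF codec. The pre-installed R stack has no TIFF
# package, so the package carries its own writer/reader for the one layout
# it produces: little-endian, 32-bit IEEE float, one sample per pixel, one
# strip per page, uncompressed, page order = time. The reader supports
# exactly this subset and refuses anything else.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offset = 273L, samples = 277L,
               rows_per_strip = 278L, strip_bytes = 279L,
               sample_format = 339L)

#' Write a numeric stack as a multi-page float TIFF
#'
#' @param arr A matrix `[ny, nx]` or array `[ny, nx, nt]`; each page is one
#'   frame, rows are image rows.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(arr, path) {
  if (is.matrix(arr)) arr <- array(arr, c(dim(arr), 1L))
  if (length(dim(arr)) != 3L) stop_user("write_tiff() expects [ny, nx, nt]")
  ny <- dim(arr)[1]; nx <- dim(arr)[2]; nt <- dim(arr)[3]
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")

  writeChar("II", con, nchars = 2, eos = NULL)
  w2(42L)
  data_bytes <- nx * ny * 4
  ifd_bytes <- 2 + 10 * 12 + 4
  # layout: header (8) | page1 data | page1 IFD | page2 data | ...
  first_ifd <- 8 + data_bytes
  w4(first_ifd)

  entry <- function(tag, type, value) {
    w2(tag); w2(type); w4(1L)
    if (type == 3L) { w2(value); w2(0L) } else w4(value)
  }
  for (t in seq_len(nt)) {
    offset_data <- 8 + (t - 1) * (data_bytes + ifd_bytes)
    writeBin(as.numeric(t(arr[, , t])), con, size = 4, endian = "little")
    w2(10L)
    entry(TIFF_TAGS[["width"]], 4L, nx)
    entry(TIFF_TAGS[["length"]], 4L, ny)
    entry(TIFF_TAGS[["bits"]], 3L, 32L)
    entry(TIFF_TAGS[["compression"]], 3L, 1L)
    entry(TIFF_TAGS[["photometric"]], 3L, 1L)
    entry(TIFF_TAGS[["strip_offset"]], 4L, offset_data)
    entry(TIFF_TAGS[["samples"]], 3L, 1L)
    entry(TIFF_TAGS[["rows_per_strip"]], 4L, ny)
    entry(TIFF_TAGS[["strip_bytes"]], 4L, data_bytes)
    entry(TIFF_TAGS[["sample_format"]], 3L, 3L)
    next_ifd <- if (t < nt) {
      offset_data + 2L * data_bytes + ifd_bytes  # next page's IFD position
    } else {
      0L
    }
    w4(next_ifd)
  }
  invisible(path)
}

#' Read a multi-page float TIFF written by [write_tiff()]
#'
#' @param path File path.
#' @return Array `[ny, nx, nt]`.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  u2 <- function(at) sum(as.integer(raw[at + 0:1]) * c(1, 256))
  u4 <- function(at) sum(as.integer(raw[at + 0:3]) * 256^(0:3))
  if (rawToChar(raw[1:2]) != "II" || u2(3L) != 42L) {
    stop_user("not a little-endian TIFF")
  }
  ifd <- u4(5L)
  pages <- list()
  while (ifd != 0) {
    n_entries <- u2(ifd + 1L)
    tags <- list()
    for (e in seq_len(n_entries)) {
      at <- ifd + 2L + (e - 1L) * 12L
      tag <- u2(at + 1L)
      type <- u2(at + 3L)
      val <- if (type == 3L) u2(at + 9L) else u4(at + 9L)
      tags[[as.character(tag)]] <- val
    }
    need <- function(tag) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) stop_user("TIFF missing tag ", tag)
      v
    }
    if (need(259L) != 1L || need(258L) != 32L ||
        !identical(tags[["339"]], 3)) {
      stop_user("unsupported TIFF layout (expect uncompressed float32)")
    }
    nx <- need(256L); ny <- need(257L)
    off <- need(273L); nb <- need(279L)
    if (nb != nx * ny * 4) stop_user("unsupported TIFF strip layout")
    vals <- readBin(raw[(off + 1L):(off + nb)], "numeric", n = nx * ny,
                    size = 4, endian = "little")
    pages[[length(pages) + 1L]] <- t(matrix(vals, nx, ny))
    ifd <- u4(ifd + 2L + n_entries * 12L + 1L)
  }
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  array(unlist(pages), c(ny, nx, length(pages)))
}

#' Write a movie to disk (channel TIFFs + JSON sidecar + mask)
#'
#' One float TIFF per channel (`<basename>_<channel>.tif`, page order =
#' time), the binary mask as `<basename>_mask.tif`, and a JSON sidecar
#' `<basename>.json` recording pixel size, frame interval, channel names,
#' and any metadata (seed, registration offsets).
#'
#' @param movie A [cell_movie()].
#' @param dir Output directory (created if missing).
#' @param basename File stem.
#' @return The sidecar path, invisibly.
#' @export
write_movie <- function(movie, dir, basename) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (ch in names(movie$channels)) {
    write_tiff(movie$channels[[ch]],
               file.path(dir, sprintf("%s_%s.tif", basename, ch)))
  }
  write_tiff(matrix(as.numeric(movie$cell_mask), nrow(movie$cell_mask)),
             file.path(dir, sprintf("%s_mask.tif", basename)))
  sidecar <- file.path(dir, sprintf("%s.json", basename))
  jsonlite::write_json(list(
    basename = basename,
    pixel_size_um = movie$pixel_size,
    frame_interval_min = movie$frame_interval,
    n_frames = movie$n_frames,
    channels = as.list(names(movie$channels)),
    meta = movie$meta
  ), sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sidecar)
}

#' Read a movie written by [write_movie()]
#'
#' @param sidecar Path to the `<basename>.json` sidecar.
#' @return A [cell_movie()].
#' @export
read_movie <- function(sidecar) {
  info <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dir <- dirname(sidecar)
  chans <- lapply(info$channels, function(ch) {
    read_tiff(file.path(dir, sprintf("%s_%s.tif", info$basename, ch)))
  })
  names(chans) <- unlist(info$channels)
  mask <- read_tiff(file.path(dir,
                              sprintf("%s_mask.tif", info$basename)))[, , 1]
  cell_movie(chans, pixel_size = info$pixel_size_um,
             frame_interval = info$frame_interval_min,
             cell_mask = mask > 0.5,
             meta = if (is.null(info$meta)) list() else info$meta)
}

#' Write / read a ground-truth trace table as CSV
#'
#' @param trace A [simulate_trace()] data frame.
#' @param path CSV path.
#' @return `path` (writer) or the trace data frame (reader).
#' @export
write_true_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_true_trace
#' @export
read_true_trace <- function(path) {
  structure(utils::read.csv(path), class = c("true_trace", "data.frame"))
}
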