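# Interchange formats. No TIFF library exists in the installed R stack, so
# volumes travel as raw little-endian float64 (amplitude block then phase
# block, x-fastest / repeat-slowest) with a JSON sidecar header; 2-D maps
# travel as headerless CSV grids; tables as CSV. Everything round-trips
# bit-exactly through these writers/readers.

#' Write / read a repeated-B-scan volume
#'
#' `write_volume()` stores an `onh_volume` as `data.bin` (raw
#' little-endian float64: the full amplitude array followed by the full
#' phase array, fastest index x, then y, z, repeat) plus a JSON sidecar
#' `header.json` recording dims, repeat count, extent, A-scan rate and
#' seed. `read_volume()` reverses it.
#'
#' @param vol An `onh_volume`.
#' @param dir Directory to write into (created if needed).
#' @return `write_volume()` returns `dir` invisibly; `read_volume()`
#'   returns an `onh_volume`.
#' @export
write_volume <- function(vol, dir) {
  stopifnot(inherits(vol, "onh_volume"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(vol$data)
  header <- list(
    format = "onhperf-volume-v1",
    dims = d[1:3], n_repeats = d[4],
    extent_mm = vol$extent_mm, ascan_rate_hz = vol$ascan_rate_hz,
    seed = vol$seed,
    layout = "float64-le: amplitude block then phase block, x fastest, repeat slowest",
    channels = c("amplitude", "phase")
  )
  jsonlite::write_json(header, file.path(dir, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(dir, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(Mod(vol$data)), con, size = 8, endian = "little")
  writeBin(as.vector(Arg(vol$data)), con, size = 8, endian = "little")
  invisible(dir)
}

#' @rdname write_volume
#' @export
read_volume <- function(dir) {
  hpath <- file.path(dir, "header.json")
  if (!file.exists(hpath)) abort(paste0("missing volume header: ", hpath))
  header <- tryCatch(jsonlite::read_json(hpath, simplifyVector = TRUE),
                     error = function(e) {
                       abort(paste0("corrupt volume header: ", conditionMessage(e)))
                     })
  if (!identical(header$format, "onhperf-volume-v1")) {
    abort("corrupt volume header: unknown format tag")
  }
  d <- as.integer(header$dims); R <- as.integer(header$n_repeats)
  n <- prod(d) * R
  con <- file(file.path(dir, "data.bin"), "rb")
  on.exit(close(con))
  amp <- readBin(con, numeric(), n, size = 8, endian = "little")
  ph <- readBin(con, numeric(), n, size = 8, endian = "little")
  if (length(amp) != n || length(ph) != n) {
    abort("volume data is truncated relative to its header")
  }
  dat <- array(complex(modulus = amp, argument = ph), dim = c(d, R))
  structure(list(data = dat, n_repeats = R,
                 extent_mm = header$extent_mm,
                 ascan_rate_hz = header$ascan_rate_hz,
                 seed = header$seed),
            class = "onh_volume")
}

#' Write / read a 2-D map as a headerless CSV grid
#'
#' @param m Numeric or logical matrix.
#' @param path File path.
#' @return `read_map()` returns a numeric matrix.
#' @export
write_map <- function(m, path) {
  utils::write.table(m * 1, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  as.matrix(utils::read.table(path, sep = ","))
}

#' Serialize a layer model to JSON
#'
#' Surfaces and disc mask are stored as nested arrays; round-trips
#' losslessly for plotting and pipeline hand-off.
#'
#' @param layers An `onh_layer_model`.
#' @param path JSON file path.
#' @return `read_layers()` returns an `onh_layer_model`.
#' @export
write_layers <- function(layers, path) {
  stopifnot(inherits(layers, "onh_layer_model"))
  obj <- list(
    format = "onhperf-layers-v1",
    z_ilm = layers$z_ilm, z_alc = layers$z_alc,
    disc_mask = if (!is.null(layers$disc_mask)) layers$disc_mask * 1L,
    area_onh_px = layers$area_onh_px, area_onh_mm2 = layers$area_onh_mm2,
    nz = layers$nz
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layers
#' @export
read_layers <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "onhperf-layers-v1")) {
    abort("corrupt layer file: unknown format tag")
  }
  structure(list(
    z_ilm = as.matrix(obj$z_ilm), z_alc = as.matrix(obj$z_alc),
    disc_mask = if (!is.null(obj$disc_mask)) as.matrix(obj$disc_mask) > 0,
    disc_contour = NULL,
    area_onh_px = obj$area_onh_px, area_onh_mm2 = obj$area_onh_mm2,
    nz = obj$nz, failed = NULL,
    override = list(z_ilm = FALSE, z_alc = FALSE)
  ), class = "onh_layer_model")
}
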