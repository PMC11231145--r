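#' Write an intensity stack as multi-page TIFF plus sidecar metadata
#'
#' Images are stored as 16-bit unsigned with a common scale factor
#' (`max / 65535`) recorded in a YAML sidecar next to the TIFF, together
#' with the optics, LED geometry (carrier frequencies), upsampling factor
#' and noise metadata, so a read round trip restores values and geometry.
#'
#' @param stack `intensity_stack`.
#' @param path output TIFF path; the sidecar is written at `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "intensity_stack"))
  mx <- max(vapply(stack$images, max, numeric(1)), 0)
  scale <- if (mx > 0) mx / 65535 else 1
  pages <- lapply(stack$images, function(im) round(im / scale) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  meta <- list(
    n_pages = length(stack$images),
    scale = scale,
    optics = unclass(stack$optics)[c("wavelength_um", "na_mo", "magnification",
                                     "pixel_pitch_um", "grid")],
    nu = list(nu_x = stack$geom$nu[, 1], nu_y = stack$geom$nu[, 2]),
    grid_spec = stack$geom$grid_spec,
    upsampling = stack$upsampling,
    noise = stack$noise
  )
  yaml::write_yaml(meta, paste0(path, ".yaml"), precision = 15)
  invisible(path)
}

#' Read an intensity stack written by [write_stack()]
#'
#' @param path TIFF path with its `<path>.yaml` sidecar.
#' @return `intensity_stack`.
#' @export
read_stack <- function(path) {
  sidecar <- paste0(path, ".yaml")
  if (!file.exists(sidecar))
    stop("missing sidecar metadata file: ", sidecar)
  meta <- yaml::read_yaml(sidecar)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != meta$n_pages)
    stop("stack has ", length(pages), " pages but sidecar records ",
         meta$n_pages)
  images <- lapply(pages, function(p) round(p * 65535) * meta$scale)
  op <- meta$optics
  optics <- fpm_optics(op$wavelength_um, op$na_mo, op$magnification,
                       op$pixel_pitch_um, op$grid)
  geom <- led_geometry_from_nu(cbind(meta$nu$nu_x, meta$nu$nu_y))
  geom$grid_spec <- meta$grid_spec
  if (geom$n_leds != length(images))
    stop("page count ", length(images), " != geometry N ", geom$n_leds)
  structure(list(images = images, geom = geom, optics = optics,
                 upsampling = meta$upsampling, noise = meta$noise),
            class = "intensity_stack")
}

#' Write a phase (or amplitude) map as 32-bit float TIFF with metadata
#'
#' Values are affinely mapped to \[0, 1\] for storage; offset and scale go in
#' a JSON sidecar along with pixel pitch and provenance.
#'
#' @param map `phase_map` or numeric matrix.
#' @param path output TIFF path; sidecar at `<path>.json`.
#' @param pitch_um pixel pitch when `map` is a bare matrix.
#' @export
write_phase_map <- function(map, path, pitch_um = NULL) {
  if (inherits(map, "phase_map")) {
    values <- map$phase; pitch_um <- map$pitch_um; prov <- map$provenance
  } else {
    stopifnot(is.matrix(map), !is.null(pitch_um)); values <- map
    prov <- "unknown"
  }
  lo <- min(values); hi <- max(values)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((values - lo) / scale, path, bits.per.sample = 32)
  jsonlite::write_json(
    list(offset = lo, scale = scale, pitch_um = pitch_um, provenance = prov),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a phase map written by [write_phase_map()]
#' @param path TIFF path with `<path>.json` sidecar.
#' @return `phase_map`.
#' @export
read_phase_map <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing sidecar metadata file: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  values <- tiff::readTIFF(path)
  as_phase_map(values * meta$scale + meta$offset, meta$pitch_um,
               meta$provenance)
}

#' Save / load a calibration model as JSON
#' @param model `calibration_model`; @param path JSON path.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_calibration_model(m$family, as.list(m$coefficients),
                        as.numeric(m$domain), m$residual_scale, m$exposure)
}

# Tiny FNV-1a hash of a string, for config fingerprints in manifests.
#' @keywords internal
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # 32-bit arithmetic in two 16-bit halves: doubles lose exactness above
    # 2^53 and bitwXor() only takes values below 2^31
    lo <- bitwXor(h %% 65536, b)
    hi <- h %/% 65536
    h <- ((lo * p) + ((hi * p) %% 65536) * 65536) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
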