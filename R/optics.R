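#' Describe the imaging optics of an FPM microscope
#'
#' Bundles the optical parameters that fix the coherent transfer function of
#' the objective and the sampling of the detector. The pupil is a circle of
#' radius `na_mo / wavelength_um` cycles/micron in the spatial-frequency
#' plane; everything downstream (forward model, reconstruction, upsampling
#' factor) is derived from these numbers.
#'
#' @param wavelength_um central illumination wavelength (micron).
#' @param na_mo numerical aperture of the microscope objective, in (0, 1).
#' @param magnification lateral magnification of the objective.
#' @param pixel_pitch_um physical detector pixel pitch (micron); the
#'   object-plane sampling is `pixel_pitch_um / magnification`.
#' @param grid low-resolution detector grid side length (pixels).
#' @return an object of class `fpm_optics`.
#' @examples
#' optics <- fpm_optics(wavelength_um = 0.5, na_mo = 0.25,
#'                      magnification = 4, pixel_pitch_um = 2, grid = 64)
#' optics$pupil_radius_cyc_um # NA_MO / lambda
#' @export
fpm_optics <- function(wavelength_um = 0.52, na_mo = 0.13,
                       magnification = 4, pixel_pitch_um = 3.45,
                       grid = 64L) {
  stopifnot(wavelength_um > 0, na_mo > 0, na_mo < 1,
            magnification > 0, pixel_pitch_um > 0, grid >= 8)
  obj_pitch <- pixel_pitch_um / magnification
  pupil_radius <- na_mo / wavelength_um              # cycles/micron
  dnu <- 1 / (grid * obj_pitch)                      # spectral sample spacing
  if (2 * pupil_radius / dnu < 2) {
    stop("pupil diameter spans fewer than 2 spectral samples; ",
         "increase the grid or the numerical aperture")
  }
  if (pupil_radius > 1 / (2 * obj_pitch)) {
    stop("pupil radius NA_MO/lambda exceeds the detector Nyquist band; ",
         "decrease NA_MO or the object-plane pixel pitch")
  }
  structure(list(
    wavelength_um = wavelength_um,
    na_mo = na_mo,
    magnification = magnification,
    pixel_pitch_um = pixel_pitch_um,
    object_pitch_um = obj_pitch,
    grid = as.integer(grid),
    pupil_radius_cyc_um = pupil_radius,
    dnu_cyc_um = dnu
  ), class = "fpm_optics")
}

#' @export
print.fpm_optics <- function(x, ...) {
  cat("FPM optics: lambda", x$wavelength_um, "um, NA", x$na_mo,
      ", mag", x$magnification, "x\n")
  cat("  detector", x$grid, "x", x$grid, "px @", x$pixel_pitch_um,
      "um (object plane", x$object_pitch_um, "um)\n")
  cat("  pupil radius", signif(x$pupil_radius_cyc_um, 4), "cycles/um (",
      signif(x$pupil_radius_cyc_um / x$dnu_cyc_um, 4), "spectral samples)\n")
  invisible(x)
}

#' LED illumination geometry as spatial carrier frequencies
#'
#' Converts the positions of the LEDs of a planar array into the spatial
#' carrier frequencies nu_n = sin(theta_n) / lambda (cycles/micron) that each
#' LED imprints on the object spectrum, and orders them center-outward so the
#' on-axis (bright-field) LED is processed first. A matrix array is truncated
#' to a disk: LEDs farther than `disk_radius` pitches from the center are
#' dropped, which for the default 15 x 15 array keeps 177 LEDs.
#'
#' @param rows,cols LED array extent (odd numbers center an LED on axis).
#' @param pitch_mm LED-to-LED spacing (mm).
#' @param height_mm distance from the array to the sample plane (mm).
#' @param optics an [fpm_optics()] object (supplies the wavelength).
#' @param disk_radius keep LEDs with sqrt(i^2 + j^2) <= disk_radius (in LED
#'   pitches); `Inf` keeps the full rectangle. The default 7.3 keeps 177 of
#'   a 15 x 15 array.
#' @return an object of class `led_geometry` with fields `nu` (N x 2 matrix,
#'   cycles/micron, ordered center-outward), `n_leds`, and the grid spec.
#' @examples
#' geom <- build_led_geometry(rows = 15, cols = 15, pitch_mm = 4,
#'                            height_mm = 60, optics = fpm_optics())
#' geom$n_leds # 177
#' @export
build_led_geometry <- function(rows = 15L, cols = 15L, pitch_mm = 4,
                               height_mm = 60, optics = fpm_optics(),
                               disk_radius = 7.3) {
  stopifnot(rows >= 1, cols >= 1, pitch_mm > 0, height_mm > 0)
  i <- seq_len(rows) - (rows + 1) / 2
  j <- seq_len(cols) - (cols + 1) / 2
  pos <- expand.grid(i = i, j = j)
  keep <- sqrt(pos$i^2 + pos$j^2) <= disk_radius
  pos <- pos[keep, , drop = FALSE]
  if (nrow(pos) == 0) stop("LED geometry is empty after disk truncation")

  x_um <- pos$i * pitch_mm * 1e3
  y_um <- pos$j * pitch_mm * 1e3
  h_um <- height_mm * 1e3
  rho <- sqrt(x_um^2 + y_um^2 + h_um^2)
  # sine of the illumination angle, componentwise, over the wavelength
  nu <- cbind(x_um / rho, y_um / rho) / optics$wavelength_um

  sin_total <- sqrt(rowSums((nu * optics$wavelength_um)^2))
  bad <- sin_total >= 1
  if (any(bad)) {
    warning(sum(bad), " LED(s) imply |sin(theta)| >= 1 and were dropped")
    nu <- nu[!bad, , drop = FALSE]
  }
  if (nrow(nu) == 0) stop("LED geometry is empty after rejecting LEDs")

  ord <- order(sqrt(rowSums(nu^2)))
  nu <- nu[ord, , drop = FALSE]
  colnames(nu) <- c("nu_x", "nu_y")
  structure(list(
    nu = nu,
    n_leds = nrow(nu),
    grid_spec = list(rows = as.integer(rows), cols = as.integer(cols),
                     pitch_mm = pitch_mm, height_mm = height_mm,
                     disk_radius = disk_radius)
  ), class = "led_geometry")
}

#' Build a geometry directly from carrier-frequency vectors
#'
#' Escape hatch for tests and custom illumination schemes: wraps an explicit
#' N x 2 matrix of carrier frequencies (cycles/micron) into a `led_geometry`,
#' sorted center-outward.
#'
#' @param nu N x 2 matrix of (nu_x, nu_y) in cycles/micron.
#' @return `led_geometry`.
#' @export
led_geometry_from_nu <- function(nu) {
  nu <- as.matrix(nu)
  stopifnot(ncol(nu) == 2, nrow(nu) >= 1, all(is.finite(nu)))
  ord <- order(sqrt(rowSums(nu^2)))
  nu <- nu[ord, , drop = FALSE]
  colnames(nu) <- c("nu_x", "nu_y")
  structure(list(nu = nu, n_leds = nrow(nu), grid_spec = NULL),
            class = "led_geometry")
}

#' @export
print.led_geometry <- function(x, ...) {
  cat("LED geometry:", x$n_leds, "LEDs, max |nu| =",
      signif(max(sqrt(rowSums(x$nu^2))), 4), "cycles/um\n")
  invisible(x)
}

# Carrier frequencies in integer spectral samples (row, col) for a given
# spectral spacing. Row index moves with nu_x here purely by storage
# convention (images are matrices indexed [row, col]).
#' @keywords internal
nu_to_samples <- function(geom, dnu) {
  s <- round(geom$nu / dnu)
  storage.mode(s) <- "integer"
  s
}

#' Circular pupil function of the objective
#'
#' The coherent transfer function: unit amplitude and constant (zero) phase
#' on a disk of radius NA_MO/lambda, zero outside. Optional defocus adds the
#' paraxial quadratic phase `pi * lambda * z * |nu|^2` inside the support,
#' the standard thin-lens defocus aberration.
#'
#' @param optics [fpm_optics()].
#' @param defocus_um defocus distance z (micron); 0 for an aberration-free
#'   pupil.
#' @return object of class `fpm_pupil`: complex matrix `p` on the detector
#'   spectral grid, logical `support`, and the generating optics.
#' @export
make_pupil <- function(optics, defocus_um = 0) {
  m <- optics$grid
  cidx <- spectral_center(m)
  f <- (seq_len(m) - cidx) * optics$dnu_cyc_um
  nu2 <- outer(f^2, f^2, "+")
  support <- nu2 <= optics$pupil_radius_cyc_um^2
  p <- matrix(0 + 0i, m, m)
  if (defocus_um != 0) {
    ph <- pi * optics$wavelength_um * defocus_um * nu2
    p[support] <- exp(1i * ph[support])
  } else {
    p[support] <- 1 + 0i
  }
  structure(list(p = p, support = support, optics = optics,
                 defocus_um = defocus_um),
            class = "fpm_pupil")
}

#' @export
print.fpm_pupil <- function(x, ...) {
  cat("Pupil:", sum(x$support), "samples inside NA_MO/lambda support")
  if (x$defocus_um != 0) cat(", defocus", x$defocus_um, "um")
  cat("\n")
  invisible(x)
}

#' Upsampling factor between detector and object grids
#'
#' The synthetic numerical aperture is NA_MO + lambda * max|nu_n|; the object
#' grid must sample it. The factor is ceil((NA_MO + lambda * max|nu_n|) /
#' NA_MO) rounded up to an even integer, so the object grid always contains
#' the farthest shifted detector band.
#'
#' @param optics [fpm_optics()]; @param geom [build_led_geometry()] output.
#' @return even integer upsampling factor >= 2.
#' @export
upsampling_factor <- function(optics, geom) {
  numax <- max(sqrt(rowSums(geom$nu^2)))
  f <- ceiling((optics$na_mo + optics$wavelength_um * numax) / optics$na_mo)
  f <- as.integer(f)
  if (f %% 2L == 1L) f <- f + 1L
  max(f, 2L)
}
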