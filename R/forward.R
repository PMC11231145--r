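#' Simulate an FPM acquisition of a complex field
#'
#' Implements the coherent forward model of sequential-illumination FPM: for
#' each LED carrier frequency nu_n the object spectrum is shifted (to the
#' nearest spectral sample), multiplied by the pupil function on the
#' detector spectral window, inverse transformed, and squared:
#' `I_n(r) = |IFT{ O(nu - nu_n) P(nu) }|^2`.
#'
#' The high-resolution grid must be `f` times the detector grid with `f` the
#' upsampling factor, so both spectral grids share one sample spacing.
#'
#' @param field `highres_field` whose grid is `f * optics$grid` per side.
#' @param pupil [make_pupil()] output (detector spectral grid).
#' @param geom [build_led_geometry()] output.
#' @param optics [fpm_optics()].
#' @return object of class `intensity_stack`: list `images` of N real
#'   non-negative matrices (optics$grid square), plus geometry, optics and
#'   the upsampling factor.
#' @export
forward_acquire <- function(field, pupil, geom, optics) {
  stopifnot(inherits(field, "highres_field"), inherits(pupil, "fpm_pupil"),
            inherits(geom, "led_geometry"), inherits(optics, "fpm_optics"))
  m <- optics$grid
  M <- nrow(field$o)
  if (M %% m != 0) stop("high-res grid is not an integer multiple of the detector grid")
  f <- M %/% m
  O <- ft2(field$o)
  shifts <- nu_to_samples(geom, optics$dnu_cyc_um)
  images <- vector("list", geom$n_leds)
  for (nn in seq_len(geom$n_leds)) {
    phi <- tryCatch(
      crop_shifted(O, shifts[nn, ], m),
      error = function(e) stop("LED ", nn, ": ", conditionMessage(e))
    )
    phi <- phi * pupil$p
    Phi <- ift2(phi) / f^2
    images[[nn]] <- Re(Phi * Conj(Phi))
  }
  structure(list(
    images = images,
    geom = geom,
    optics = optics,
    upsampling = f,
    noise = NULL
  ), class = "intensity_stack")
}

#' Add shot and read noise to an intensity stack
#'
#' Scales each image to an expected photon count (`photons` at unit
#' intensity), draws Poisson shot noise, rescales, adds Gaussian read noise
#' of standard deviation `read_sigma` (intensity units), and clips at zero.
#'
#' @param stack an `intensity_stack`.
#' @param photons photon budget per unit intensity; `Inf` disables shot
#'   noise.
#' @param read_sigma read-noise standard deviation; 0 disables it.
#' @param seed RNG seed for reproducibility.
#' @return a noisy `intensity_stack` with noise metadata filled in.
#' @export
add_noise <- function(stack, photons = Inf, read_sigma = 0, seed = 1L) {
  stopifnot(inherits(stack, "intensity_stack"))
  if (photons <= 0) stop("photon budget must be positive")
  if (read_sigma < 0) stop("read-noise sigma must be non-negative")
  with_seed(seed, {
    images <- lapply(stack$images, function(im) {
      out <- im
      if (is.finite(photons)) {
        out <- matrix(stats::rpois(length(im), lambda = im * photons) / photons,
                      nrow(im), ncol(im))
      }
      if (read_sigma > 0) {
        out <- out + matrix(stats::rnorm(length(im), 0, read_sigma),
                            nrow(im), ncol(im))
      }
      pmax(out, 0)
    })
    out <- stack
    out$images <- images
    out$noise <- list(photons = photons, read_sigma = read_sigma,
                      seed = as.integer(seed))
    out
  })
}

#' @export
print.intensity_stack <- function(x, ...) {
  cat("Intensity stack:", length(x$images), "images of",
      nrow(x$images[[1]]), "x", ncol(x$images[[1]]), "px\n")
  if (!is.null(x$noise))
    cat("  noise: photons =", x$noise$photons,
        ", read sigma =", x$noise$read_sigma, "\n")
  invisible(x)
}

#' One-call synthetic acquisition
#'
#' Convenience wrapper: renders the scene on the grid implied by the optics
#' and geometry (detector grid times the upsampling factor) and pushes it
#' through [forward_acquire()].
#'
#' @param spec [scene_spec()]; its `field_um`/`pitch_um` are overridden by
#'   the optics-derived grid.
#' @inheritParams forward_acquire
#' @param pupil optional pupil; defaults to the aberration-free pupil.
#' @return list with `stack`, `truth` (the rendered `highres_field`) and
#'   `pupil`.
#' @export
simulate_acquisition <- function(spec, geom, optics, pupil = NULL) {
  f <- upsampling_factor(optics, geom)
  pitch_hr <- optics$object_pitch_um / f
  spec$pitch_um <- pitch_hr
  spec$field_um <- optics$grid * optics$object_pitch_um
  truth <- synth_diatom_scene(spec)
  if (is.null(pupil)) pupil <- make_pupil(optics)
  stack <- forward_acquire(truth, pupil, geom, optics)
  list(stack = stack, truth = truth, pupil = pupil)
}
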