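#' Reconstruction settings
#'
#' @param iters number of outer loops J over the full LED set.
#' @param delta1,delta2 regularization constants of the object and pupil
#'   step maps, relative to the unit-normalized squared-modulus scales of
#'   the pupil and object spectra respectively.
#' @param tol early-stop tolerance on the relative data misfit; set to 0 to
#'   always run all `iters` loops.
#' @param pupil_recovery logical; jointly refine the pupil (embedded pupil
#'   recovery) or keep the initial pupil fixed.
#' @return object of class `recon_config`.
#' @export
recon_config <- function(iters = 20L, delta1 = 1e-4, delta2 = 1e-4,
                         tol = 1e-6, pupil_recovery = TRUE) {
  stopifnot(iters >= 1, delta1 > 0, delta2 > 0, tol >= 0)
  structure(list(iters = as.integer(iters), delta1 = delta1,
                 delta2 = delta2, tol = tol,
                 pupil_recovery = isTRUE(pupil_recovery)),
            class = "recon_config")
}

#' Initialize the iterative retrieval state
#'
#' The object spectrum is seeded with the up-sampled central bright-field
#' image: the square root of the on-axis intensity, taken as a zero-phase
#' amplitude, Fourier transformed and embedded in the center of the
#' high-resolution spectral grid. The pupil starts as the ideal circle of
#' radius NA_MO/lambda with constant zero phase.
#'
#' @param stack `intensity_stack`.
#' @param geom,optics acquisition geometry and optics.
#' @param config [recon_config()].
#' @return object of class `recon_state` with the current spectrum `O`,
#'   pupil matrix `P`, support mask, shift table, and an empty misfit
#'   history.
#' @export
initialize_state <- function(stack, geom, optics, config = recon_config()) {
  stopifnot(inherits(stack, "intensity_stack"), length(stack$images) >= 1,
            length(stack$images) == geom$n_leds)
  m <- optics$grid
  f <- stack$upsampling
  M <- f * m
  shifts <- nu_to_samples(geom, optics$dnu_cyc_um)
  nu_mag <- sqrt(rowSums(geom$nu^2))
  bright <- which(nu_mag < optics$pupil_radius_cyc_um)
  if (length(bright) == 0)
    stop("no bright-field LED (all |nu_n| >= NA_MO/lambda); cannot initialize")
  central <- bright[which.min(nu_mag[bright])]

  a <- sqrt(pmax(stack$images[[central]], 0))
  O <- embed_centered(ft2(a) * f^2, M)

  pup <- make_pupil(optics)
  structure(list(
    O = O, P = pup$p, support = pup$support,
    shifts = shifts, m = m, M = M, f = f,
    central = central,
    config = config,
    misfit = numeric(0),
    j = 0L
  ), class = "recon_state")
}

#' Single-LED object/pupil update
#'
#' One step of the sequential Gerchberg-Saxton-Fienup retrieval with joint
#' pupil recovery. Simulates the detector field for LED `n`, replaces its
#' amplitude by the measured square-root intensity, transforms back, and
#' applies the gradient-descent updates: the shifted object band is
#' corrected with the pupil-weighted step map and the pupil with the
#' object-weighted step map, each regularized by `delta1`/`delta2` and
#' normalized by the grid-wide maximum modulus of the other estimate. The
#' pupil is re-projected on its circular support after every update.
#'
#' @param state `recon_state`.
#' @param I_n measured intensity image for this LED (non-negative matrix).
#' @param n LED index into the state's shift table.
#' @return updated `recon_state`; `$last_misfit_num`/`_den` carry this LED's
#'   contribution to the amplitude misfit.
#' @export
update_once <- function(state, I_n, n) {
  stopifnot(inherits(state, "recon_state"), all(I_n >= 0))
  cfg <- state$config
  s <- state$shifts[n, ]
  m <- state$m
  f <- state$f

  Ocrop <- tryCatch(crop_shifted(state$O, s, m),
                    error = function(e) stop("LED ", n, ": ", conditionMessage(e)))
  phi <- Ocrop * state$P
  Phi <- ift2(phi) / f^2
  amp <- Mod(Phi)
  sqrtI <- sqrt(I_n)
  # where |Phi| = 0 keep sqrt(I) at zero phase
  ratio <- matrix(1 + 0i, m, m)
  nz <- amp > 0
  ratio[nz] <- Phi[nz] / amp[nz]
  Phi_p <- sqrtI * ratio
  phi_p <- ft2(Phi_p) * f^2
  dphi <- phi_p - phi
  if (any(!is.finite(Re(dphi))) || any(!is.finite(Im(dphi))))
    stop("non-finite update at LED ", n)

  # step maps use the previous-loop estimates throughout: max|O| is taken
  # before the object band is corrected
  maxP <- max(Mod(state$P))
  maxO <- max(Mod(state$O))
  absP <- Mod(state$P)
  G <- (absP * Conj(state$P)) / (maxP * (absP^2 + cfg$delta1 * maxP^2))
  state$O <- add_shifted(state$O, G * dphi, s)

  if (cfg$pupil_recovery) {
    absO <- Mod(Ocrop)
    H <- (absO * Conj(Ocrop)) / (maxO * (absO^2 + cfg$delta2 * maxO^2))
    state$P <- state$P + H * dphi
    state$P[!state$support] <- 0 + 0i
  }

  state$last_misfit_num <- sum((sqrtI - amp)^2)
  state$last_misfit_den <- sum(sqrtI^2)
  state
}

#' Reconstruct the high-resolution field from an FPM stack
#'
#' Runs `J` outer loops over the LEDs in their (center-outward) acquisition
#' order, each visit applying [update_once()], and records the relative
#' amplitude misfit `sum_n ||sqrt(I_n) - |Phi_n|||^2 / sum_n ||sqrt(I_n)||^2`
#' per loop. Stops early once the misfit drops below `config$tol`; aborts
#' with a diagnostic error if the misfit exceeds ten times its initial
#' value.
#'
#' @inheritParams initialize_state
#' @return list with `field` (`highres_field`, provenance "reconstructed"),
#'   `pupil` (`fpm_pupil` carrying the recovered pupil) and `history`
#'   (misfit per outer loop).
#' @examples
#' optics <- fpm_optics(wavelength_um = 0.5, na_mo = 0.25, magnification = 4,
#'                      pixel_pitch_um = 2, grid = 32)
#' geom <- build_led_geometry(rows = 3, cols = 3, pitch_mm = 4,
#'                            height_mm = 25, optics = optics)
#' sim <- simulate_acquisition(scene_spec(seed = 3), geom, optics)
#' rec <- reconstruct(sim$stack, geom, optics, recon_config(iters = 5))
#' utils::tail(rec$history, 1)
#' @export
reconstruct <- function(stack, geom, optics, config = recon_config()) {
  state <- initialize_state(stack, geom, optics, config)
  N <- geom$n_leds
  for (j in seq_len(config$iters)) {
    num <- 0; den <- 0
    for (n in seq_len(N)) {
      state <- update_once(state, stack$images[[n]], n)
      num <- num + state$last_misfit_num
      den <- den + state$last_misfit_den
    }
    state$j <- j
    mis <- if (den > 0) num / den else 0
    state$misfit <- c(state$misfit, mis)
    if (j > 1 && mis > 10 * state$misfit[1])
      stop("reconstruction diverged: misfit ", signif(mis, 4),
           " exceeds 10x initial ", signif(state$misfit[1], 4))
    if (mis < config$tol) break
  }
  o <- ift2(state$O)
  field <- structure(list(
    o = o,
    phase = Arg(o),
    mask = NULL,
    pitch_um = optics$object_pitch_um / state$f,
    provenance = "reconstructed",
    spec = NULL
  ), class = "highres_field")
  pupil <- structure(list(p = state$P, support = state$support,
                          optics = optics, defocus_um = NA_real_),
                     class = "fpm_pupil")
  list(field = field, pupil = pupil, history = state$misfit)
}

#' Extract the phase-contrast map from a complex field
#'
#' Takes `arg o(r)` in (-pi, pi]. With `flatten = TRUE` a robust low-order
#' (quadratic) polynomial background, fit on the low-phase background pixels,
#' is subtracted — this removes residual tilt/defocus ramps before
#' thresholding and texture analysis. No phase unwrapping is performed; a
#' warning is emitted if 1% or more of the pixels sit within 1% of +/- pi,
#' which indicates wrap-around.
#'
#' @param field `highres_field`.
#' @param flatten subtract a fitted quadratic background surface.
#' @return object of class `phase_map`: matrix `phase` (rad), `pitch_um`,
#'   provenance.
#' @export
extract_phase_map <- function(field, flatten = FALSE) {
  stopifnot(inherits(field, "highres_field"))
  ph <- Arg(field$o)
  if (mean(abs(ph) > 0.99 * pi) >= 0.01)
    warning("possible phase wrap-around: >= 1% of pixels near +/- pi")
  if (flatten) ph <- flatten_background(ph)
  structure(list(phase = ph, pitch_um = field$pitch_um,
                 provenance = field$provenance),
            class = "phase_map")
}

# Robust quadratic background removal: fit x, y, x^2, y^2, xy on pixels
# below the 60th phase percentile (background-dominated), subtract the
# fitted surface everywhere.
#' @keywords internal
flatten_background <- function(ph) {
  n1 <- nrow(ph); n2 <- ncol(ph)
  x <- rep(seq_len(n1) / n1, times = n2)
  y <- rep(seq_len(n2) / n2, each = n1)
  v <- as.vector(ph)
  bg <- v <= stats::quantile(v, 0.6)
  X <- cbind(1, x, y, x^2, y^2, x * y)
  beta <- stats::lm.fit(X[bg, , drop = FALSE], v[bg])$coefficients
  beta[is.na(beta)] <- 0
  matrix(v - X %*% beta, n1, n2)
}

#' @export
print.phase_map <- function(x, ...) {
  cat("Phase-contrast map:", nrow(x$phase), "x", ncol(x$phase), "px @",
      x$pitch_um, "um (", x$provenance, ")\n")
  invisible(x)
}

#' Wrap a real phase matrix as a `phase_map`
#'
#' Used when descriptors are computed directly on simulated ground-truth
#' phase (skipping the optical forward/inverse round trip).
#'
#' @param phase real matrix (rad); @param pitch_um pixel pitch (micron).
#' @param provenance free-text provenance tag.
#' @export
as_phase_map <- function(phase, pitch_um, provenance = "direct") {
  stopifnot(is.matrix(phase), all(is.finite(phase)), pitch_um > 0)
  structure(list(phase = phase, pitch_um = pitch_um, provenance = provenance),
            class = "phase_map")
}
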