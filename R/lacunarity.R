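#' Binarize a phase-contrast map into an occupancy mask
#'
#' Box-counting statistics need an occupancy set. Two thresholding modes are
#' provided: `"otsu"` (default) picks the threshold maximizing between-class
#' variance of the phase histogram; `"fixed"` applies a constant phase
#' threshold in radians, which is the mode to use across a calibration
#' series (one threshold per experiment, so dose-driven phase loss shows up
#' in the masks rather than being re-normalized away image by image).
#'
#' @param map a `phase_map`.
#' @param method `"otsu"` or `"fixed"`.
#' @param param threshold in radians for `method = "fixed"`; ignored for
#'   Otsu.
#' @return object of class `binary_mask`: logical matrix `mask` (object =
#'   TRUE), the method and threshold used, the connected-component count and
#'   per-component equivalent diameters (micron and pixels).
#' @examples
#' pm <- as_phase_map(matrix(c(0, 0.5)[1 + (matrix(runif(64^2), 64) > 0.8)],
#'                           64, 64), pitch_um = 0.5)
#' bm <- binarize_phase(pm, method = "fixed", param = 0.2)
#' sum(bm$mask)
#' @export
binarize_phase <- function(map, method = c("otsu", "fixed"), param = NULL) {
  stopifnot(inherits(map, "phase_map"), all(is.finite(map$phase)))
  method <- match.arg(method)
  ph <- map$phase
  if (method == "otsu") {
    rng <- range(ph)
    if (diff(rng) == 0) {
      thr <- rng[1]   # constant map: empty mask below
      mask <- matrix(FALSE, nrow(ph), ncol(ph))
    } else {
      scaled <- (ph - rng[1]) / diff(rng)
      thr_scaled <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
      thr <- rng[1] + thr_scaled * diff(rng)
      mask <- ph > thr
    }
  } else {
    if (is.null(param)) stop("fixed thresholding needs `param` (radians)")
    thr <- param
    mask <- ph > thr
  }
  if (!any(mask)) warning("binarization produced an all-background mask")
  if (all(mask)) warning("binarization produced an all-object mask")

  diam_px <- numeric(0)
  n_comp <- 0L
  if (any(mask) && !all(mask)) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    areas <- tabulate(as.integer(EBImage::imageData(lab)))
    areas <- areas[areas > 0]
    n_comp <- length(areas)
    diam_px <- 2 * sqrt(areas / pi)
  }
  structure(list(
    mask = mask,
    method = method,
    threshold_rad = thr,
    n_components = n_comp,
    equiv_diam_px = diam_px,
    equiv_diam_um = diam_px * map$pitch_um,
    pitch_um = map$pitch_um
  ), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("Binary mask:", nrow(x$mask), "x", ncol(x$mask), "px, fill",
      signif(mean(x$mask), 3), ",", x$n_components, "components (",
      x$method, "threshold", signif(x$threshold_rad, 3), "rad)\n")
  invisible(x)
}

# Box masses for all fully-inside r x r gliding-box positions (step 1),
# via a zero-padded summed-area table.
#' @keywords internal
box_masses <- function(mask, r) {
  n1 <- nrow(mask); n2 <- ncol(mask)
  S <- matrix(0, n1 + 1, n2 + 1)
  S[-1, -1] <- t(apply(apply(mask * 1, 2, cumsum), 1, cumsum))
  i <- seq_len(n1 - r + 1)
  j <- seq_len(n2 - r + 1)
  S[i + r, j + r, drop = FALSE] - S[i, j + r, drop = FALSE] -
    S[i + r, j, drop = FALSE] + S[i, j, drop = FALSE]
}

#' Gliding-box lacunarity profile
#'
#' For each box size `r`, slides an `r x r` window over every fully-inside
#' position (unit step), counts the occupied pixels `m` in each window, and
#' computes the gliding-box lacunarity `Lambda(r) = E[m^2] / (E[m])^2` — one
#' plus the squared coefficient of variation of box mass. `Lambda = 1` for
#' translation-invariant fullness; larger values mean gappier, more clumped
#' sets at that scale.
#'
#' @param mask a `binary_mask` (or logical matrix).
#' @param scales integer vector of box sizes, each in
#'   `[1, min(dim(mask))]`.
#' @return object of class `lacunarity_profile`: `scales` (ascending, px and
#'   micron), `lambda`, and the algorithm tag.
#' @examples
#' m <- matrix(FALSE, 8, 8); m[4, 5] <- TRUE
#' p <- gliding_box_lacunarity(m, scales = 1)
#' p$lambda # 64 for a single occupied pixel at r = 1
#' @export
gliding_box_lacunarity <- function(mask, scales) {
  pitch <- 1
  if (inherits(mask, "binary_mask")) {
    pitch <- mask$pitch_um
    mask <- mask$mask
  }
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  scales <- sort(unique(as.integer(scales)))
  if (any(scales < 1) || any(scales > min(dim(mask))))
    stop("every scale must satisfy 1 <= r <= min(image dims)")
  if (!any(mask))
    stop("empty mask: lacunarity is undefined (no occupied pixels)")
  lambda <- vapply(scales, function(r) {
    mm <- box_masses(mask, r)
    mu <- mean(mm)
    if (mu == 0) return(NA_real_)  # occupied pixels all within r of the edge
    mean(mm^2) / mu^2
  }, numeric(1))
  structure(list(
    scales = scales,
    scales_um = scales * pitch,
    lambda = lambda,
    algorithm = "gliding-box",
    normalization = "E[m^2]/E[m]^2"
  ), class = "lacunarity_profile")
}

#' @export
print.lacunarity_profile <- function(x, ...) {
  cat("Gliding-box lacunarity profile:\n")
  print(stats::setNames(signif(x$lambda, 5), paste0("r=", x$scales)))
  invisible(x)
}

#' Global lacunarity: geometric mean over a dyadic scale ladder
#'
#' An ensemble descriptor of the hole-size distribution across scales:
#' `GL = exp(mean(log Lambda(r)))` over the profile's scales. The geometric
#' mean is used because Lambda spans decades over a dyadic ladder and the
#' geometric mean is the scale-symmetric summary; arithmetic aggregation is
#' available via `aggregate = "arithmetic"`.
#'
#' @param profile a `lacunarity_profile` with at least 2 scales.
#' @param aggregate `"geometric"` (default) or `"arithmetic"`.
#' @return scalar GL.
#' @export
global_lacunarity <- function(profile, aggregate = c("geometric", "arithmetic")) {
  stopifnot(inherits(profile, "lacunarity_profile"))
  aggregate <- match.arg(aggregate)
  lam <- profile$lambda[!is.na(profile$lambda)]
  if (length(lam) < 2) stop("global lacunarity needs >= 2 scales")
  if (any(lam <= 0)) stop("non-positive lacunarity value: invalid profile")
  if (aggregate == "geometric") exp(mean(log(lam))) else mean(lam)
}

#' Local lacunarity at a single, diatom-sized scale
#'
#' `LL = Lambda(r_local)` from the gliding-box formula: the hole-size
#' statistic at the one scale that probes the interplay between individual
#' bio-probes and the surrounding medium.
#'
#' @param mask `binary_mask` or logical matrix.
#' @param r_local box size in pixels.
#' @return scalar LL.
#' @export
local_lacunarity <- function(mask, r_local) {
  prof <- gliding_box_lacunarity(mask, scales = r_local)
  prof$lambda[1]
}

#' Choose the local scale from the object-size distribution
#'
#' Returns the median equivalent diameter of the mask's connected
#' components, rounded to a whole pixel and clamped to
#' `[2, min(image dims) / 4]` — a box the size of a typical single probe.
#'
#' @param mask `binary_mask` with recorded component diameters.
#' @return integer box size (pixels).
#' @export
select_local_scale <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (mask$n_components < 1)
    stop("empty mask: supply r_local explicitly")
  r <- round(stats::median(mask$equiv_diam_px))
  as.integer(min(max(r, 2), floor(min(dim(mask$mask)) / 4)))
}

#' Multi-scale lacunarity
#'
#' The dose descriptor: the ratio of the global (multi-scale ensemble)
#' lacunarity to the local (single-scale, probe-sized) lacunarity,
#' `MSL = GL / LL`.
#'
#' @param gl,ll global and local lacunarity, both > 0.
#' @return scalar MSL.
#' @export
multi_scale_lacunarity <- function(gl, ll) {
  stopifnot(is.finite(gl), is.finite(ll))
  if (gl <= 0) stop("GL must be positive")
  if (ll <= 0) stop("LL must be positive")
  gl / ll
}

#' Default dyadic scale ladder for a mask
#'
#' Powers of two from 2 up to `min(dim) / 4`, the range over which gliding
#' boxes are well populated on the masks this package produces.
#'
#' @param mask logical matrix or `binary_mask`.
#' @return integer vector of scales.
#' @export
default_scales <- function(mask) {
  if (inherits(mask, "binary_mask")) mask <- mask$mask
  rmax <- min(dim(mask)) / 4
  2^(1:max(1, floor(log2(rmax))))
}

#' Full fractal + texture descriptor set for one field of view
#'
#' Binarizes the phase map, computes the lacunarity profile on the dyadic
#' ladder, GL, LL at `r_local` (selected from the component sizes when not
#' given), MSL, and the range GLCM entropy.
#'
#' @param map `phase_map`.
#' @param method,param passed to [binarize_phase()].
#' @param scales scale ladder; default [default_scales()].
#' @param r_local local box size in px; `NULL` selects it via
#'   [select_local_scale()].
#' @param glcm passed to [range_glcm_entropy()]; a [glcm_spec()].
#' @return one-row `data.frame`: GL, LL, MSL, r_local_px, r_local_um,
#'   delta_s, fill fraction and threshold used.
#' @export
phase_descriptors <- function(map, method = "fixed", param = 0.2,
                              scales = NULL, r_local = NULL,
                              glcm = glcm_spec()) {
  bm <- binarize_phase(map, method = method, param = param)
  if (is.null(scales)) scales <- default_scales(bm)
  prof <- gliding_box_lacunarity(bm, scales)
  gl <- global_lacunarity(prof)
  if (is.null(r_local)) r_local <- select_local_scale(bm)
  ll <- local_lacunarity(bm, r_local)
  msl <- multi_scale_lacunarity(gl, ll)
  ds <- range_glcm_entropy(map, glcm)
  data.frame(
    GL = gl, LL = ll, MSL = msl,
    r_local_px = as.integer(r_local),
    r_local_um = r_local * map$pitch_um,
    delta_s = ds,
    fill = mean(bm$mask),
    threshold_rad = bm$threshold_rad
  )
}
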