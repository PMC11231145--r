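#' Gray-level co-occurrence settings
#'
#' @param levels number of gray levels Q the phase map is quantized to.
#' @param distance offset length in pixels.
#' @param angles_deg offset directions in degrees; the defaults are the four
#'   standard Haralick directions.
#' @param symmetric count each pixel pair in both directions.
#' @param lo_q,hi_q quantization range as phase quantiles; values outside
#'   are clamped into the end bins. The default is the full observed range:
#'   realistic phase maps are mostly background, so inner percentile ranges
#'   (e.g. 1st-99th) collapse to zero width and flatten the descriptor.
#' @return object of class `glcm_spec`.
#' @export
glcm_spec <- function(levels = 64L, distance = 1L,
                      angles_deg = c(0, 45, 90, 135),
                      symmetric = TRUE, lo_q = 0, hi_q = 1) {
  stopifnot(levels >= 2, distance >= 1, length(angles_deg) >= 1,
            lo_q >= 0, hi_q <= 1, lo_q < hi_q)
  structure(list(levels = as.integer(levels), distance = as.integer(distance),
                 angles_deg = angles_deg, symmetric = isTRUE(symmetric),
                 lo_q = lo_q, hi_q = hi_q),
            class = "glcm_spec")
}

# Quantize a phase matrix to 1..Q over its robust range.
#' @keywords internal
quantize_levels <- function(ph, spec) {
  qs <- stats::quantile(ph, c(spec$lo_q, spec$hi_q), names = FALSE)
  if (qs[2] <= qs[1]) return(matrix(1L, nrow(ph), ncol(ph)))
  q <- floor((ph - qs[1]) / (qs[2] - qs[1]) * spec$levels) + 1L
  q[q < 1L] <- 1L
  q[q > spec$levels] <- spec$levels
  matrix(as.integer(q), nrow(ph), ncol(ph))
}

# Integer pixel offset (drow, dcol) for an angle: 0 deg pairs horizontally
# neighboring pixels (column direction), 90 deg vertically.
#' @keywords internal
angle_offset <- function(angle_deg, distance) {
  a <- angle_deg * pi / 180
  c(drow = -round(distance * sin(a)), dcol = round(distance * cos(a)))
}

#' Gray-level co-occurrence matrix of a phase map
#'
#' Quantizes the map to `spec$levels` gray levels over its robust range and
#' tabulates co-occurring level pairs at the given pixel offset. With
#' `symmetric = TRUE` each pair is counted in both orders. The matrix is
#' normalized to sum to one.
#'
#' @param map `phase_map` (or plain numeric matrix).
#' @param spec [glcm_spec()].
#' @param angle_deg offset direction for this matrix.
#' @return Q x Q co-occurrence probability matrix.
#' @export
glcm <- function(map, spec = glcm_spec(), angle_deg = 0) {
  ph <- if (inherits(map, "phase_map")) map$phase else map
  stopifnot(is.matrix(ph), all(is.finite(ph)))
  q <- quantize_levels(ph, spec)
  off <- angle_offset(angle_deg, spec$distance)
  n1 <- nrow(q); n2 <- ncol(q)
  r0 <- max(1, 1 - off[1]); r1 <- min(n1, n1 - off[1])
  c0 <- max(1, 1 - off[2]); c1 <- min(n2, n2 - off[2])
  if (r0 > r1 || c0 > c1) stop("offset larger than the image")
  a <- q[r0:r1, c0:c1]
  b <- q[(r0 + off[1]):(r1 + off[1]), (c0 + off[2]):(c1 + off[2])]
  Q <- spec$levels
  counts <- tabulate(as.vector((a - 1L) * Q + b), nbins = Q * Q)
  mat <- matrix(counts, Q, Q, byrow = TRUE)
  if (spec$symmetric) mat <- mat + t(mat)
  mat / sum(mat)
}

#' Entropy of a co-occurrence matrix
#'
#' Shannon entropy `-sum(p * log2(p))` over the nonzero cells, in bits.
#' Bounded by `2 log2(Q)` for a Q x Q matrix.
#'
#' @param mat normalized co-occurrence matrix (sums to 1).
#' @return entropy in bits.
#' @export
glcm_entropy <- function(mat) {
  stopifnot(is.matrix(mat), all(mat >= 0))
  if (abs(sum(mat) - 1) > 1e-8)
    stop("co-occurrence matrix is not normalized (sum != 1)")
  p <- mat[mat > 0]
  -sum(p * log2(p))
}

#' Range GLCM entropy of a phase map
#'
#' The anisotropy-sensitive disorder descriptor delta-s: the co-occurrence
#' entropy is computed for each offset direction in `spec` and the spread
#' `max - min` across directions is returned (the Haralick "range"
#' statistic), in bits. A clean isotropic field gives a small delta-s;
#' oriented structure and heterogeneous debris raise it.
#'
#' @inheritParams glcm
#' @return delta-s in bits (>= 0).
#' @examples
#' stripes <- matrix(rep(c(0, 1), each = 4, times = 8), 8, 8)
#' range_glcm_entropy(as_phase_map(stripes, 1), glcm_spec(levels = 2))
#' @export
range_glcm_entropy <- function(map, spec = glcm_spec()) {
  if (length(spec$angles_deg) < 2)
    stop("range GLCM entropy needs >= 2 offset directions")
  ent <- vapply(spec$angles_deg,
                function(a) glcm_entropy(glcm(map, spec, a)),
                numeric(1))
  max(ent) - min(ent)
}
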