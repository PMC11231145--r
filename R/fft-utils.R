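# Spectral-grid helpers.
#
# Convention used throughout: spectra are stored DC-at-center. For a grid of
# n samples the zero-frequency sample sits at index floor(n/2) + 1, matching
# the usual fftshift convention for both even and odd n. All shifts between
# the detector (low-resolution) and object (high-resolution) spectral grids
# are integer numbers of spectral samples; both grids share the same sample
# spacing 1/(n_lr * pitch_lr) cycles/micron, the high-resolution grid simply
# extends further.

#' @keywords internal
fftshift2 <- function(x) {
  d <- dim(x)
  i <- c((ceiling(d[1] / 2) + 1):d[1], 1:ceiling(d[1] / 2))
  j <- c((ceiling(d[2] / 2) + 1):d[2], 1:ceiling(d[2] / 2))
  x[i, j, drop = FALSE]
}

#' @keywords internal
ifftshift2 <- function(x) {
  d <- dim(x)
  i <- c((floor(d[1] / 2) + 1):d[1], 1:floor(d[1] / 2))
  j <- c((floor(d[2] / 2) + 1):d[2], 1:floor(d[2] / 2))
  x[i, j, drop = FALSE]
}

# Forward 2-D Fourier transform, DC-centered output, unnormalized
#' @keywords internal
ft2 <- function(x) fftshift2(stats::fft(x))

# Inverse 2-D Fourier transform of a DC-centered spectrum, 1/n normalized
#' @keywords internal
ift2 <- function(X) stats::fft(ifftshift2(X), inverse = TRUE) / length(X)

#' @keywords internal
spectral_center <- function(n) floor(n / 2) + 1L

# Crop the m x m spectral window of the centered spectrum `O` that samples
# O(nu - nu_n) over the detector band, where `shift` is nu_n in integer
# spectral samples (row, col). At window center nu = 0 the value O(-nu_n) is
# read, so the window is centered at the grid position center - shift.
#' @keywords internal
crop_shifted <- function(O, shift, m) {
  M <- dim(O)
  cM <- c(spectral_center(M[1]), spectral_center(M[2]))
  cm <- c(spectral_center(m), spectral_center(m))
  r0 <- cM[1] - shift[1] - cm[1]
  c0 <- cM[2] - shift[2] - cm[2]
  if (r0 < 0 || c0 < 0 || r0 + m > M[1] || c0 + m > M[2]) {
    stop("spectral shift (", shift[1], ", ", shift[2],
         ") places the detector band outside the object spectrum support")
  }
  O[r0 + seq_len(m), c0 + seq_len(m), drop = FALSE]
}

# Add `delta` (m x m) into the window of `O` addressed by crop_shifted().
#' @keywords internal
add_shifted <- function(O, delta, shift) {
  m <- nrow(delta)
  M <- dim(O)
  cM <- c(spectral_center(M[1]), spectral_center(M[2]))
  cm <- spectral_center(m)
  r0 <- cM[1] - shift[1] - cm
  c0 <- cM[2] - shift[2] - cm
  O[r0 + seq_len(m), c0 + seq_len(m)] <-
    O[r0 + seq_len(m), c0 + seq_len(m)] + delta
  O
}

# Embed an m x m centered spectrum into the center of an M x M zero grid.
#' @keywords internal
embed_centered <- function(X, M) {
  m <- nrow(X)
  out <- matrix(0 + 0i, M, M)
  off <- spectral_center(M) - spectral_center(m)
  out[off + seq_len(m), off + seq_len(m)] <- X
  out
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
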