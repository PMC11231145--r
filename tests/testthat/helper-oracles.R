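# Independent oracle implementations used to cross-check the package's
# spectral pipeline, lacunarity and GLCM code. Everything here is written
# from the definitions by direct summation / enumeration and shares no code
# with the implementation under test.

# Direct-summation centered 2-D DFT: X[f1, f2] = sum_n x[n] e^{-2pi i f.n/N},
# with f running over centered frequencies (index - (floor(N/2)+1)).
dft2_direct <- function(x) {
  N1 <- nrow(x); N2 <- ncol(x)
  c1 <- floor(N1 / 2) + 1; c2 <- floor(N2 / 2) + 1
  out <- matrix(0 + 0i, N1, N2)
  for (k1 in seq_len(N1)) for (k2 in seq_len(N2)) {
    f1 <- k1 - c1; f2 <- k2 - c2
    acc <- 0 + 0i
    for (n1 in seq_len(N1)) for (n2 in seq_len(N2)) {
      acc <- acc + x[n1, n2] *
        exp(-2i * pi * (f1 * (n1 - 1) / N1 + f2 * (n2 - 1) / N2))
    }
    out[k1, k2] <- acc
  }
  out
}

# Direct-summation inverse of a centered spectrum, scaled by 1/`norm`.
idft2_direct <- function(X, norm) {
  N1 <- nrow(X); N2 <- ncol(X)
  c1 <- floor(N1 / 2) + 1; c2 <- floor(N2 / 2) + 1
  out <- matrix(0 + 0i, N1, N2)
  for (n1 in seq_len(N1)) for (n2 in seq_len(N2)) {
    acc <- 0 + 0i
    for (k1 in seq_len(N1)) for (k2 in seq_len(N2)) {
      f1 <- k1 - c1; f2 <- k2 - c2
      acc <- acc + X[k1, k2] *
        exp(2i * pi * (f1 * (n1 - 1) / N1 + f2 * (n2 - 1) / N2))
    }
    out[n1, n2] <- acc / norm
  }
  out
}

# Brute-force forward model: I = |IFT{O(nu - nu_n) P(nu)}|^2 for one LED
# with integer spectral shift s = (s1, s2); o is M x M, P is m x m.
forward_oracle <- function(o, P, s, m) {
  M <- nrow(o)
  O <- dft2_direct(o)
  cM <- floor(M / 2) + 1
  cm <- floor(m / 2) + 1
  band <- matrix(0 + 0i, m, m)
  for (k1 in seq_len(m)) for (k2 in seq_len(m)) {
    # window frequency f = k - cm; value O(f - s) at grid index cM + f - s
    i1 <- cM + (k1 - cm) - s[1]
    i2 <- cM + (k2 - cm) - s[2]
    band[k1, k2] <- O[i1, i2]
  }
  Phi <- idft2_direct(band * P, norm = M^2)
  Mod(Phi)^2
}

# Independent transcription of the sequential retrieval update (amplitude
# replacement + object/pupil gradient steps with regularized step maps).
# Returns the updated (O, P). delta1/delta2 are relative to max|P|^2 and
# max|O|^2. support is the pupil's logical support mask.
update_oracle <- function(O, P, support, I_n, s, f, delta1, delta2,
                          pupil_recovery = TRUE) {
  M <- nrow(O); m <- nrow(P)
  cM <- floor(M / 2) + 1; cm <- floor(m / 2) + 1
  idx1 <- function(k1) cM + (k1 - cm) - s[1]
  idx2 <- function(k2) cM + (k2 - cm) - s[2]

  band <- matrix(0 + 0i, m, m)
  for (k1 in seq_len(m)) for (k2 in seq_len(m))
    band[k1, k2] <- O[idx1(k1), idx2(k2)]
  phi <- band * P
  Phi <- idft2_direct(phi, norm = M^2)
  amp <- Mod(Phi)
  ratio <- matrix(1 + 0i, m, m)
  ratio[amp > 0] <- Phi[amp > 0] / amp[amp > 0]
  Phi_p <- sqrt(I_n) * ratio
  phi_p <- dft2_direct(Phi_p) * f^2
  dphi <- phi_p - phi

  maxP <- max(Mod(P))
  maxO <- max(Mod(O))
  O_new <- O
  for (k1 in seq_len(m)) for (k2 in seq_len(m)) {
    G <- (Mod(P[k1, k2]) * Conj(P[k1, k2])) /
      (maxP * (Mod(P[k1, k2])^2 + delta1 * maxP^2))
    O_new[idx1(k1), idx2(k2)] <- O_new[idx1(k1), idx2(k2)] + G * dphi[k1, k2]
  }
  P_new <- P
  if (pupil_recovery) {
    for (k1 in seq_len(m)) for (k2 in seq_len(m)) {
      H <- (Mod(band[k1, k2]) * Conj(band[k1, k2])) /
        (maxO * (Mod(band[k1, k2])^2 + delta2 * maxO^2))
      P_new[k1, k2] <- P_new[k1, k2] + H * dphi[k1, k2]
    }
    P_new[!support] <- 0 + 0i
  }
  list(O = O_new, P = P_new)
}

# Exhaustive gliding-box lacunarity: enumerate every fully-inside r x r box.
lacunarity_oracle <- function(mask, r) {
  n1 <- nrow(mask); n2 <- ncol(mask)
  masses <- c()
  for (i in seq_len(n1 - r + 1)) for (j in seq_len(n2 - r + 1))
    masses <- c(masses, sum(mask[i:(i + r - 1), j:(j + r - 1)]))
  mean(masses^2) / mean(masses)^2
}

# Pair-enumeration GLCM on an already-quantized integer matrix.
glcm_oracle <- function(q, drow, dcol, Q, symmetric = TRUE) {
  n1 <- nrow(q); n2 <- ncol(q)
  mat <- matrix(0, Q, Q)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    i2 <- i + drow; j2 <- j + dcol
    if (i2 >= 1 && i2 <= n1 && j2 >= 1 && j2 <= n2) {
      mat[q[i, j], q[i2, j2]] <- mat[q[i, j], q[i2, j2]] + 1
      if (symmetric) mat[q[i2, j2], q[i, j]] <- mat[q[i2, j2], q[i, j]] + 1
    }
  }
  mat / sum(mat)
}

# Small optics/geometry fixtures shared across test files.
test_optics <- function(grid = 32) {
  fpm_optics(wavelength_um = 0.5, na_mo = 0.25, magnification = 4,
             pixel_pitch_um = 2, grid = grid)
}

test_geometry <- function(optics, rows = 3, pitch_mm = 4, height_mm = 25) {
  build_led_geometry(rows = rows, cols = rows, pitch_mm = pitch_mm,
                     height_mm = height_mm, optics = optics)
}

# Wrap a complex matrix as a highres_field (fixture plumbing).
as_field <- function(o, pitch_um) {
  structure(list(o = o, phase = Arg(o), mask = NULL, pitch_um = pitch_um,
                 provenance = "simulated", spec = NULL),
            class = "highres_field")
}
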