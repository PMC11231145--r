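make_toy_acquisition <- function(seed = 3, stress = 0.3, grid = 64,
                                 defocus_um = 0) {
  optics <- test_optics(grid = grid)
  geom <- build_led_geometry(rows = 5, cols = 5, pitch_mm = 2.5,
                             height_mm = 28, optics = optics)
  spec <- scene_spec(stress = stress, seed = seed, min_chains = 2)
  f <- upsampling_factor(optics, geom)
  spec$pitch_um <- optics$object_pitch_um / f
  spec$field_um <- optics$grid * optics$object_pitch_um
  truth <- synth_diatom_scene(spec)
  pupil <- make_pupil(optics, defocus_um = defocus_um)
  stack <- forward_acquire(truth, pupil, geom, optics)
  list(optics = optics, geom = geom, truth = truth, stack = stack,
       pupil = pupil)
}

test_that("initialization seeds the object with the central image", {
  optics <- test_optics(grid = 16)
  geom <- test_geometry(optics)
  f <- upsampling_factor(optics, geom)
  M <- f * optics$grid
  field <- as_field(matrix(1 + 0i, M, M), optics$object_pitch_um / f)
  stk <- forward_acquire(field, make_pupil(optics), geom, optics)
  st <- initialize_state(stk, geom, optics)

  # uniform stack: spectrum is a delta at DC
  c0 <- floor(M / 2) + 1
  dc <- Mod(st$O[c0, c0])
  rest <- Mod(st$O); rest[c0, c0] <- 0
  expect_lt(max(rest), 1e-10 * dc)

  # pupil amplitude sums to the support pixel count
  expect_equal(sum(Mod(st$P)), sum(st$support))

  # round trip: pushing the initial guess through the forward model
  # reproduces the central image on a bright-field-only noiseless toy
  o0 <- fpmfa:::ift2(st$O)
  stk2 <- forward_acquire(as_field(o0, optics$object_pitch_um / f),
                          make_pupil(optics), geom, optics)
  rel <- max(abs(stk2$images[[1]] - stk$images[[1]])) / max(stk$images[[1]])
  expect_lt(rel, 1e-6)
})

test_that("initialization requires a bright-field LED", {
  optics <- test_optics(grid = 16)
  dark <- led_geometry_from_nu(rbind(c(0.6, 0), c(0, 0.6)))
  f <- 2; M <- f * optics$grid
  field <- as_field(matrix(1 + 0i, M, M), optics$object_pitch_um / f)
  stk <- forward_acquire(field, make_pupil(optics), dark, optics)
  expect_error(initialize_state(stk, dark, optics), "bright-field")
})

test_that("consistent data is a fixed point of the single-LED update", {
  acq <- make_toy_acquisition(grid = 32)
  st <- initialize_state(acq$stack, acq$geom, acq$optics)
  # overwrite the state with the exact ground truth
  st$O <- fpmfa:::ft2(acq$truth$o)
  st$P <- acq$pupil$p
  O0 <- st$O; P0 <- st$P
  for (n in c(1, 5, acq$geom$n_leds)) {
    st <- update_once(st, acq$stack$images[[n]], n)
  }
  expect_lt(max(Mod(st$O - O0)) / max(Mod(O0)), 1e-9)
  expect_lt(max(Mod(st$P - P0)) / max(Mod(P0)), 1e-9)
})

test_that("one update matches the independent equation transcription", {
  # 8x8 detector grid, single oblique LED, complex random state
  m <- 8; f <- 2; M <- m * f
  optics <- fpm_optics(wavelength_um = 0.5, na_mo = 0.2, magnification = 4,
                       pixel_pitch_um = 2, grid = m)
  s <- c(1L, -2L)
  geom <- led_geometry_from_nu(rbind(c(0, 0), s * optics$dnu_cyc_um))
  set.seed(21)
  o <- exp(1i * matrix(runif(M^2, -1, 1), M, M))
  truth <- as_field(o, optics$object_pitch_um / f)
  pupil <- make_pupil(optics)
  stack <- forward_acquire(truth, pupil, geom, optics)

  st <- initialize_state(stack, geom, optics,
                         recon_config(delta1 = 1e-4, delta2 = 1e-4))
  # random complex state so the update is non-trivial
  st$O <- matrix(complex(real = rnorm(M^2), imaginary = rnorm(M^2)), M, M)
  st$P <- pupil$p * exp(1i * 0.3)
  st$P[!st$support] <- 0

  ora <- update_oracle(st$O, st$P, st$support, stack$images[[2]], s, f,
                       delta1 = 1e-4, delta2 = 1e-4)
  upd <- update_once(st, stack$images[[2]], 2)
  expect_lt(max(Mod(upd$O - ora$O)), 1e-12 * max(Mod(ora$O)))
  expect_lt(max(Mod(upd$P - ora$P)), 1e-12 * max(Mod(ora$P)))
})

test_that("misfit decreases on noiseless data and pupil support is conserved", {
  acq <- make_toy_acquisition(grid = 32)
  rec <- reconstruct(acq$stack, acq$geom, acq$optics,
                     recon_config(iters = 10, tol = 0))
  h <- rec$history
  expect_lt(h[length(h)], h[1] / 10)
  expect_true(all(diff(h) <= 0.01 * h[1]))
  support <- make_pupil(acq$optics)$support
  expect_true(all(Mod(rec$pupil$p[!support]) == 0))
})

test_that("single central LED with all-pass pupil degenerates to upsampling", {
  optics <- test_optics(grid = 16)
  geom <- led_geometry_from_nu(matrix(0, 1, 2))
  f <- 2; M <- f * optics$grid
  set.seed(4)
  amp <- matrix(runif(M^2, 0.5, 1.5), M, M)
  # band-limit the amplitude well inside the pupil so the single image
  # carries the complete spectrum
  A <- fpmfa:::ft2(amp)
  keep <- fpmfa:::embed_centered(matrix(1 + 0i, 5, 5), M)
  o <- fpmfa:::ift2(A * (Mod(keep) > 0))
  stk <- forward_acquire(as_field(o, optics$object_pitch_um / f),
                         make_pupil(optics), geom, optics)
  rec <- reconstruct(stk, geom, optics,
                     recon_config(iters = 1, pupil_recovery = FALSE))
  # amplitude reproduces sqrt(I); phase is (numerically) constant
  down <- Mod(rec$field$o)[seq(1, M, f), seq(1, M, f)]
  expect_equal(down, sqrt(stk$images[[1]]), tolerance = 1e-6)
  expect_lt(diff(range(Arg(rec$field$o))), 1e-6)
})

test_that("phase maps extract, flatten, and flag degenerate fields", {
  M <- 64
  expect_equal(extract_phase_map(as_field(matrix(1 + 0i, M, M), 0.5))$phase,
               matrix(0, M, M))
  pm <- extract_phase_map(as_field(matrix(exp(0.3i), M, M), 0.5))
  expect_equal(pm$phase, matrix(0.3, M, M), tolerance = 1e-12)
  pm_flat <- extract_phase_map(as_field(matrix(exp(0.3i), M, M), 0.5),
                               flatten = TRUE)
  expect_equal(max(abs(pm_flat$phase)), 0, tolerance = 1e-9)

  # tilted background plus one blob: flattening recovers the blob height
  x <- outer(seq_len(M), rep(1, M)) / M
  blob <- matrix(0, M, M); blob[28:36, 28:36] <- 0.8
  field <- as_field(exp(1i * (0.2 * x + blob)), 0.5)
  rec <- extract_phase_map(field, flatten = TRUE)
  peak <- max(rec$phase)
  expect_equal(peak, 0.8, tolerance = 0.05)
})
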