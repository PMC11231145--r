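test_that("analytic gliding-box values hold exactly", {
  # translation-invariant fullness: Lambda = 1 at every scale
  full <- matrix(TRUE, 8, 8)
  expect_equal(gliding_box_lacunarity(full, c(1, 2, 4))$lambda, c(1, 1, 1))

  # single occupied pixel in 8x8 at r = 1: E[m^2]/E[m]^2 = 64
  single <- matrix(FALSE, 8, 8); single[4, 5] <- TRUE
  expect_equal(gliding_box_lacunarity(single, 1)$lambda, 64)
})

test_that("gliding-box profile equals exhaustive enumeration", {
  set.seed(31)
  m4 <- matrix(runif(16) > 0.5, 4, 4)
  m4[1, 1] <- TRUE  # ensure non-empty
  expect_equal(gliding_box_lacunarity(m4, 2)$lambda,
               lacunarity_oracle(m4, 2), tolerance = 1e-14)

  # exhaustive property: random masks up to 6x6, every scale
  for (k in 1:20) {
    n <- sample(2:6, 1)
    mk <- matrix(runif(n * n) > runif(1, 0.2, 0.8), n, n)
    if (!any(mk)) mk[sample(n, 1), sample(n, 1)] <- TRUE
    for (r in 1:n) {
      got <- gliding_box_lacunarity(mk, r)$lambda
      expect_equal(got, lacunarity_oracle(mk, r), tolerance = 1e-12,
                   info = sprintf("mask %d, r = %d", k, r))
    }
  }
})

test_that("profile invariants: Lambda >= 1, tends to 1 at the image scale", {
  set.seed(32)
  mk <- matrix(runif(64^2) > 0.6, 64, 64)
  prof <- gliding_box_lacunarity(mk, c(1, 2, 4, 8, 16, 32, 64))
  expect_true(all(prof$lambda >= 1 - 1e-12))
  expect_lt(abs(prof$lambda[length(prof$lambda)] - 1), 0.01)
})

test_that("cyclic shifts of a periodic mask barely change the profile", {
  # window large relative to the period, so box-phase weighting imbalance
  # (the only residual edge effect of fully-inside boxes) stays below 1%
  base <- matrix(FALSE, 1024, 1024)
  base[(row(base) %% 8) < 3 & (col(base) %% 8) < 3] <- TRUE
  prof0 <- gliding_box_lacunarity(base, c(2, 4, 8))$lambda
  shifted <- base[c(4:1024, 1:3), c(6:1024, 1:5)]
  prof1 <- gliding_box_lacunarity(shifted, c(2, 4, 8))$lambda
  expect_true(all(abs(prof1 - prof0) / prof0 < 0.01))
})

test_that("global lacunarity is the geometric mean across the ladder", {
  prof <- structure(list(scales = c(2L, 4L), scales_um = c(2, 4),
                         lambda = c(2, 8), algorithm = "gliding-box",
                         normalization = "E[m^2]/E[m]^2"),
                    class = "lacunarity_profile")
  expect_equal(global_lacunarity(prof), 4)
  expect_equal(global_lacunarity(prof, aggregate = "arithmetic"), 5)
  flat <- prof; flat$lambda <- c(1, 1)
  expect_equal(global_lacunarity(flat), 1)
  short <- prof; short$lambda <- 2; short$scales <- 2L
  expect_error(global_lacunarity(short), ">= 2 scales")
})

test_that("infilling holes lowers the global lacunarity", {
  set.seed(33)
  mk <- matrix(runif(128^2) > 0.7, 128, 128)
  closed <- EBImage::imageData(EBImage::closing(
    EBImage::Image(mk * 1), EBImage::makeBrush(5, "disc"))) > 0
  scales <- c(2, 4, 8, 16)
  gl_open <- global_lacunarity(gliding_box_lacunarity(mk, scales))
  gl_closed <- global_lacunarity(gliding_box_lacunarity(closed, scales))
  expect_lt(gl_closed, gl_open)
})

test_that("local lacunarity is the profile value at the local scale", {
  set.seed(34)
  mk <- matrix(runif(16) > 0.4, 4, 4); mk[2, 2] <- TRUE
  expect_equal(local_lacunarity(mk, 2), lacunarity_oracle(mk, 2),
               tolerance = 1e-12)
  expect_equal(local_lacunarity(matrix(TRUE, 8, 8), 3), 1)

  big <- matrix(runif(64^2) > 0.5, 64, 64)
  prof <- gliding_box_lacunarity(big, c(2, 4, 8))
  expect_equal(local_lacunarity(big, 4), prof$lambda[prof$scales == 4])
})

test_that("local scale selection follows the component size distribution", {
  # one disk of diameter 10 px
  disk <- matrix(FALSE, 64, 64)
  disk[(row(disk) - 32)^2 + (col(disk) - 32)^2 <= 25] <- TRUE
  pm <- as_phase_map(disk * 0.5, pitch_um = 1)
  bm <- binarize_phase(pm, method = "fixed", param = 0.2)
  expect_equal(select_local_scale(bm), 10L, tolerance = 1)

  # synthetic components of diameters ~{6, 10, 40}: median wins
  mk <- matrix(FALSE, 256, 256)
  for (spec in list(c(40, 40, 3), c(120, 120, 5), c(200, 200, 20))) {
    mk[(row(mk) - spec[1])^2 + (col(mk) - spec[2])^2 <= spec[3]^2] <- TRUE
  }
  bm2 <- binarize_phase(as_phase_map(mk * 0.5, 1), "fixed", param = 0.2)
  expect_equal(select_local_scale(bm2), 10L, tolerance = 1)

  # empty masks demand an explicit scale
  suppressWarnings({
    bm_empty <- binarize_phase(as_phase_map(matrix(0, 16, 16), 1),
                               "fixed", param = 0.2)
  })
  expect_error(select_local_scale(bm_empty), "explicit")
})

test_that("MSL is exactly the GL/LL ratio and validates its inputs", {
  expect_equal(multi_scale_lacunarity(4, 2), 2)
  expect_equal(multi_scale_lacunarity(3, 3), 1)
  expect_error(multi_scale_lacunarity(0, 2), "GL")
  expect_error(multi_scale_lacunarity(2, 0), "LL")
})

test_that("empty and invalid inputs produce errors, not NaN", {
  expect_error(gliding_box_lacunarity(matrix(FALSE, 8, 8), 2), "empty")
  expect_error(gliding_box_lacunarity(matrix(TRUE, 8, 8), 9), "scale")
  expect_error(gliding_box_lacunarity(matrix(TRUE, 8, 8), 0), "scale")
})

test_that("binarization modes behave as documented", {
  # fixed threshold on a two-valued map keeps exactly the upper value
  ph <- matrix(0, 16, 16); ph[5:8, 5:8] <- 0.5
  bm <- binarize_phase(as_phase_map(ph, 1), "fixed", param = 0.2)
  expect_identical(bm$mask, ph == 0.5)

  # all-zero map: empty mask with a warning
  expect_warning(binarize_phase(as_phase_map(matrix(0, 8, 8), 1),
                                "fixed", param = 0.2),
                 "all-background")

  # Otsu separates two well-separated blobs; equivalent diameters recorded
  ph2 <- matrix(0, 64, 64)
  ph2[(row(ph2) - 16)^2 + (col(ph2) - 16)^2 <= 36] <- 1
  ph2[(row(ph2) - 48)^2 + (col(ph2) - 48)^2 <= 36] <- 1
  bm2 <- binarize_phase(as_phase_map(ph2, 1), "otsu")
  expect_equal(bm2$n_components, 2L)
  expect_true(all(abs(bm2$equiv_diam_px - 12) <= 2))
})

test_that("MSL of pure-noise masks is stable across seeds at fixed density", {
  msl <- sapply(1:8, function(k) {
    set.seed(400 + k)
    mk <- matrix(runif(128^2) > 0.8, 128, 128)
    prof <- gliding_box_lacunarity(mk, c(2, 4, 8, 16))
    global_lacunarity(prof) / local_lacunarity(mk, 4)
  })
  expect_lt(stats::sd(msl) / mean(msl), 0.1)
})
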