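test_that("single-pixel harmonic fit recovers coefficients exactly and flags bad schedules", {
  cfg <- acquisition_config()
  times <- (0:63) / 64 * (2 * pi / cfg$omega)
  # constant half-intensity series is pure A = 1
  fit <- fit_fourier_pixel(rep(0.5, 64), times, cfg)
  expect_equal(c(fit$A, fit$B, fit$C, fit$D), c(1, 0, 0, 0), tolerance = 1e-12)
  # noiseless synthesis round trip
  theta <- cfg$omega * times + cfg$phi0
  I <- 0.5 * (1.5 - 0 * sin(2 * theta) + 0.5 * cos(4 * theta) + 0 * sin(4 * theta))
  fit <- fit_fourier_pixel(I, times, cfg)
  expect_equal(c(fit$A, fit$B, fit$C, fit$D), c(1.5, 0, 0.5, 0),
               tolerance = 1e-12)
  expect_lt(fit$rms, 1e-12)
  # repeated identical angles cannot determine four harmonics
  expect_error(fit_fourier_pixel(rep(0.5, 8), rep(0, 8), cfg),
               "rank-deficient")
})

test_that("harmonic fits achieve linear-model accuracy under Gaussian noise", {
  cfg <- acquisition_config()
  times <- (0:63) / 64 * (2 * pi / cfg$omega)
  theta <- cfg$omega * times
  truth <- c(A = 1.2, B = 0.3, C = 0.2, D = -0.4)
  I0 <- 0.5 * (truth["A"] - truth["B"] * sin(2 * theta) +
                 truth["C"] * cos(4 * theta) + truth["D"] * sin(4 * theta))
  sd_noise <- 0.01
  set.seed(99)
  ok <- 0L
  n_trials <- 1000
  # exact sampling theory for the orthogonal uniform design: the 1/2-scaled
  # basis gives SE(A) = 2*sd/sqrt(T) and SE(B,C,D) = 2*sqrt(2)*sd/sqrt(T)
  se <- c(2, 2 * sqrt(2), 2 * sqrt(2), 2 * sqrt(2)) * sd_noise / sqrt(64)
  for (i in seq_len(n_trials)) {
    fit <- fit_fourier_pixel(I0 + rnorm(64, sd = sd_noise), times, cfg)
    est <- c(fit$A, fit$B, fit$C, fit$D)
    if (all(abs(est - truth) < 3 * se)) ok <- ok + 1L
  }
  # joint 3-SE coverage of four independent coefficients is ~98.9%
  expect_gt(ok / n_trials, 0.97)
})

test_that("stack fitting equals the per-pixel loop", {
  fld <- build_leaf(tiny_leaf(8, 3), growth_model(), 4, 0, seed = 2)
  stk <- simulate_acquisition(fld, frames = 16, noise = noise_model(), seed = 3)
  co <- fit_fourier_stack(stk)
  for (i in 1:8) for (j in 1:8) {
    px <- fit_fourier_pixel(stk$frames[i, j, ], stk$times, stk$cfg)
    expect_equal(c(co$A[i, j], co$B[i, j], co$C[i, j], co$D[i, j]),
                 c(px$A, px$B, px$C, px$D), tolerance = 1e-12)
  }
  # 2x2 stack of identical series gives identical coefficient tuples
  stk2 <- stk
  stk2$frames <- array(rep(stk$frames[1, 1, ], each = 4), dim = c(2, 2, 16))
  co2 <- fit_fourier_stack(stk2)
  expect_equal(max(abs(co2$A - co2$A[1, 1])), 0)
  expect_equal(max(abs(co2$B - co2$B[1, 1])), 0)
  # all-zero frames give all-zero coefficients
  stk3 <- stk2
  stk3$frames[] <- 0
  co3 <- fit_fourier_stack(stk3)
  expect_true(all(co3$A == 0 & co3$B == 0 & co3$C == 0 & co3$D == 0))
})

test_that("Fourier-to-Stokes inversion follows S0=A-C, S1=2C, S2=2D, S3=B", {
  as_img <- function(A, B, C, D) {
    stokes_from_fourier(list(A = matrix(A), B = matrix(B), C = matrix(C),
                             D = matrix(D)))
  }
  img <- as_img(1, 0, 0, 0)
  expect_equal(c(img$S0, img$S1, img$S2, img$S3), c(1, 0, 0, 0))
  img <- as_img(1.5, 0, 0.5, 0)
  expect_equal(c(img$S0, img$S1, img$S2, img$S3), c(1, 1, 0, 0))
  img <- as_img(1, 1, 0, 0)
  expect_equal(c(img$S0, img$S1, img$S2, img$S3), c(1, 0, 0, 1))
  # inversion composed with the forward coefficient mapping is the identity
  set.seed(12)
  S <- random_physical_stokes(100)
  for (i in 1:100) {
    img <- as_img(S[i, 1] + S[i, 2] / 2, S[i, 4], S[i, 2] / 2, S[i, 3] / 2)
    expect_equal(c(img$S0, img$S1, img$S2, img$S3), S[i, ], tolerance = 1e-12)
  }
})

test_that("DOP mask applies strict bounds, the intensity floor, and is monotone", {
  S0 <- matrix(c(1, 1, 1, 1, 0.01, 0), 2, 3)
  S3 <- matrix(c(0.7, 1.2, 0, 0.5, 0.007, 0), 2, 3)
  img <- structure(list(S0 = S0, S1 = S0 * 0, S2 = S0 * 0, S3 = S3,
                        dop = sqrt(S3^2) / S0, valid = NULL,
                        normalized = FALSE), class = "stokes_image")
  img$dop[S0 == 0] <- NA
  m <- dop_mask(img, min_intensity = NULL)
  expect_true(m$valid[1, 1])    # DOP 0.7 kept
  expect_false(m$valid[2, 1])   # DOP 1.2 excluded (>= 100% rule)
  expect_false(m$valid[1, 2])   # DOP exactly 0 excluded (<= 0% rule)
  expect_false(m$valid[2, 3])   # S0 = 0 undefined -> excluded
  expect_true(m$valid[1, 3])    # dim pixel survives without a floor...
  m_auto <- dop_mask(img, min_intensity = "auto")
  expect_false(m_auto$valid[1, 3])  # ...but not with the default 5% floor
  # shrinking the window never adds pixels
  wide <- dop_mask(img, 0, 1, min_intensity = NULL)$valid
  narrow <- dop_mask(img, 0.3, 0.9, min_intensity = NULL)$valid
  expect_true(all(narrow <= wide))
})

test_that("normalization rescales valid pixels, is idempotent, and guards S0 <= 0", {
  S0 <- matrix(c(2, 1, -0.1, 4), 2, 2)
  img <- structure(list(S0 = S0, S1 = matrix(c(1, 0, 0, 2), 2, 2),
                        S2 = matrix(0, 2, 2),
                        S3 = matrix(c(0.5, 0, 0, 1), 2, 2),
                        dop = abs(matrix(c(0.56, 0, 0, 0.56), 2, 2)),
                        valid = matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2),
                        normalized = FALSE), class = "stokes_image")
  norm <- normalize_stokes(img)
  expect_equal(norm$S1[1, 1], 0.5)
  expect_equal(norm$S3[1, 1], 0.25)
  expect_equal(norm$S0[2, 2], 1)
  expect_true(is.na(norm$S1[1, 2]))  # invalid pixel -> missing marker
  expect_identical(normalize_stokes(norm), norm)  # idempotent
  img$valid <- NULL
  expect_error(normalize_stokes(img), "S0 <= 0")
})

test_that("initial plate phase is recoverable from a reference acquisition", {
  lm0 <- leaf_model(8, 8, 100,
                    regions = data.frame(
                      ret_scale = c(midrib = 1, vein = 1, lamina = 1),
                      diatten = c(0, 0, 0), depol = c(1, 1, 1),
                      axis_mean = c(0, 0, 0), axis_kappa = c(5, 5, 5)))
  lm0$transmission[] <- 1
  fld <- build_leaf(lm0, growth_model(0, 0, circ_fraction = 0), 0, 0, seed = 1)
  for (phi0 in c(-0.3, 0, 0.21, 0.6)) {
    cfg <- acquisition_config(phi0 = phi0)
    stk <- simulate_acquisition(fld, cfg = cfg, frames = 64, noise = NULL)
    est <- estimate_phi0(stk)
    folded <- phi0 - round(phi0 / (pi / 2)) * (pi / 2)
    expect_equal(est, folded, tolerance = 1e-9)
  }
})
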