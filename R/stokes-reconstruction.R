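#' Fit the rotating-retarder harmonics for one pixel
#'
#' Least-squares fit of the intensity time series to
#' \deqn{I_t = \tfrac12 [A - B \sin 2\theta_t + C \cos 4\theta_t + D \sin 4\theta_t]}
#' with \eqn{\theta_t = \omega t + \varphi_0}. The fit is exact on noiseless
#' data and tolerates non-uniform timestamps (it is a linear model, not an
#' FFT).
#'
#' @param series numeric vector of intensities.
#' @param times frame times (s), same length as `series`.
#' @param cfg an [acquisition_config()] supplying `omega` and `phi0`.
#' @return list with `A`, `B`, `C`, `D` and the residual `rms`.
#' @export
fit_fourier_pixel <- function(series, times, cfg = acquisition_config()) {
  X <- fourier_design(times, cfg)
  fit <- qr(X)
  if (fit$rank < 4) {
    stop("rank-deficient acquisition schedule: ", length(times),
         " frames at angles [", paste(signif(range(cfg$omega * times + cfg$phi0), 4),
                                      collapse = ", "),
         "] rad do not determine all four harmonics")
  }
  beta <- qr.coef(fit, series)
  res <- series - X %*% beta
  list(A = beta[1], B = beta[2], C = beta[3], D = beta[4],
       rms = sqrt(mean(res^2)))
}

fourier_design <- function(times, cfg) {
  theta <- cfg$omega * times + cfg$phi0
  0.5 * cbind(1, -sin(2 * theta), cos(4 * theta), sin(4 * theta))
}

#' Fit the harmonics for every pixel of a stack
#'
#' Vectorized equivalent of looping [fit_fourier_pixel()] over pixels: one QR
#' factorization of the shared design matrix, applied to all pixels at once.
#'
#' @param stack an `intensity_stack`.
#' @return object of class `fourier_coefficients`: list of H x W maps `A`,
#'   `B`, `C`, `D` and per-pixel residual `rms`.
#' @export
fit_fourier_stack <- function(stack) {
  stopifnot(inherits(stack, "intensity_stack"))
  d <- dim(stack$frames)
  h <- d[1]; w <- d[2]; T_ <- d[3]
  X <- fourier_design(stack$times, stack$cfg)
  fit <- qr(X)
  if (fit$rank < 4) {
    stop("rank-deficient acquisition schedule: ", T_,
         " frames do not determine all four harmonics")
  }
  Y <- matrix(aperm(stack$frames, c(3, 1, 2)), nrow = T_)  # T x (H*W)
  beta <- qr.coef(fit, Y)                                  # 4 x (H*W)
  res <- Y - X %*% beta
  shape <- function(v) matrix(v, h, w)
  structure(list(A = shape(beta[1, ]), B = shape(beta[2, ]),
                 C = shape(beta[3, ]), D = shape(beta[4, ]),
                 rms = shape(sqrt(colMeans(res^2)))),
            class = "fourier_coefficients")
}

#' Stokes images from fitted harmonic coefficients
#'
#' Inverts the harmonic expansion:
#' `S0 = A - C`, `S1 = 2C`, `S2 = 2D`, `S3 = B`.
#'
#' @param coeffs a `fourier_coefficients` object (or a list with `A`, `B`,
#'   `C`, `D`).
#' @return an object of class `stokes_image` with per-pixel maps `S0`..`S3`
#'   and `dop`; not yet masked or normalized.
#' @export
stokes_from_fourier <- function(coeffs) {
  S0 <- coeffs$A - coeffs$C
  S1 <- 2 * coeffs$C
  S2 <- 2 * coeffs$D
  S3 <- coeffs$B
  dop <- sqrt(S1^2 + S2^2 + S3^2) / S0
  dop[S0 == 0] <- NA_real_
  structure(list(S0 = S0, S1 = S1, S2 = S2, S3 = S3, dop = dop,
                 valid = NULL, normalized = FALSE),
            class = "stokes_image")
}

#' @export
print.stokes_image <- function(x, ...) {
  d <- dim(as.matrix(x$S0))
  cat("Stokes image", d[1], "x", d[2], "px;",
      if (is.null(x$valid)) "unmasked" else
        paste0(sum(x$valid), " valid px (", signif(100 * mean(x$valid), 3), "%)"),
      ";", if (x$normalized) "normalized (S0 = 1)" else "unnormalized", "\n")
  invisible(x)
}

#' Mask pixels by degree of polarization
#'
#' Keeps pixels with `lo < DOP < hi` (strict inequalities, so DOP of exactly
#' 0 or 1 and unphysical values outside are excluded) and, when an intensity
#' floor is in effect, `S0 > min_intensity`. Nearly all abnormal-DOP pixels
#' in practice are dim beam-edge pixels, so the default floor is 5% of the
#' median positive S0.
#'
#' @param image a `stokes_image`.
#' @param lo,hi strict DOP bounds (defaults 0 and 1).
#' @param min_intensity intensity floor; `"auto"` (default) uses 5% of the
#'   median of positive S0, `NULL` disables the floor.
#' @return the image with its `valid` mask set (and the mask invisibly
#'   retrievable as `image$valid`).
#' @export
dop_mask <- function(image, lo = 0, hi = 1, min_intensity = "auto") {
  stopifnot(inherits(image, "stokes_image"), lo < hi)
  floor_val <- -Inf
  if (identical(min_intensity, "auto")) {
    pos <- image$S0[image$S0 > 0]
    if (length(pos)) floor_val <- 0.05 * stats::median(pos)
  } else if (!is.null(min_intensity)) {
    floor_val <- min_intensity
  }
  valid <- !is.na(image$dop) & image$dop > lo & image$dop < hi &
    image$S0 > floor_val
  valid[is.na(valid)] <- FALSE
  image$valid <- valid
  image
}

#' Normalize a Stokes image to S0 = 1
#'
#' Divides every valid pixel by its S0 so the components become the
#' normalized (s1, s2, s3); invalid pixels are set to `NA`. Idempotent.
#'
#' @param image a masked `stokes_image`.
#' @return the normalized image (`normalized = TRUE`).
#' @export
normalize_stokes <- function(image) {
  stopifnot(inherits(image, "stokes_image"))
  if (image$normalized) return(image)
  if (is.null(image$valid)) {
    if (any(image$S0 <= 0)) {
      stop("cannot normalize an unmasked image containing S0 <= 0 pixels; ",
           "apply dop_mask() first")
    }
    image$valid <- matrix(TRUE, nrow(image$S0), ncol(image$S0))
  }
  v <- image$valid
  for (comp in c("S1", "S2", "S3")) {
    m <- image[[comp]]
    m[v] <- m[v] / image$S0[v]
    m[!v] <- NA_real_
    image[[comp]] <- m
  }
  s0 <- image$S0
  s0[v] <- 1
  s0[!v] <- NA_real_
  image$S0 <- s0
  image$dop[!v] <- NA_real_
  image$normalized <- TRUE
  image
}

#' Reconstruct a Stokes image from an intensity stack
#'
#' Convenience chain: [fit_fourier_stack()] then [stokes_from_fourier()],
#' [dop_mask()] and [normalize_stokes()].
#'
#' @param stack an `intensity_stack`.
#' @param dop_lo,dop_hi strict DOP bounds.
#' @param min_intensity intensity floor passed to [dop_mask()].
#' @return a masked, normalized `stokes_image`.
#' @export
reconstruct_stokes <- function(stack, dop_lo = 0, dop_hi = 1,
                               min_intensity = "auto") {
  img <- stokes_from_fourier(fit_fourier_stack(stack))
  img <- dop_mask(img, lo = dop_lo, hi = dop_hi, min_intensity = min_intensity)
  normalize_stokes(img)
}

#' Estimate the initial QWP phase from a reference acquisition
#'
#' With no sample in the beam the exit state is the input polarizer state, so
#' the detected harmonics have a known phase; fitting the stack against a
#' free-phase harmonic basis recovers `phi0`. Used when acquisition metadata
#' lacks the initial plate phase.
#'
#' @param stack reference `intensity_stack` acquired with no sample.
#' @param reference_state known exit Stokes vector (default: the 135-degree
#'   input polarizer state).
#' @return estimated `phi0` in radians, in (-pi/4, pi/4\] (the 4-theta
#'   harmonic determines it modulo pi/2).
#' @export
estimate_phi0 <- function(stack,
                          reference_state = c(1, 0, -1, 0)) {
  stopifnot(inherits(stack, "intensity_stack"))
  theta <- stack$cfg$omega * stack$times   # phase-free angles
  T_ <- length(theta)
  Y <- rowMeans(matrix(aperm(stack$frames, c(3, 1, 2)), nrow = T_))
  X <- cbind(1, sin(2 * theta), cos(2 * theta), sin(4 * theta), cos(4 * theta))
  b <- qr.coef(qr(X), Y)
  Dref <- reference_state[3] / 2
  Cref <- reference_state[2] / 2
  if (abs(Dref) < 1e-12 && abs(Cref) < 1e-12) {
    stop("reference state has no 4-theta harmonic; cannot estimate phi0")
  }
  # I = .. + (C/2) cos(4 theta + 4 phi0) + (D/2) sin(4 theta + 4 phi0)
  # expand and match the fitted sin/cos 4-theta amplitudes
  ref_phase <- atan2(Cref, Dref)
  fit_phase <- atan2(b[5], b[4])
  phi0 <- (fit_phase - ref_phase) / 4
  # fold into (-pi/4, pi/4]
  phi0 <- phi0 - round(phi0 / (pi / 2)) * (pi / 2)
  phi0
}
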