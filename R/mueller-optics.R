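#' Ideal linear polarizer Mueller matrix
#'
#' Returns the 4x4 Mueller matrix of an ideal (unit-transmittance) linear
#' polarizer with its transmission axis at `angle` radians from horizontal.
#' The matrix is a projector: `M %*% M == M`.
#'
#' @param angle transmission-axis angle in radians.
#' @return a 4x4 numeric matrix.
#' @examples
#' polarizer_mueller(0)                    # horizontal polarizer
#' polarizer_mueller(deg2rad(135))         # the fixed input polarizer
#' @export
polarizer_mueller <- function(angle) {
  stopifnot(is.finite(angle))
  c2 <- cos(2 * angle)
  s2 <- sin(2 * angle)
  0.5 * matrix(c(
    1,       c2,       s2,      0,
    c2,      c2^2,     c2 * s2, 0,
    s2,      c2 * s2,  s2^2,    0,
    0,       0,        0,       0
  ), nrow = 4, byrow = TRUE)
}

#' Linear retarder Mueller matrix
#'
#' Unit-transmittance linear retarder with retardance `retardance` (radians)
#' and fast axis at `fast_axis` radians. The handedness convention is fixed so
#' that the rotating-quarter-wave-plate + horizontal-analyzer chain produces a
#' detected intensity of the form
#' \deqn{I = \tfrac12 [A - B\sin 2\theta + C\cos 4\theta + D\sin 4\theta]}
#' with \eqn{B = S_3} (see [detector_intensity()]). Determinant is +1 and both
#' total intensity and degree of polarization are preserved.
#'
#' @param retardance retardance in radians (pi/2 for a quarter-wave plate).
#' @param fast_axis fast-axis angle in radians.
#' @return a 4x4 numeric matrix.
#' @export
retarder_mueller <- function(retardance, fast_axis = 0) {
  stopifnot(is.finite(retardance), is.finite(fast_axis))
  C <- cos(2 * fast_axis)
  S <- sin(2 * fast_axis)
  cd <- cos(retardance)
  sd <- sin(retardance)
  matrix(c(
    1, 0,                 0,                 0,
    0, C^2 + S^2 * cd,    C * S * (1 - cd),  -S * sd,
    0, C * S * (1 - cd),  S^2 + C^2 * cd,    C * sd,
    0, S * sd,            -C * sd,           cd
  ), nrow = 4, byrow = TRUE)
}

#' Circular retarder (rotator) Mueller matrix
#'
#' Pure circular retardance `cr` (radians): a rotation of the linear
#' polarization components (S1, S2) by `cr`, leaving S3 untouched. Models
#' optical rotation, e.g. from chiral solutes.
#'
#' @param cr circular retardance in radians.
#' @return a 4x4 numeric matrix.
#' @export
circular_retarder_mueller <- function(cr) {
  stopifnot(is.finite(cr))
  matrix(c(
    1, 0,        0,       0,
    0, cos(cr),  sin(cr), 0,
    0, -sin(cr), cos(cr), 0,
    0, 0,        0,       1
  ), nrow = 4, byrow = TRUE)
}

#' Diagonal depolarizer Mueller matrix
#'
#' `diag(1, p1, p2, p3)`: each polarized component is shrunk by its factor, so
#' applying the matrix to a state of degree of polarization p with equal
#' factors yields DOP `p1 * p`.
#'
#' @param p1,p2,p3 depolarization factors in \[0, 1\].
#' @return a 4x4 numeric matrix.
#' @export
depolarizer_mueller <- function(p1, p2 = p1, p3 = p1) {
  if (any(c(p1, p2, p3) < 0) || any(c(p1, p2, p3) > 1)) {
    stop("depolarization factors must lie in [0, 1]")
  }
  diag(c(1, p1, p2, p3))
}

#' Linear diattenuator Mueller matrix
#'
#' Partial polarizer with diattenuation `d` in \[0, 1\] and transmission axis
#' `angle`: `d = 0` is the identity, `d = 1` the ideal polarizer. Mean
#' transmittance is kept at 1 so diattenuation does not change beam-averaged
#' intensity.
#'
#' @param d diattenuation magnitude in \[0, 1\].
#' @param angle transmission-axis angle in radians.
#' @return a 4x4 numeric matrix.
#' @export
diattenuator_mueller <- function(d, angle = 0) {
  if (d < 0 || d > 1) stop("diattenuation must lie in [0, 1]")
  c2 <- cos(2 * angle)
  s2 <- sin(2 * angle)
  a <- sqrt(1 - d^2)
  # axis-frame diattenuator, then rotate into the lab frame
  m <- matrix(c(
    1, d,  0, 0,
    d, 1,  0, 0,
    0, 0,  a, 0,
    0, 0,  0, a
  ), nrow = 4, byrow = TRUE)
  R <- rotation_mueller(angle)
  Rm <- rotation_mueller(-angle)
  Rm %*% m %*% R
}

# Frame rotation in Stokes space by `angle` (radians, physical axis angle).
rotation_mueller <- function(angle) {
  c2 <- cos(2 * angle)
  s2 <- sin(2 * angle)
  matrix(c(
    1, 0,   0,  0,
    0, c2,  s2, 0,
    0, -s2, c2, 0,
    0, 0,   0,  1
  ), nrow = 4, byrow = TRUE)
}

#' Apply a Mueller matrix to a Stokes vector
#'
#' @param M 4x4 Mueller matrix.
#' @param S Stokes vector `c(S0, S1, S2, S3)`, or a 4-row matrix of vectors.
#' @return the transformed Stokes vector(s), same shape as `S`.
#' @export
apply_mueller <- function(M, S) {
  stopifnot(is.matrix(M), all(dim(M) == c(4, 4)))
  if (is.matrix(S)) {
    stopifnot(nrow(S) == 4)
    M %*% S
  } else {
    stopifnot(length(S) == 4)
    drop(M %*% S)
  }
}

#' Degree of polarization
#'
#' `DOP = sqrt(S1^2 + S2^2 + S3^2) / S0`; 0 for unpolarized light, 1 for fully
#' polarized light. Values above 1 are unphysical and arise from noise.
#'
#' @param S Stokes vector or 4-row matrix of Stokes vectors.
#' @return numeric DOP value(s). `S0 == 0` is an invalid-pixel condition and
#'   signals an error for a single vector; for matrix input such columns
#'   return `NA` so the caller can mask them.
#' @export
degree_of_polarization <- function(S) {
  if (is.matrix(S)) {
    stopifnot(nrow(S) == 4)
    dop <- sqrt(S[2, ]^2 + S[3, ]^2 + S[4, ]^2) / S[1, ]
    dop[S[1, ] == 0] <- NA_real_
    return(dop)
  }
  stopifnot(length(S) == 4)
  if (S[1] == 0) stop("S0 = 0: degree of polarization undefined (invalid pixel)")
  sqrt(S[2]^2 + S[3]^2 + S[4]^2) / S[1]
}

#' Polarization-ellipse parameters of a Stokes vector
#'
#' Converts a polarized Stokes vector to its ellipse representation: azimuth
#' `psi` in \[0, pi), ellipticity angle `chi` in \[-pi/4, pi/4\], and degree of
#' polarization `p`. On the Poincare sphere the state sits at longitude
#' `2*psi` and latitude `2*chi`. The inverse mapping is
#' `s1 = p cos2chi cos2psi`, `s2 = p cos2chi sin2psi`, `s3 = p sin2chi`.
#'
#' @param S Stokes vector with `DOP > 0`.
#' @return list with elements `psi`, `chi`, `p`.
#' @export
ellipse_params <- function(S) {
  p <- degree_of_polarization(S)
  if (p == 0) stop("DOP = 0: azimuth undefined for unpolarized light")
  s <- S[2:4] / S[1] / p  # unit Poincare direction
  chi <- 0.5 * asin(max(-1, min(1, s[3])))
  if (abs(s[1]) < 1e-15 && abs(s[2]) < 1e-15) {
    psi <- 0  # circular state: azimuth unconstrained, report 0
  } else {
    psi <- 0.5 * atan2(s[2], s[1])
    if (psi < 0) psi <- psi + pi
    if (psi >= pi) psi <- psi - pi
  }
  list(psi = psi, chi = chi, p = p)
}

#' Stokes vector from ellipse parameters
#'
#' Inverse of [ellipse_params()] for a normalized state (`S0 = 1`).
#'
#' @param psi azimuth in radians.
#' @param chi ellipticity angle in radians.
#' @param p degree of polarization.
#' @return Stokes vector `c(1, s1, s2, s3)`.
#' @export
stokes_from_ellipse <- function(psi, chi, p = 1) {
  c(1,
    p * cos(2 * chi) * cos(2 * psi),
    p * cos(2 * chi) * sin(2 * psi),
    p * sin(2 * chi))
}

#' Acquisition configuration for the rotating-retarder polarimeter
#'
#' Bundles the optical-train parameters of the acquisition: quarter-wave-plate
#' angular speed `omega` (rad/s), initial plate phase `phi0` (rad), plate
#' retardance `delta` (rad, pi/2 for an ideal quarter-wave plate), analyzer
#' transmission-axis angle `alpha` (rad) and the fixed input-polarizer angle
#' (rad, default 135 degrees).
#'
#' @param omega QWP angular speed in rad/s (default 20).
#' @param phi0 initial QWP phase in radians.
#' @param delta QWP retardance in radians.
#' @param alpha analyzer angle in radians.
#' @param input_polarizer_angle source polarizer angle in radians.
#' @return an object of class `acquisition_config`.
#' @export
acquisition_config <- function(omega = 20, phi0 = 0, delta = pi / 2,
                               alpha = 0, input_polarizer_angle = deg2rad(135)) {
  stopifnot(omega > 0, is.finite(phi0), is.finite(delta), is.finite(alpha))
  structure(list(omega = omega, phi0 = phi0, delta = delta, alpha = alpha,
                 input_polarizer_angle = input_polarizer_angle),
            class = "acquisition_config")
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat("Acquisition: omega =", x$omega, "rad/s, phi0 =", x$phi0,
      "rad, delta =", signif(x$delta, 4), "rad, alpha =",
      rad2deg(x$alpha), "deg, input polarizer =",
      rad2deg(x$input_polarizer_angle), "deg\n")
  invisible(x)
}

#' Detected intensity behind the rotating quarter-wave plate
#'
#' Closed-form detector intensity for light of Stokes vector `S_exit`
#' (the state leaving the sample) passing through the rotating retarder at
#' angle `theta = omega * t + phi0` and the analyzer at `alpha = 0`:
#' \deqn{I = \tfrac12 [A - B\sin 2\theta + C\cos 4\theta + D\sin 4\theta]}
#' with `A = S0 + S1/2`, `B = S3`, `C = S1/2`, `D = S2/2`. This equals the
#' explicit Mueller-chain intensity `analyzer(alpha) . retarder(delta, theta)`
#' when `delta = pi/2`; for a non-ideal plate retardance the chain form is
#' used.
#'
#' @param S_exit Stokes vector after the sample.
#' @param qwp_angle retarder fast-axis angle(s) `theta` in radians.
#' @param cfg an [acquisition_config()].
#' @return detected intensity (vectorized over `qwp_angle`).
#' @export
detector_intensity <- function(S_exit, qwp_angle, cfg = acquisition_config()) {
  stopifnot(length(S_exit) == 4)
  if (abs(cfg$delta - pi / 2) < 1e-12 && abs(cfg$alpha) < 1e-12) {
    A <- S_exit[1] + S_exit[2] / 2
    B <- S_exit[4]
    C <- S_exit[2] / 2
    D <- S_exit[3] / 2
    0.5 * (A - B * sin(2 * qwp_angle) + C * cos(4 * qwp_angle) +
             D * sin(4 * qwp_angle))
  } else {
    P <- polarizer_mueller(cfg$alpha)
    vapply(qwp_angle, function(th) {
      (P %*% retarder_mueller(cfg$delta, th) %*% S_exit)[1]
    }, numeric(1))
  }
}

#' Read or write a Mueller matrix as 4x4 CSV
#'
#' Plain row-major 4x4 CSV, no header; the interchange format for measured
#' Mueller matrices.
#'
#' @param path file path.
#' @param M 4x4 matrix to write.
#' @return `read_mueller_csv` returns a 4x4 matrix; `write_mueller_csv`
#'   returns `path` invisibly.
#' @export
read_mueller_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  # tolerate an optional header row of non-numeric labels
  if (any(is.na(suppressWarnings(as.numeric(m[1, ]))))) {
    m <- m[-1, , drop = FALSE]
  }
  m <- matrix(as.numeric(m), nrow = 4, ncol = 4,
              byrow = FALSE)
  dimnames(m) <- NULL
  if (any(!is.finite(m))) stop("non-finite entries in Mueller CSV: ", path)
  m
}

#' @rdname read_mueller_csv
#' @export
write_mueller_csv <- function(M, path) {
  stopifnot(is.matrix(M), all(dim(M) == c(4, 4)))
  utils::write.table(M, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
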