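#' Convert degrees to radians
#'
#' Acquisition geometry is specified in degrees in most lab notebooks while all
#' internal angle arithmetic is in radians; these helpers convert between the
#' two.
#'
#' @param x angle(s) in degrees (`deg2rad`) or radians (`rad2deg`).
#' @return numeric vector of converted angles.
#' @export
deg2rad <- function(x) x * pi / 180

#' @rdname deg2rad
#' @export
rad2deg <- function(x) x * 180 / pi

# Draw from a von Mises distribution (Best & Fisher 1979 rejection sampler).
# Used for per-pixel retarder axis orientations; kappa = 0 falls back to a
# uniform draw on (-pi, pi].
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) {
    return(stats::runif(n, -pi, pi) + mu)
  }
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    u2 <- stats::runif(m)
    keep <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    nk <- sum(keep)
    if (nk > 0) {
      u3 <- stats::runif(nk)
      theta <- sign(u3 - 0.5) * acos(f[keep])
      out[(got + 1L):(got + nk)] <- theta
      got <- got + nk
    }
  }
  out + mu
}

# Derive a reproducible 32-bit sub-seed from a base seed and an index.
# Simple splitmix-style integer hash, kept below 2^31.
derive_seed <- function(seed, index) {
  x <- (as.double(seed) * 2654435761 + as.double(index) * 40503 + 12345) %% 2147483647
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
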