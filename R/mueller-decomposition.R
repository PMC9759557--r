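#' Diattenuation components of a Mueller matrix
#'
#' From the first row of `M / m00`: total diattenuation
#' `D = |(m01, m02, m03)| / m00`, linear part
#' `LD = sqrt(m01^2 + m02^2) / m00`, circular part `CD = |m03| / m00`;
#' `D^2 = LD^2 + CD^2` by construction.
#'
#' @param M 4x4 Mueller matrix with `M[1, 1] > 0`.
#' @return list with `D`, `LD`, `CD`.
#' @export
diattenuation_components <- function(M) {
  stopifnot(is.matrix(M), all(dim(M) == c(4, 4)))
  if (!(M[1, 1] > 0)) stop("M[1, 1] must be positive")
  v <- M[1, 2:4] / M[1, 1]
  list(D = sqrt(sum(v^2)), LD = sqrt(v[1]^2 + v[2]^2), CD = abs(v[3]))
}

#' Retardance components of a pure retarder Mueller matrix
#'
#' For a retarder (3x3 rotation block, det +1): total retardance
#' `R = arccos((tr(m_R) - 1) / 2)` in `[0, pi]`; linear retardance
#' `LR = arccos(sqrt((m11+m22)^2 + (m21-m12)^2) - 1)`; circular retardance
#' (twice the optical rotation angle) `CR = atan2(m12 - m21, m11 + m22)`.
#' These satisfy `cos R = 2 cos^2(LR/2) cos^2(CR/2) - 1`.
#'
#' @param M_R 4x4 retarder Mueller matrix.
#' @param tol orthogonality tolerance for the 3x3 block.
#' @return list with `R`, `LR`, `CR` (radians).
#' @export
retardance_components <- function(M_R, tol = 1e-6) {
  stopifnot(is.matrix(M_R), all(dim(M_R) == c(4, 4)))
  m <- M_R[2:4, 2:4]
  if (max(abs(m %*% t(m) - diag(3))) > tol || det(m) < 1 - tol) {
    stop("retarder block is not a proper rotation within tolerance ", tol)
  }
  clamp <- function(x) pmax(-1, pmin(1, x))
  R <- acos(clamp((sum(diag(m)) - 1) / 2))
  LR <- acos(clamp(sqrt((m[1, 1] + m[2, 2])^2 + (m[2, 1] - m[1, 2])^2) - 1))
  CR <- atan2(m[1, 2] - m[2, 1], m[1, 1] + m[2, 2])
  list(R = R, LR = LR, CR = CR)
}

#' Lu-Chipman polar decomposition of a Mueller matrix
#'
#' Factors `M = M_Delta %*% M_R %*% M_D` into a depolarizer, a retarder and a
#' diattenuator (the classic order for transmission polarimetry), and reports
#' the scalar summaries: diattenuation `D`, `LD`, `CD`; retardance `R`, `LR`,
#' `CR`; depolarization index `delta_index` (0 = none). Mildly non-physical
#' inputs (noise-inflated diattenuation, slightly negative depolarizer
#' eigenvalues) are warned about and clipped; an exactly singular
#' diattenuator (`D = 1`) is handled by its limit, identity retarder and
#' depolarizer.
#'
#' @param M 4x4 Mueller matrix, `M[1, 1] > 0`, finite entries.
#' @return object of class `polar_decomposition`: list with factors `M_D`,
#'   `M_R`, `M_Delta` and the scalar summaries.
#' @export
lu_chipman <- function(M) {
  stopifnot(is.matrix(M), all(dim(M) == c(4, 4)))
  if (any(!is.finite(M))) stop("non-finite entries in Mueller matrix")
  m00 <- M[1, 1]
  if (!(m00 > 0)) stop("M[1, 1] must be positive")

  dvec <- M[1, 2:4] / m00
  D <- sqrt(sum(dvec^2))
  if (D > 1) {
    if (D > 1 + 1e-3) {
      warning("diattenuation ", signif(D, 4), " > 1: non-physical input, clipping")
    }
    dvec <- dvec / D * (1 - 1e-12)
    D <- 1 - 1e-12
  }
  dia <- diattenuation_components(M)

  if (1 - D < 1e-9) {
    # singular diattenuator: M is (the limit of) a pure polarizer times the
    # rest; retarder and depolarizer go to identity
    dec <- list(M_D = M / m00, M_R = diag(4), M_Delta = diag(4),
                D = dia$D, LD = dia$LD, CD = dia$CD,
                R = 0, LR = 0, CR = 0, delta_index = 0, m00 = m00)
    return(structure(dec, class = "polar_decomposition"))
  }

  a <- sqrt(1 - D^2)
  dhat <- if (D > 0) dvec / D else c(1, 0, 0)
  mD <- a * diag(3) + (1 - a) * (dhat %o% dhat)
  M_D <- rbind(c(1, dvec), cbind(dvec, mD))

  Mp <- (M / m00) %*% solve(M_D)
  mprime <- Mp[2:4, 2:4]
  p_delta <- Mp[2:4, 1]

  mm <- mprime %*% t(mprime)
  ev <- eigen(mm, symmetric = TRUE)
  lam <- ev$values
  if (min(lam) < -1e-3) {
    warning("depolarizer eigenvalue ", signif(min(lam), 4),
            " < 0: non-physical input, clipping")
  }
  lam <- pmax(lam, 0)
  s <- sqrt(lam)
  detm <- det(mprime)
  sgn <- if (detm < 0) -1 else 1
  if (all(s < 1e-12)) {
    m_delta <- matrix(0, 3, 3)          # total depolarizer
    m_R <- diag(3)
  } else {
    m_delta <- sgn * solve(mm + (s[1] * s[2] + s[2] * s[3] + s[3] * s[1]) * diag(3)) %*%
      ((s[1] + s[2] + s[3]) * mm + s[1] * s[2] * s[3] * diag(3))
    m_R <- solve(m_delta) %*% mprime
  }
  M_Delta <- rbind(c(1, 0, 0, 0), cbind(p_delta, m_delta))
  M_R <- rbind(c(1, 0, 0, 0), cbind(c(0, 0, 0), m_R))
  dimnames(M_D) <- dimnames(M_Delta) <- dimnames(M_R) <- NULL

  ret <- tryCatch(retardance_components(M_R, tol = 1e-3),
                  error = function(e) {
                    # re-orthogonalize via SVD polar projection and retry
                    sv <- svd(m_R)
                    mr2 <- sv$u %*% t(sv$v)
                    retardance_components(rbind(c(1, 0, 0, 0),
                                                cbind(c(0, 0, 0), mr2)))
                  })
  delta_index <- 1 - mean(abs(eigen((m_delta + t(m_delta)) / 2, symmetric = TRUE,
                                    only.values = TRUE)$values))

  structure(list(M_D = M_D, M_R = M_R, M_Delta = M_Delta,
                 D = dia$D, LD = dia$LD, CD = dia$CD,
                 R = ret$R, LR = ret$LR, CR = ret$CR,
                 delta_index = delta_index, m00 = m00),
            class = "polar_decomposition")
}

#' @export
print.polar_decomposition <- function(x, ...) {
  cat(sprintf(paste0("Lu-Chipman decomposition: D = %.4f (LD %.4f, CD %.4f); ",
                     "R = %.4f rad (LR %.4f, CR %.4f); depolarization %.4f\n"),
              x$D, x$LD, x$CD, x$R, x$LR, x$CR, x$delta_index))
  invisible(x)
}

#' Reconstruct the input from a polar decomposition
#'
#' @param dec a `polar_decomposition`.
#' @return the 4x4 product `m00 * M_Delta %*% M_R %*% M_D`.
#' @export
reconstruct_mueller <- function(dec) {
  stopifnot(inherits(dec, "polar_decomposition"))
  dec$m00 * dec$M_Delta %*% dec$M_R %*% dec$M_D
}
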