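# Random fully polarized Stokes vectors (unit DOP, random overall intensity)
random_polarized_stokes <- function(n, intensity = 1) {
  t(vapply(seq_len(n), function(i) {
    stokes_from_ellipse(stats::runif(1, 0, pi),
                        stats::runif(1, -pi / 4, pi / 4)) * intensity
  }, numeric(4)))
}

# Random physical (possibly partially polarized) Stokes vectors
random_physical_stokes <- function(n) {
  t(vapply(seq_len(n), function(i) {
    stokes_from_ellipse(stats::runif(1, 0, pi), stats::runif(1, -pi / 4, pi / 4),
                        p = stats::runif(1)) * stats::runif(1, 0.2, 2)
  }, numeric(4)))
}

# Random non-depolarizing Mueller matrix: retarders and a weak diattenuator
random_nondepolarizing_mueller <- function() {
  retarder_mueller(stats::runif(1, 0, pi), stats::runif(1, 0, pi)) %*%
    circular_retarder_mueller(stats::runif(1, -1, 1)) %*%
    diattenuator_mueller(stats::runif(1, 0, 0.9), stats::runif(1, 0, pi))
}

# Random physical factor product M_Delta . M_R . M_D with known components
random_polar_factors <- function() {
  d <- stats::runif(1, 0, 0.8)
  th_d <- stats::runif(1, 0, pi)
  lr <- stats::runif(1, 0.1, pi - 0.1)
  th_r <- stats::runif(1, 0, pi)
  cr <- stats::runif(1, -1.2, 1.2)
  p <- stats::runif(3, 0.4, 1)
  M_D <- diattenuator_mueller(d, th_d)
  M_R <- circular_retarder_mueller(cr) %*% retarder_mueller(lr, th_r)
  M_Delta <- depolarizer_mueller(p[1], p[2], p[3])
  list(M = M_Delta %*% M_R %*% M_D, M_D = M_D, M_R = M_R, M_Delta = M_Delta,
       d = d, lr = lr, cr = cr, p = p)
}

# Tiny leaf/study fixtures used across reconstruction and pipeline tests
tiny_leaf <- function(px = 32, beam = 12) leaf_model(px, px, beam)

tiny_config <- function(seed = 5L) {
  pipeline_config(design = study_design(c(0, 400), c(0, 10), 2, seed = seed),
                  leaf = tiny_leaf(), seed = seed)
}

# Build a masked normalized Stokes image directly from component maps
stokes_image_from_maps <- function(s1, s2, s3) {
  img <- structure(list(S0 = matrix(1, nrow(s1), ncol(s1)),
                        S1 = s1, S2 = s2, S3 = s3,
                        dop = sqrt(s1^2 + s2^2 + s3^2),
                        valid = matrix(TRUE, nrow(s1), ncol(s1)),
                        normalized = TRUE),
                   class = "stokes_image")
  img
}
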