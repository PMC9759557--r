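#' Extract |s3| samples from a Stokes image
#'
#' The absolute circular-polarization component over all valid pixels of a
#' masked, normalized image, in row-major pixel order. |s3| folds the
#' two-sided s3 distribution into a single right tail, which is what the GEV
#' analysis models.
#'
#' @param image a masked, normalized `stokes_image`.
#' @return numeric vector of |s3| values.
#' @export
abs_s3_samples <- function(image) {
  stopifnot(inherits(image, "stokes_image"))
  if (!image$normalized) stop("image must be normalized (see normalize_stokes)")
  if (is.null(image$valid)) stop("image must be masked (see dop_mask)")
  v <- as.vector(t(image$valid))
  if (!any(v)) stop("no valid pixels after masking")
  abs(as.vector(t(image$S3))[v])
}

#' Robust summary: median and median absolute deviation
#'
#' The MAD here is the raw `median(|x - median(x)|)` with no consistency
#' factor.
#'
#' @param samples numeric vector.
#' @return list with `median`, `mad` and `n`.
#' @export
summary_median_mad <- function(samples) {
  x <- samples[is.finite(samples)]
  if (!length(x)) stop("empty sample")
  med <- stats::median(x)
  list(median = med, mad = stats::median(abs(x - med)), n = length(x))
}

#' Compare two samples with a Wilcoxon rank test
#'
#' `rank_sum` is the two-sample Wilcoxon (Mann-Whitney) test and accepts
#' unequal sample sizes; `signed_rank` is the paired Wilcoxon test and
#' requires equal lengths. Ties are mid-ranked. The degenerate paired case in
#' which every difference is zero is reported with `p_value = 1` by
#' convention.
#'
#' @param a,b numeric samples.
#' @param method `"rank_sum"` (default) or `"signed_rank"`.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param exact passed to [stats::wilcox.test()]; default lets it decide.
#' @return list with `statistic`, `p_value`, `method`, `alternative` and
#'   `degenerate`.
#' @export
compare_distributions <- function(a, b, method = c("rank_sum", "signed_rank"),
                                  alternative = "two.sided", exact = NULL) {
  method <- match.arg(method)
  if (method == "signed_rank") {
    if (length(a) != length(b)) {
      stop("signed_rank is a paired test and needs equal lengths (",
           length(a), " vs ", length(b), "); use method = \"rank_sum\" ",
           "for unpaired samples")
    }
    if (all(a - b == 0)) {
      return(list(statistic = 0, p_value = 1, method = method,
                  alternative = alternative, degenerate = TRUE))
    }
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                              alternative = alternative,
                                              exact = exact))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = FALSE,
                                              alternative = alternative,
                                              exact = exact))
  }
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = method, alternative = alternative, degenerate = FALSE)
}

#' Probability density of polarization states on the Poincare sphere
#'
#' Bins each valid pixel's unit Poincare direction `(s1, s2, s3) / p` on an
#' equiangular (azimuth `2 psi`, latitude `2 chi`) grid and converts counts
#' to a density per steradian, so the density integrates to 1 over the
#' sphere.
#'
#' @param image a masked, normalized `stokes_image` (pixels with DOP > 0).
#' @param n_az number of azimuth bins over `[0, 2 pi)`.
#' @param n_lat number of latitude bins over `[-pi/2, pi/2]`.
#' @return object of class `sphere_density`: list with `density` and
#'   `solid_angle` matrices (`n_az` x `n_lat`), bin edges/centers and the
#'   pixel count `n`.
#' @export
poincare_density <- function(image, n_az = 72, n_lat = 36) {
  stopifnot(inherits(image, "stokes_image"), n_az >= 2, n_lat >= 2)
  if (is.null(image$valid)) stop("image must be masked (see dop_mask)")
  v <- image$valid & is.finite(image$dop) & image$dop > 0
  if (!any(v)) stop("no valid polarized pixels")
  s1 <- image$S1[v] / image$S0[v]
  s2 <- image$S2[v] / image$S0[v]
  s3 <- image$S3[v] / image$S0[v]
  p <- sqrt(s1^2 + s2^2 + s3^2)
  az <- atan2(s2 / p, s1 / p) %% (2 * pi)
  lat <- asin(pmax(-1, pmin(1, s3 / p)))

  az_edges <- seq(0, 2 * pi, length.out = n_az + 1)
  lat_edges <- seq(-pi / 2, pi / 2, length.out = n_lat + 1)
  ia <- pmin(findInterval(az, az_edges, rightmost.closed = TRUE), n_az)
  il <- pmin(findInterval(lat, lat_edges, rightmost.closed = TRUE), n_lat)
  counts <- matrix(0, n_az, n_lat)
  tab <- table(factor(ia, levels = 1:n_az), factor(il, levels = 1:n_lat))
  counts[] <- as.numeric(tab)

  d_az <- diff(az_edges)
  band <- diff(sin(lat_edges))
  omega <- outer(d_az, band)               # per-bin solid angle (sr)
  n <- length(az)
  structure(list(density = counts / n / omega, solid_angle = omega,
                 az_edges = az_edges, lat_edges = lat_edges,
                 az_centers = (az_edges[-1] + az_edges[-(n_az + 1)]) / 2,
                 lat_centers = (lat_edges[-1] + lat_edges[-(n_lat + 1)]) / 2,
                 n = n),
            class = "sphere_density")
}

#' Per-image GEV characterisation of |s3|
#'
#' Fits the GEV by maximum likelihood to the valid-pixel |s3| sample of one
#' reconstructed image and records the robust summaries, giving one row of
#' the study fit table.
#'
#' @param image a masked, normalized `stokes_image`.
#' @param ... passed to [gev_fit_mle()].
#' @return one-row data frame with `xi`, `mu`, `sigma`, `loglik`, `n`,
#'   `converged`, `median`, `mad`.
#' @export
characterize_s3 <- function(image, ...) {
  s <- abs_s3_samples(image)
  fit <- gev_fit_mle(s, ...)
  sm <- summary_median_mad(s)
  data.frame(xi = fit$xi, mu = fit$mu, sigma = fit$sigma,
             loglik = fit$loglik, n = fit$n, converged = fit$converged,
             median = sm$median, mad = sm$mad)
}
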