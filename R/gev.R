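#' Generalized extreme value density
#'
#' Density of the GEV family with shape `xi`, location `mu` and scale `sigma`.
#' Writing `s = (x - mu) / sigma`, for `xi != 0` and `1 + xi * s > 0`
#' \deqn{f(x) = \sigma^{-1} (1+\xi s)^{-(1+1/\xi)} \exp[-(1+\xi s)^{-1/\xi}]}
#' and zero outside the support; `xi = 0` is the Gumbel limit
#' \deqn{f(x) = \sigma^{-1} \exp(-s) \exp[-\exp(-s)].}
#'
#' @param x quantiles (vectorized).
#' @param xi shape parameter.
#' @param mu location parameter.
#' @param sigma scale parameter (> 0).
#' @param log if `TRUE`, return log density.
#' @return density values (0, or `-Inf` for `log = TRUE`, outside support).
#' @export
gev_pdf <- function(x, xi = 0, mu = 0, sigma = 1, log = FALSE) {
  if (sigma <= 0) stop("sigma must be positive")
  s <- (x - mu) / sigma
  if (abs(xi) < 1e-9) {
    ld <- -s - exp(-s) - base::log(sigma)
  } else {
    z <- 1 + xi * s
    ld <- ifelse(z > 0,
                 -(1 + 1 / xi) * base::log(pmax(z, .Machine$double.xmin)) -
                   pmax(z, .Machine$double.xmin)^(-1 / xi) - base::log(sigma),
                 -Inf)
  }
  if (log) ld else exp(ld)
}

#' GEV cumulative distribution function
#'
#' @inheritParams gev_pdf
#' @return probabilities.
#' @export
gev_cdf <- function(x, xi = 0, mu = 0, sigma = 1) {
  if (sigma <= 0) stop("sigma must be positive")
  s <- (x - mu) / sigma
  if (abs(xi) < 1e-9) {
    exp(-exp(-s))
  } else {
    z <- 1 + xi * s
    p <- exp(-pmax(z, 0)^(-1 / xi))
    # outside support: 0 below a lower endpoint (xi > 0), 1 above an upper
    # endpoint (xi < 0)
    p[z <= 0] <- if (xi > 0) 0 else 1
    p
  }
}

#' GEV quantile function
#'
#' @param p probabilities in (0, 1).
#' @inheritParams gev_pdf
#' @return quantiles.
#' @export
gev_quantile <- function(p, xi = 0, mu = 0, sigma = 1) {
  if (sigma <= 0) stop("sigma must be positive")
  stopifnot(all(p > 0 & p < 1))
  if (abs(xi) < 1e-9) {
    mu - sigma * base::log(-base::log(p))
  } else {
    mu + sigma * ((-base::log(p))^(-xi) - 1) / xi
  }
}

#' Draw GEV random variates
#'
#' Inverse-transform sampling; deterministic under `set.seed()`.
#'
#' @param n number of draws.
#' @inheritParams gev_pdf
#' @return numeric vector of draws.
#' @export
gev_rand <- function(n, xi = 0, mu = 0, sigma = 1) {
  gev_quantile(stats::runif(n), xi = xi, mu = mu, sigma = sigma)
}

#' Median of a GEV distribution
#'
#' Closed form `mu + sigma * ((log 2)^(-xi) - 1) / xi` (Gumbel limit
#' `mu - sigma * log(log 2)`).
#'
#' @inheritParams gev_pdf
#' @return the distribution median.
#' @export
gev_median <- function(xi = 0, mu = 0, sigma = 1) {
  gev_quantile(0.5, xi = xi, mu = mu, sigma = sigma)
}

# Hosking probability-weighted-moments starting values for the GEV MLE.
gev_pwm_start <- function(x) {
  x <- sort(x)
  n <- length(x)
  j <- seq_len(n)
  b0 <- mean(x)
  b1 <- sum((j - 1) / (n - 1) * x) / n
  b2 <- sum((j - 1) * (j - 2) / ((n - 1) * (n - 2)) * x) / n
  cc <- (2 * b1 - b0) / (3 * b2 - b0) - base::log(2) / base::log(3)
  k <- 7.8590 * cc + 2.9554 * cc^2        # Hosking's k = -xi
  if (abs(k) < 1e-8) {
    sigma <- (2 * b1 - b0) / base::log(2)
    mu <- b0 - 0.5772156649 * sigma
    xi <- 0
  } else {
    sigma <- (2 * b1 - b0) * k / (gamma(1 + k) * (1 - 2^(-k)))
    mu <- b0 + sigma * (gamma(1 + k) - 1) / k
    xi <- -k
  }
  if (!is.finite(sigma) || sigma <= 0) sigma <- stats::sd(x)
  if (!is.finite(mu)) mu <- stats::median(x)
  if (!is.finite(xi)) xi <- 0
  c(xi = xi, mu = mu, sigma = sigma)
}

#' Maximum-likelihood fit of the GEV distribution
#'
#' Maximizes the GEV log likelihood by Nelder-Mead over
#' `(mu, log sigma, xi)`, starting from Hosking's probability-weighted-moments
#' estimates; the support constraint `1 + xi (x - mu) / sigma > 0` is enforced
#' by a likelihood penalty. Deterministic for a given sample.
#'
#' @param samples numeric sample (n >= 50 recommended).
#' @param start optional named start values `c(xi=, mu=, sigma=)`.
#' @param hessian if `TRUE`, also return approximate standard errors from the
#'   numerical Hessian.
#' @return an object of class `gev_fit`: list with `xi`, `mu`, `sigma`,
#'   `loglik`, `n`, `converged` and optional `stderr`.
#' @export
gev_fit_mle <- function(samples, start = NULL, hessian = FALSE) {
  x <- samples[is.finite(samples)]
  if (length(x) < 5) stop("need at least 5 finite observations")
  if (stats::sd(x) == 0) stop("degenerate (constant) sample")
  if (is.null(start)) start <- gev_pwm_start(x)

  nll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2]); xi <- par[3]
    z <- 1 + xi * (x - mu) / sigma
    if (any(z <= 0)) return(1e10)
    -sum(gev_pdf(x, xi = xi, mu = mu, sigma = sigma, log = TRUE))
  }
  p0 <- c(start[["mu"]], base::log(start[["sigma"]]), start[["xi"]])
  # nudge the start inside the support if PWM put it on the boundary
  if (nll(p0) >= 1e10) p0[3] <- 0
  opt <- stats::optim(p0, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12),
                      hessian = hessian)
  est <- c(xi = opt$par[3], mu = opt$par[1], sigma = exp(opt$par[2]))
  stderr <- NULL
  if (hessian) {
    se_t <- tryCatch(sqrt(diag(solve(opt$hessian))), error = function(e) rep(NA_real_, 3))
    # delta method for sigma (fitted on log scale); reorder to xi, mu, sigma
    stderr <- c(xi = se_t[3], mu = se_t[1], sigma = se_t[2] * est[["sigma"]])
  }
  structure(list(xi = est[["xi"]], mu = est[["mu"]], sigma = est[["sigma"]],
                 loglik = -opt$value, n = length(x),
                 converged = opt$convergence == 0, stderr = stderr),
            class = "gev_fit")
}

#' @export
print.gev_fit <- function(x, ...) {
  cat(sprintf("GEV MLE (n = %d%s): xi = %.4f, mu = %.5f, sigma = %.5f, logLik = %.2f\n",
              x$n, if (x$converged) "" else ", NOT converged",
              x$xi, x$mu, x$sigma, x$loglik))
  invisible(x)
}
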