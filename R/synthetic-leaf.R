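#' Virtual leaf geometry and per-region optical parameters
#'
#' Describes the simulated leaf as a labelled pixel grid inside a circular
#' probe beam. Regions (`midrib`, `vein`, `lamina`, `background`) partition the
#' frame; each in-leaf region carries its own optical parameters: a multiplier
#' on the mean linear retardance, diattenuation magnitude, depolarization
#' factor, and the mean/concentration of the retarder fast-axis orientation
#' (von Mises on the doubled angle, since an axis is pi-periodic).
#' Background pixels transmit no light; the beam has a super-Gaussian
#' transmission profile so pixels near the beam edge are dim, which is what
#' drives their exclusion by the DOP filter downstream.
#'
#' @param height,width frame size in pixels.
#' @param beam_radius beam radius in pixels.
#' @param regions data frame of per-region optics; see Details. Rows must be
#'   named `midrib`, `vein`, `lamina`.
#' @details Default region optics: the midrib carries the largest
#'   diattenuation and slightly higher retardance than the lamina, veins sit
#'   in between, mirroring how aligned vascular fibres behave; axis
#'   orientations cluster near the region's fibre direction.
#' @return an object of class `leaf_model`.
#' @export
leaf_model <- function(height = 128, width = 128, beam_radius = 48,
                       regions = NULL) {
  stopifnot(height >= 8, width >= 8, beam_radius > 0)
  if (is.null(regions)) {
    regions <- data.frame(
      ret_scale  = c(midrib = 1.3, vein = 1.1, lamina = 1.0),
      diatten    = c(0.12, 0.04, 0.02),
      depol      = c(0.75, 0.75, 0.75),
      axis_mean  = c(pi / 2, deg2rad(60), deg2rad(50)),
      axis_kappa = c(90, 60, 40)
    )
  }
  stopifnot(all(c("midrib", "vein", "lamina") %in% rownames(regions)))

  # pixel-centre coordinates relative to frame centre
  cx <- (width + 1) / 2
  cy <- (height + 1) / 2
  xs <- matrix(rep(seq_len(width), each = height), nrow = height) - cx
  ys <- matrix(rep(seq_len(height), width), nrow = height) - cy
  r <- sqrt(xs^2 + ys^2)

  region <- matrix("lamina", height, width)
  ang <- atan2(ys, xs)
  region[abs(sin(3 * ang)) < 0.06 & r > 6] <- "vein"   # six radial veins
  region[abs(xs) <= 3] <- "midrib"                     # vertical midrib
  region[r > beam_radius] <- "background"

  transmission <- exp(-(r / beam_radius)^6)            # soft-edged beam
  transmission[region == "background"] <- 0

  structure(list(height = height, width = width, beam_radius = beam_radius,
                 regions = regions, region_map = region,
                 transmission = transmission),
            class = "leaf_model")
}

#' Growth model: leaf retardance versus time and salinity
#'
#' The mean linear retardance of the leaf follows
#' \deqn{\bar\delta(t, c) = \delta_0 + g \, t \, e^{-c / c_0}}
#' nondecreasing in growth time `t` (days) and nonincreasing in NaCl
#' concentration `c` (mM): growing tissue lays down more aligned birefringent
#' material, and salt stress slows that growth. Per-pixel linear retardance is
#' Gamma-distributed with shape `shape` and mean \eqn{\bar\delta}; circular
#' retardance (optical rotation from chiral solutes) is Normal with mean
#' `circ_fraction` times \eqn{\bar\delta}.
#'
#' @param delta0 baseline mean linear retardance (rad) at day 0.
#' @param g growth rate of mean retardance (rad/day).
#' @param salt_scale e-folding NaCl concentration `c0` (mM) of growth
#'   suppression.
#' @param circ_fraction ratio of mean circular to mean linear retardance.
#' @param shape Gamma shape parameter of the per-pixel retardance dispersion.
#' @return an object of class `growth_model`.
#' @export
growth_model <- function(delta0 = 0.15, g = 0.035, salt_scale = 250,
                         circ_fraction = 0.05, shape = 4) {
  stopifnot(delta0 >= 0, g >= 0, salt_scale > 0, circ_fraction >= 0, shape > 0)
  structure(list(delta0 = delta0, g = g, salt_scale = salt_scale,
                 circ_fraction = circ_fraction, shape = shape),
            class = "growth_model")
}

#' Mean linear retardance of the growth model
#'
#' @param growth a [growth_model()].
#' @param day treatment day(s).
#' @param conc NaCl concentration(s), mM.
#' @return mean linear retardance (rad), vectorized.
#' @export
mean_retardance <- function(growth, day, conc) {
  growth$delta0 + growth$g * day * exp(-conc / growth$salt_scale)
}

#' Study design grid
#'
#' Factorial design of NaCl concentration x treatment day x replicate,
#' defaulting to the 5 x 6 x 5 layout of the salt-stress experiment
#' (0/100/200/300/400 mM, days 0--10 every 2 days, five replicates).
#'
#' @param concentrations NaCl concentrations in mM.
#' @param days treatment days.
#' @param replicates number of replicates per cell.
#' @param seed base seed; per-stack sub-seeds are derived from it.
#' @return an object of class `study_design` (a data frame of design rows
#'   with derived per-stack seeds, plus attributes).
#' @export
study_design <- function(concentrations = c(0, 100, 200, 300, 400),
                         days = c(0, 2, 4, 6, 8, 10),
                         replicates = 5, seed = 1L) {
  stopifnot(length(concentrations) > 0, length(days) > 0, replicates >= 1,
            all(concentrations >= 0), all(days >= 0))
  grid <- expand.grid(replicate = seq_len(replicates), day = days,
                      concentration_mM = concentrations,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("concentration_mM", "day", "replicate")]
  grid$seed <- derive_seed(seed, seq_len(nrow(grid)))
  structure(grid, class = c("study_design", "data.frame"),
            base_seed = as.integer(seed))
}

#' Detector noise model
#'
#' Additive Gaussian detector noise: shot-like variance proportional to the
#' instantaneous intensity (`shot_scale` is variance per unit intensity) plus
#' constant read noise of standard deviation `read_sigma`, with optional
#' quantization to `quantization` bits over the frame's dynamic range.
#'
#' @param shot_scale variance-per-intensity factor (>= 0).
#' @param read_sigma additive read-noise SD (>= 0), in intensity units.
#' @param quantization integer bit depth, or `NULL` for none.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(shot_scale = 5e-4, read_sigma = 0.005,
                        quantization = NULL) {
  stopifnot(shot_scale >= 0, read_sigma >= 0)
  structure(list(shot_scale = shot_scale, read_sigma = read_sigma,
                 quantization = quantization),
            class = "noise_model")
}

# ---- vectorized per-pixel Mueller fields -----------------------------------
# A field is a 16 x N matrix: column i holds pixel i's 4x4 Mueller matrix in
# column-major order. All constructors and products are vectorized over pixels.

mm_field_entry <- function(i, j) (j - 1L) * 4L + i

mm_field_multiply <- function(A, B) {
  out <- matrix(0, 16, ncol(A))
  for (i in 1:4) for (j in 1:4) {
    acc <- 0
    for (k in 1:4) {
      acc <- acc + A[mm_field_entry(i, k), ] * B[mm_field_entry(k, j), ]
    }
    out[mm_field_entry(i, j), ] <- acc
  }
  out
}

mm_field_apply <- function(field, S) {
  stopifnot(length(S) == 4)
  out <- matrix(0, 4, ncol(field))
  for (i in 1:4) {
    out[i, ] <- field[mm_field_entry(i, 1), ] * S[1] +
      field[mm_field_entry(i, 2), ] * S[2] +
      field[mm_field_entry(i, 3), ] * S[3] +
      field[mm_field_entry(i, 4), ] * S[4]
  }
  out
}

mm_field_identity <- function(n) {
  f <- matrix(0, 16, n)
  f[mm_field_entry(1, 1), ] <- 1
  f[mm_field_entry(2, 2), ] <- 1
  f[mm_field_entry(3, 3), ] <- 1
  f[mm_field_entry(4, 4), ] <- 1
  f
}

lin_retarder_field <- function(delta, theta) {
  n <- max(length(delta), length(theta))
  delta <- rep_len(delta, n); theta <- rep_len(theta, n)
  C <- cos(2 * theta); S <- sin(2 * theta)
  cd <- cos(delta); sd_ <- sin(delta)
  f <- matrix(0, 16, n)
  f[mm_field_entry(1, 1), ] <- 1
  f[mm_field_entry(2, 2), ] <- C^2 + S^2 * cd
  f[mm_field_entry(2, 3), ] <- C * S * (1 - cd)
  f[mm_field_entry(2, 4), ] <- -S * sd_
  f[mm_field_entry(3, 2), ] <- C * S * (1 - cd)
  f[mm_field_entry(3, 3), ] <- S^2 + C^2 * cd
  f[mm_field_entry(3, 4), ] <- C * sd_
  f[mm_field_entry(4, 2), ] <- S * sd_
  f[mm_field_entry(4, 3), ] <- -C * sd_
  f[mm_field_entry(4, 4), ] <- cd
  f
}

circ_retarder_field <- function(cr) {
  n <- length(cr)
  f <- matrix(0, 16, n)
  f[mm_field_entry(1, 1), ] <- 1
  f[mm_field_entry(2, 2), ] <- cos(cr)
  f[mm_field_entry(2, 3), ] <- sin(cr)
  f[mm_field_entry(3, 2), ] <- -sin(cr)
  f[mm_field_entry(3, 3), ] <- cos(cr)
  f[mm_field_entry(4, 4), ] <- 1
  f
}

diattenuator_field <- function(d, theta) {
  n <- max(length(d), length(theta))
  d <- rep_len(d, n); theta <- rep_len(theta, n)
  C <- cos(2 * theta); S <- sin(2 * theta)
  a <- sqrt(pmax(0, 1 - d^2))
  f <- matrix(0, 16, n)
  # R(-theta) %*% diag-frame diattenuator %*% R(theta), expanded analytically
  f[mm_field_entry(1, 1), ] <- 1
  f[mm_field_entry(1, 2), ] <- d * C
  f[mm_field_entry(1, 3), ] <- d * S
  f[mm_field_entry(2, 1), ] <- d * C
  f[mm_field_entry(3, 1), ] <- d * S
  f[mm_field_entry(2, 2), ] <- C^2 + a * S^2
  f[mm_field_entry(2, 3), ] <- (1 - a) * C * S
  f[mm_field_entry(3, 2), ] <- (1 - a) * C * S
  f[mm_field_entry(3, 3), ] <- S^2 + a * C^2
  f[mm_field_entry(4, 4), ] <- a
  f
}

depolarizer_field <- function(p) {
  n <- length(p)
  f <- matrix(0, 16, n)
  f[mm_field_entry(1, 1), ] <- 1
  f[mm_field_entry(2, 2), ] <- p
  f[mm_field_entry(3, 3), ] <- p
  f[mm_field_entry(4, 4), ] <- p
  f
}

# ---------------------------------------------------------------------------

#' Build a virtual leaf as a per-pixel Mueller-matrix field
#'
#' Each in-beam pixel gets the Mueller matrix
#' `M = depolarizer . circular_retarder . linear_retarder(delta, axis) .
#' diattenuator`, scaled by the beam transmission profile. Per-pixel linear
#' retardance is Gamma(`shape`, mean = region retardance scale times
#' `mean_retardance(growth, day, conc)`); the fast axis is von Mises about the
#' region orientation; circular retardance is Normal with mean
#' `circ_fraction` times the mean linear retardance. Deterministic given
#' `seed`. Background pixels transmit no light (zero matrix).
#'
#' @param model a [leaf_model()].
#' @param growth a [growth_model()].
#' @param day treatment day.
#' @param conc NaCl concentration in mM.
#' @param seed integer seed.
#' @return an object of class `mueller_field`: list with the 16 x N field
#'   matrix `m` (column-major 4x4 per pixel, pixels in column-major frame
#'   order), frame dimensions, region map and the generating parameters.
#' @export
build_leaf <- function(model, growth, day, conc, seed = 1L) {
  stopifnot(inherits(model, "leaf_model"), inherits(growth, "growth_model"),
            day >= 0, conc >= 0)
  n <- model$height * model$width
  region <- as.vector(model$region_map)
  tau <- as.vector(model$transmission)
  dbar <- mean_retardance(growth, day, conc)

  set.seed(as.integer(seed))
  delta <- numeric(n)
  axis <- numeric(n)
  diat <- numeric(n)
  depol <- numeric(n)
  # draw per region so region parameter changes do not reshuffle other regions
  for (rg in c("midrib", "vein", "lamina")) {
    idx <- which(region == rg)
    if (!length(idx)) next
    pars <- model$regions[rg, ]
    delta[idx] <- stats::rgamma(length(idx), shape = growth$shape,
                                scale = pars$ret_scale * dbar / growth$shape)
    axis[idx] <- rvonmises(length(idx), 2 * pars$axis_mean, pars$axis_kappa) / 2
    diat[idx] <- pars$diatten
    depol[idx] <- pars$depol
  }
  cr_mean <- growth$circ_fraction * dbar
  cr <- stats::rnorm(n, mean = cr_mean, sd = 0.5 * cr_mean)

  f <- mm_field_multiply(
    depolarizer_field(depol),
    mm_field_multiply(
      circ_retarder_field(cr),
      mm_field_multiply(lin_retarder_field(delta, axis),
                        diattenuator_field(diat, axis))))
  f <- f * rep(tau, each = 16)
  f[, region == "background"] <- 0

  structure(list(m = f, height = model$height, width = model$width,
                 region_map = model$region_map, day = day, conc = conc,
                 seed = as.integer(seed),
                 params = list(delta_mean = dbar, growth = growth)),
            class = "mueller_field")
}

#' Simulate a rotating-QWP acquisition of a Mueller field
#'
#' For each frame time `t` the per-pixel detected intensity is the
#' Mueller-chain intensity of `apply_mueller(M_pix, S_in)` through the
#' quarter-wave plate at angle `omega * t + phi0` and the analyzer, where
#' `S_in` is the beam after the fixed input polarizer (unpolarized source
#' assumed), plus detector noise. Frames are spread uniformly over one full
#' plate rotation.
#'
#' @param field a `mueller_field` from [build_leaf()], or a plain 16 x N
#'   field matrix with `height`/`width` attributes.
#' @param cfg an [acquisition_config()].
#' @param frames number of frames (>= 4; >= 8 and a full rotation
#'   recommended).
#' @param noise a [noise_model()], or `NULL` for a noiseless acquisition.
#' @param seed integer seed for the noise draws.
#' @param times optional explicit frame times (s); default uniform over one
#'   rotation `2*pi/omega`.
#' @return an object of class `intensity_stack`: list with `frames`
#'   (H x W x T array), `times`, `cfg`, `seed` and simulation metadata.
#' @export
simulate_acquisition <- function(field, cfg = acquisition_config(),
                                 frames = 64, noise = noise_model(),
                                 seed = 1L, times = NULL) {
  stopifnot(inherits(field, "mueller_field"))
  if (frames < 4) stop("at least 4 frames are required for the harmonic fit")
  if (is.null(times)) {
    period <- 2 * pi / cfg$omega
    times <- (seq_len(frames) - 1) / frames * period
  } else {
    frames <- length(times)
  }
  coverage <- (max(times) - min(times)) * cfg$omega
  if (coverage < 2 * pi * (1 - 1 / frames) - 1e-9) {
    warning("angular coverage below one full QWP rotation (",
            signif(coverage, 4), " rad)")
  }

  s_in <- apply_mueller(polarizer_mueller(cfg$input_polarizer_angle),
                        c(1, 0, 0, 0))
  s_exit <- mm_field_apply(field$m, s_in)          # 4 x N

  # analyzer-row weights per frame: first row of analyzer . retarder(theta_t)
  P <- polarizer_mueller(cfg$alpha)
  theta <- cfg$omega * times + cfg$phi0
  W <- t(vapply(theta, function(th) {
    drop(P[1, ] %*% retarder_mueller(cfg$delta, th))
  }, numeric(4)))                                  # T x 4
  I <- W %*% s_exit                                # T x N

  if (!is.null(noise)) {
    set.seed(as.integer(seed))
    nval <- length(I)
    sd_tot <- sqrt(noise$shot_scale * pmax(I, 0) + noise$read_sigma^2)
    I <- I + stats::rnorm(nval) * sd_tot
    if (!is.null(noise$quantization)) {
      lev <- 2^noise$quantization - 1
      rng <- range(I)
      I <- round((I - rng[1]) / diff(rng) * lev) / lev * diff(rng) + rng[1]
    }
  }

  arr <- array(0, dim = c(field$height, field$width, frames))
  for (t in seq_len(frames)) {
    arr[, , t] <- matrix(I[t, ], field$height, field$width)
  }
  structure(list(frames = arr, times = times, cfg = cfg,
                 seed = as.integer(seed),
                 meta = list(day = field$day, conc = field$conc,
                             field_seed = field$seed)),
            class = "intensity_stack")
}

#' @export
print.intensity_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat("Intensity stack:", d[3], "frames of", d[1], "x", d[2], "px, t =",
      signif(min(x$times), 4), "..", signif(max(x$times), 4), "s\n")
  invisible(x)
}

#' Simulate a full salt-stress study
#'
#' One acquisition per (concentration, day, replicate) cell of the design,
#' each with its own derived seed (replicate leaves differ; reruns are
#' identical). Stacks can be returned in memory, written to disk as
#' multi-page TIFF + JSON sidecar, or streamed through a `process` callback
#' (used by the pipeline to avoid holding the whole study in memory).
#'
#' @param design a [study_design()].
#' @param leaf a [leaf_model()].
#' @param growth a [growth_model()].
#' @param noise a [noise_model()] or `NULL`.
#' @param cfg an [acquisition_config()].
#' @param frames frames per acquisition.
#' @param out_dir if given, stacks are written here and not kept in memory.
#' @param process optional `function(stack, design_row)`; its return values
#'   are collected in place of the stacks.
#' @return list with `metadata` (the design data frame, plus file paths if
#'   written) and `stacks` (list of stacks, of `process` results, or `NULL`).
#' @export
simulate_study <- function(design, leaf = leaf_model(),
                           growth = growth_model(), noise = noise_model(),
                           cfg = acquisition_config(), frames = 64,
                           out_dir = NULL, process = NULL) {
  stopifnot(inherits(design, "study_design"))
  keep <- is.null(out_dir) && is.null(process)
  stacks <- if (is.null(process) && is.null(out_dir)) vector("list", nrow(design)) else NULL
  results <- if (!is.null(process)) vector("list", nrow(design)) else NULL
  paths <- character(nrow(design))
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    fld <- build_leaf(leaf, growth, day = row$day, conc = row$concentration_mM,
                      seed = row$seed)
    stk <- simulate_acquisition(fld, cfg = cfg, frames = frames, noise = noise,
                                seed = derive_seed(row$seed, 7L))
    stk$meta$replicate <- row$replicate
    if (!is.null(out_dir)) {
      fn <- sprintf("stack_c%04d_d%02d_r%02d.tif",
                    row$concentration_mM, row$day, row$replicate)
      paths[i] <- file.path(out_dir, fn)
      write_intensity_stack(stk, paths[i])
    }
    if (!is.null(process)) results[[i]] <- process(stk, row)
    if (keep) stacks[[i]] <- stk
  }
  metadata <- as.data.frame(design)
  if (!is.null(out_dir)) metadata$path <- paths
  list(metadata = metadata,
       stacks = if (!is.null(process)) results else stacks)
}
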