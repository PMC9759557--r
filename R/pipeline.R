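#' Assemble a pipeline configuration
#'
#' Collects the acquisition, simulation, reconstruction and statistics
#' settings plus the master seed into one object. All angles are radians
#' internally; [read_pipeline_config()] accepts degrees in config files via
#' `*_deg` keys.
#'
#' @param design a [study_design()].
#' @param leaf a [leaf_model()].
#' @param growth a [growth_model()].
#' @param noise a [noise_model()] or `NULL`.
#' @param acquisition an [acquisition_config()].
#' @param frames frames per acquisition.
#' @param dop_lo,dop_hi strict DOP bounds for the pixel mask.
#' @param min_intensity intensity floor for the mask (`"auto"`, `NULL` or a
#'   number).
#' @param test_method Wilcoxon variant for group comparisons.
#' @param n_az,n_lat Poincare density bins.
#' @param seed master seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(design = study_design(), leaf = leaf_model(),
                            growth = growth_model(), noise = noise_model(),
                            acquisition = acquisition_config(), frames = 64,
                            dop_lo = 0, dop_hi = 1, min_intensity = "auto",
                            test_method = "rank_sum",
                            n_az = 72, n_lat = 36, seed = 1L) {
  structure(list(design = design, leaf = leaf, growth = growth, noise = noise,
                 acquisition = acquisition, frames = frames,
                 dop_lo = dop_lo, dop_hi = dop_hi,
                 min_intensity = min_intensity, test_method = test_method,
                 n_az = n_az, n_lat = n_lat, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Recognized blocks: `design`, `leaf`, `growth`, `noise`, `acquisition`,
#' `reconstruction`, `stats`, plus top-level `frames` and `seed`. Angle keys
#' ending in `_deg` are converted to radians. Missing blocks fall back to the
#' package defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  seed <- as.integer(raw$seed %||% 1L)
  des <- raw$design %||% list()
  design <- study_design(
    concentrations = des$concentrations %||% c(0, 100, 200, 300, 400),
    days = des$days %||% c(0, 2, 4, 6, 8, 10),
    replicates = des$replicates %||% 5,
    seed = seed)
  lf <- raw$leaf %||% list()
  leaf <- leaf_model(height = lf$height %||% 128, width = lf$width %||% 128,
                     beam_radius = lf$beam_radius %||% 48)
  gr <- raw$growth %||% list()
  growth <- growth_model(delta0 = gr$delta0 %||% 0.15, g = gr$g %||% 0.035,
                         salt_scale = gr$salt_scale %||% 250,
                         circ_fraction = gr$circ_fraction %||% 0.05,
                         shape = gr$shape %||% 4)
  nz <- raw$noise %||% list()
  noise <- noise_model(shot_scale = nz$shot_scale %||% 5e-4,
                       read_sigma = nz$read_sigma %||% 0.005,
                       quantization = nz$quantization)
  ac <- raw$acquisition %||% list()
  angle <- function(block, key, default_rad) {
    if (!is.null(block[[paste0(key, "_deg")]])) {
      deg2rad(block[[paste0(key, "_deg")]])
    } else {
      block[[key]] %||% default_rad
    }
  }
  acquisition <- acquisition_config(
    omega = ac$omega %||% 20,
    phi0 = angle(ac, "phi0", 0),
    delta = angle(ac, "delta", pi / 2),
    alpha = angle(ac, "alpha", 0),
    input_polarizer_angle = angle(ac, "input_polarizer", deg2rad(135)))
  rc <- raw$reconstruction %||% list()
  st <- raw$stats %||% list()
  pipeline_config(design = design, leaf = leaf, growth = growth, noise = noise,
                  acquisition = acquisition, frames = raw$frames %||% 64,
                  dop_lo = rc$dop_lo %||% 0, dop_hi = rc$dop_hi %||% 1,
                  min_intensity = rc$min_intensity %||% "auto",
                  test_method = st$method %||% "rank_sum",
                  n_az = st$n_az %||% 72, n_lat = st$n_lat %||% 36,
                  seed = seed)
}

# Reconstruct one stack and characterize |s3|; one fit-table row plus QC info.
fit_one_stack <- function(stack, row, config, keep_samples = FALSE) {
  img <- reconstruct_stokes(stack, dop_lo = config$dop_lo,
                            dop_hi = config$dop_hi,
                            min_intensity = config$min_intensity)
  chr <- characterize_s3(img)
  out <- cbind(data.frame(concentration_mM = row$concentration_mM,
                          day = row$day, replicate = row$replicate),
               chr,
               data.frame(excluded = sum(!img$valid),
                          mean_dop = mean(img$dop[img$valid])))
  if (keep_samples) attr(out, "samples") <- abs_s3_samples(img)
  out
}

#' Simulate and analyse a full study, returning the fit table
#'
#' Streams the study cell by cell — build leaf, simulate the acquisition,
#' reconstruct the Stokes image, fit the GEV to |s3| — so the whole study is
#' never held in memory. This is the machine-readable twin of the study
#' summary table: one row per (concentration, day, replicate) with the GEV
#' parameters, robust summaries and pixel-QC counts.
#'
#' @param config a [pipeline_config()].
#' @param verbose log per-stack progress (excluded-pixel counts) via
#'   [message()].
#' @param keep_samples_day if not `NULL`, |s3| samples for stacks at this day
#'   are collected and attached as `attr(, "samples")` (a list keyed by
#'   concentration), for [classify_salt_stress()].
#' @return data frame with columns `concentration_mM`, `day`, `replicate`,
#'   `xi`, `mu`, `sigma`, `loglik`, `n`, `converged`, `median`, `mad`,
#'   `excluded`, `mean_dop`.
#' @export
run_study <- function(config = pipeline_config(), verbose = FALSE,
                      keep_samples_day = NULL) {
  design <- config$design
  rows <- vector("list", nrow(design))
  samples <- list()
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    fld <- build_leaf(config$leaf, config$growth, day = row$day,
                      conc = row$concentration_mM, seed = row$seed)
    stk <- simulate_acquisition(fld, cfg = config$acquisition,
                                frames = config$frames, noise = config$noise,
                                seed = derive_seed(row$seed, 7L))
    keep <- !is.null(keep_samples_day) && row$day == keep_samples_day
    res <- fit_one_stack(stk, row, config, keep_samples = keep)
    if (keep) {
      key <- as.character(row$concentration_mM)
      samples[[key]] <- c(samples[[key]], attr(res, "samples"))
      attr(res, "samples") <- NULL
    }
    if (verbose) {
      message(sprintf("c=%4d mM day %2d rep %d: %d px excluded, mean DOP %.3f",
                      row$concentration_mM, row$day, row$replicate,
                      res$excluded, res$mean_dop))
    }
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  if (!is.null(keep_samples_day)) attr(out, "samples") <- samples
  out
}

#' Run the full analysis pipeline and write its outputs
#'
#' Simulate (or ingest) the study, reconstruct, fit, then run the trend
#' analyses: per-concentration ANOVA of the GEV shape across days, per-day
#' Spearman correlation and OLS regression of the GEV location on
#' concentration. Writes `fit_table.csv`, `anova_trends.csv`,
#' `spearman.csv`, `regressions.csv` and `manifest.json` to `out_dir`.
#' Reruns with the same configuration produce identical CSV contents.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param stacks_dir optional directory of previously written stacks
#'   (TIFF + sidecar); when given, simulation is skipped and the stacks are
#'   read instead (their sidecar metadata must carry `day`, `conc`,
#'   `replicate`).
#' @param verbose log stage progress.
#' @return list with `fit_table`, `anova`, `spearman`, `regressions` and the
#'   `manifest`, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stacks_dir = NULL, verbose = FALSE) {
  t0 <- Sys.time()
  stage <- function(what) if (verbose) message("[", what, "] ",
                                               format(Sys.time() - t0))
  stage("simulate+reconstruct+fit")
  if (is.null(stacks_dir)) {
    fit_table <- run_study(config, verbose = verbose)
  } else {
    paths <- list.files(stacks_dir, pattern = "\\.tiff?$", full.names = TRUE)
    if (!length(paths)) stop("stage simulate: no stacks found in ", stacks_dir)
    rows <- lapply(paths, function(p) {
      stk <- read_intensity_stack(p)
      row <- data.frame(concentration_mM = stk$meta$conc, day = stk$meta$day,
                        replicate = stk$meta$replicate %||% 1L)
      fit_one_stack(stk, row, config)
    })
    fit_table <- do.call(rbind, rows)
  }

  stage("trend analysis")
  empty <- data.frame()
  days <- sort(unique(fit_table$day))
  can_anova <- length(days) >= 2 &&
    min(table(fit_table$concentration_mM, fit_table$day)) >= 2
  anova_tab <- if (can_anova) {
    do.call(rbind, lapply(
      sort(unique(fit_table$concentration_mM)), function(conc) {
        a <- gev_trend_anova(fit_table, "xi", conc)
        data.frame(parameter = "xi", concentration_mM = conc,
                   f_statistic = a$f_statistic, p_value = a$p_value,
                   stars = a$stars)
      }))
  } else empty
  can_conc <- length(unique(fit_table$concentration_mM)) >= 3
  sp_tab <- if (can_conc) {
    do.call(rbind, lapply(days, function(d) {
      s <- spearman_param_vs_concentration(fit_table, "mu", d)
      data.frame(day = d, parameter = "mu", rho = s$rho, p_value = s$p_value)
    }))
  } else empty
  reg_tab <- if (can_conc) {
    do.call(rbind, lapply(days, function(d) {
      r <- regress_location_vs_concentration(fit_table, d)
      data.frame(day = d, slope = r$slope, intercept = r$intercept,
                 slope_lo = r$slope_ci[1], slope_hi = r$slope_ci[2],
                 r_squared = r$r_squared, n = r$n)
    }))
  } else empty

  stage("write")
  manifest <- write_results(
    tables = list(fit_table = fit_table, anova_trends = anova_tab,
                  spearman = sp_tab, regressions = reg_tab),
    out_dir = out_dir, seed = config$seed,
    config = config[setdiff(names(config), c("design", "leaf"))])
  if (verbose) {
    message(sprintf("total DOP-excluded pixels: %d over %d images",
                    sum(fit_table$excluded), nrow(fit_table)))
  }
  stage("done")
  invisible(list(fit_table = fit_table, anova = anova_tab, spearman = sp_tab,
                 regressions = reg_tab, manifest = manifest))
}
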