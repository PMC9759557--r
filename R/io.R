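#' Write an intensity stack as multi-page TIFF with a JSON sidecar
#'
#' Frames go to a 32-bit float multi-page TIFF; because TIFF samples are
#' stored in \[0, 1\], intensities are affinely mapped and the offset/scale
#' recorded in the sidecar, which also carries the acquisition configuration,
#' timestamps, seed and any design metadata. [read_intensity_stack()] undoes
#' the mapping.
#'
#' @param stack an `intensity_stack`.
#' @param path output TIFF path (`.tif`); the sidecar is written next to it
#'   with a `.json` extension.
#' @return `path`, invisibly.
#' @export
write_intensity_stack <- function(stack, path) {
  stopifnot(inherits(stack, "intensity_stack"))
  d <- dim(stack$frames)
  rng <- range(stack$frames)
  offset <- rng[1]
  scale <- max(rng[2] - rng[1], .Machine$double.eps)
  pages <- lapply(seq_len(d[3]), function(t) {
    (stack$frames[, , t] - offset) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  sidecar <- list(
    omega = stack$cfg$omega, phi0 = stack$cfg$phi0, delta = stack$cfg$delta,
    alpha = stack$cfg$alpha,
    input_polarizer_angle = stack$cfg$input_polarizer_angle,
    times = stack$times, seed = stack$seed,
    intensity_offset = offset, intensity_scale = scale,
    meta = stack$meta
  )
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.tiff?$", ".json", path)

#' Read an intensity stack written by [write_intensity_stack()]
#'
#' @param path TIFF path with its JSON sidecar alongside.
#' @return an `intensity_stack`.
#' @export
read_intensity_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sc_path <- sidecar_path(path)
  if (!file.exists(sc_path)) stop("missing JSON sidecar: ", sc_path)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  required <- c("omega", "phi0", "times")
  miss <- setdiff(required, names(sc))
  if (length(miss)) {
    stop("sidecar ", sc_path, " lacks required metadata field(s): ",
         paste(miss, collapse = ", "))
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0) stop("TIFF has no pages: ", path)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("TIFF pages differ in shape: ", path)
  }
  if (length(pages) != length(sc$times)) {
    stop("page count (", length(pages), ") does not match sidecar times (",
         length(sc$times), ")")
  }
  offset <- sc$intensity_offset %||% 0
  scale <- sc$intensity_scale %||% 1
  arr <- array(0, dim = c(dims[1, 1], dims[2, 1], length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- pages[[t]] * scale + offset
  cfg <- acquisition_config(
    omega = sc$omega, phi0 = sc$phi0,
    delta = sc$delta %||% (pi / 2), alpha = sc$alpha %||% 0,
    input_polarizer_angle = sc$input_polarizer_angle %||% deg2rad(135))
  structure(list(frames = arr, times = sc$times, cfg = cfg,
                 seed = sc$seed %||% NA_integer_, meta = sc$meta),
            class = "intensity_stack")
}

#' Write analysis tables and images with a manifest
#'
#' Writes each table as CSV (UTF-8, comma-separated, header row) and each
#' Stokes image as a 4-page float TIFF (planes S0, S1, S2, S3; `NA` as the
#' missing-value marker), then a `manifest.json` listing every file with its
#' MD5 checksum plus the seed and package version. Identical inputs produce
#' byte-identical CSVs.
#'
#' @param tables named list of data frames (may be empty).
#' @param images named list of `stokes_image` objects (may be empty).
#' @param out_dir output directory (created if needed).
#' @param seed seed to record in the manifest.
#' @param config optional configuration list, hashed into the manifest.
#' @return the manifest, invisibly.
#' @export
write_results <- function(tables = list(), images = list(), out_dir,
                          seed = NA_integer_, config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(tables)) {
    fp <- file.path(out_dir, paste0(nm, ".csv"))
    df <- tables[[nm]]
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 10))
    utils::write.csv(df, fp, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    files <- c(files, fp)
  }
  for (nm in names(images)) {
    img <- images[[nm]]
    fp <- file.path(out_dir, paste0(nm, ".tif"))
    planes <- lapply(list(img$S0, img$S1, img$S2, img$S3), function(m) {
      m[!is.finite(m)] <- 0
      (m - min(m)) / max(max(m) - min(m), .Machine$double.eps)
    })
    tiff::writeTIFF(planes, fp, bits.per.sample = 32L, compression = "none")
    files <- c(files, fp)
  }
  config_hash <- NA_character_
  if (!is.null(config)) {
    tf <- tempfile(fileext = ".json")
    jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    config_hash <- unname(tools::md5sum(tf))
    unlink(tf)
  }
  manifest <- list(
    files = data.frame(path = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE),
    seed = seed,
    config_md5 = config_hash,
    package_version = as.character(utils::packageVersion("polarleaf"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
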