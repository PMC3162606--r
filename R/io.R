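#' Write a movie as a TIFF stack with a JSON sidecar
#'
#' One 32-bit float frame per time point.  Because the TIFF writer stores
#' values in [0, 1], intensities are affinely rescaled and the scale and
#' offset recorded, together with the time axis and pixel size, in a
#' sidecar \code{<path>.json}; \code{\link{read_movie}} inverts the
#' transform.
#'
#' @param movie a \code{\link{movie_grid}}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "movie_grid"))
  x <- movie$intensities
  rng <- range(x[is.finite(x)])
  offset <- rng[1]
  scale <- if (diff(rng) > 0) diff(rng) else 1
  frames <- lapply(seq_len(dim(x)[3]),
                   function(k) (x[, , k] - offset) / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(time = movie$time, pixel_size = movie$pixel_size,
               offset = offset, scale = scale,
               dim = dim(x), mask = which(!movie$mask))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a movie written by \code{\link{write_movie}}
#'
#' @param path TIFF path; metadata is taken from \code{<path>.json}
#'   unless supplied explicitly.
#' @param time,pixel_size override / supply metadata when no sidecar is
#'   present.
#' @return a \code{\link{movie_grid}}; non-finite pixels are masked.
#' @export
read_movie <- function(path, time = NULL, pixel_size = NULL) {
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list()
  time <- time %||% meta$time
  pixel_size <- pixel_size %||% meta$pixel_size
  if (is.null(pixel_size))
    stop("`pixel_size` missing: supply it or provide the JSON sidecar")
  frames <- tiff::readTIFF(path, all = TRUE)
  H <- nrow(frames[[1]]); W <- ncol(frames[[1]]); nT <- length(frames)
  if (is.null(time))
    stop("`time` missing: supply it or provide the JSON sidecar")
  if (length(time) != nT)
    stop(sprintf("metadata mismatch: %d frames but %d time points",
                 nT, length(time)))
  x <- array(unlist(frames), dim = c(H, W, nT))
  offset <- meta$offset %||% 0
  scale <- meta$scale %||% 1
  x <- x * scale + offset
  mask <- matrix(TRUE, H, W)
  if (length(meta$mask)) mask[meta$mask] <- FALSE
  movie_grid(x, time = time, pixel_size = pixel_size, mask = mask)
}

#' Write ground truth as JSON + CSV sidecars
#'
#' Scalars (true Delta, velocity, spec) go to \code{<prefix>.json}; the
#' per-pixel phase-offset map and defect mask go to \code{<prefix>.csv}
#' in long format with unit-labelled headers.
#'
#' @param truth a \code{ground_truth}.
#' @param prefix output path prefix.
#' @return the two paths, invisibly.
#' @export
write_ground_truth <- function(truth, prefix) {
  stopifnot(inherits(truth, "ground_truth"))
  jpath <- paste0(prefix, ".json"); cpath <- paste0(prefix, ".csv")
  jsonlite::write_json(
    list(true_delta_rad_per_2pi = truth$true_delta,
         true_velocity_mm_per_h = truth$true_velocity,
         spec = unclass(truth$spec)),
    jpath, auto_unbox = TRUE, digits = NA)
  H <- nrow(truth$phase_offset); W <- ncol(truth$phase_offset)
  df <- data.frame(row = rep(seq_len(H), W),
                   col = rep(seq_len(W), each = H),
                   phase_offset_cycles = as.vector(truth$phase_offset),
                   amplitude_counts = as.vector(truth$amplitude_map),
                   defect = as.vector(truth$defect_mask))
  write.csv(df, cpath, row.names = FALSE)
  invisible(c(jpath, cpath))
}

#' Read a simulation configuration from YAML
#'
#' Unknown keys are an error (no silent defaults); \code{seed} is
#' mandatory.
#'
#' @param path YAML file whose keys are \code{\link{sim_config}}
#'   arguments.
#' @return a \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  if (is.null(cfg$seed)) stop("`seed` is mandatory in a simulation config")
  do.call(sim_config, cfg)
}

#' Run manifest for persisted results
#'
#' Records the configuration, seeds, package version, input/output file
#' checksums and a timestamp, so that every persisted table can be traced
#' to the run that produced it.
#'
#' @param config the configuration object (any list-like).
#' @param seeds seeds used.
#' @param files character vector of files to checksum.
#' @param path if given, the manifest is written there as JSON.
#' @return the manifest list, invisibly if written.
#' @export
run_manifest <- function(config, seeds, files = character(0), path = NULL) {
  man <- list(package = "scnwave",
              version = as.character(utils::packageVersion("scnwave")),
              timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
              seeds = seeds,
              config = if (is.list(config)) unclass(config) else config,
              checksums = as.list(tools::md5sum(files[file.exists(files)])))
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
    return(invisible(man))
  }
  man
}
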