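#' Specification for a synthetic bioluminescence movie
#'
#' Describes a synthetic time-lapse movie that emulates the statistical
#' structure of a bioluminescence recording of a cultured SCN slice:
#' damped circadian oscillations per pixel, a traveling phase wave
#' radiating from an origin at a fixed velocity, cell-scale phase jitter
#' that is constant in time, a smooth spatial amplitude bump, a baseline
#' trend, Gaussian measurement noise, and (optionally) dead-cell defects.
#'
#' Phase jitter and defects are assigned per cell block (square patches of
#' \code{cell_size} pixels), not per pixel, so that pixel-level windows
#' correspond to a known number of statistically independent cells.
#'
#' @param grid_shape integer c(H, W), pixels.
#' @param pixel_size mm per pixel.
#' @param sampling_interval hours between frames; must be <= 1 h so that a
#'   6 h smoothing window spans at least 6 samples.
#' @param duration total length in hours; must cover >= 3 periods so the
#'   envelope interpolation has at least three peaks.
#' @param period oscillation period in hours.
#' @param wave_velocity wave speed in mm/h (> 0).
#' @param wave_origin c(row, col) pixel coordinates of the wave source.
#' @param phase_jitter_sd per-cell phase jitter, in rad/2pi (cycles);
#'   constant over time.
#' @param cell_size pixels per simulated cell (square blocks).
#' @param amplitude_profile list with \code{center} (c(row, col)),
#'   \code{width} (pixels), \code{peak} and \code{floor} (counts):
#'   a Gaussian bump emulating the bright central region.
#' @param damping_time exponential damping time of the oscillation
#'   amplitude, hours; \code{Inf} for undamped.
#' @param baseline constant background counts.
#' @param trend_slope linear baseline drift, counts/h.
#' @param noise_sd Gaussian measurement noise sd, counts.
#' @param defect_fraction probability that a cell block is dead (its
#'   pixels carry baseline and noise only).
#' @param seed integer seed; mandatory, the generators are deterministic
#'   given the spec.
#' @return an object of class \code{movie_spec}.
#' @export
#' @examples
#' spec <- synthetic_movie_spec(seed = 1)
#' mv <- generate_movie(spec)
#' dim(mv$movie$intensities)
synthetic_movie_spec <- function(grid_shape = c(40L, 40L),
                                 pixel_size = 0.01,
                                 sampling_interval = 0.5,
                                 duration = 120,
                                 period = 24,
                                 wave_velocity = 0.2,
                                 wave_origin = c(1, 1),
                                 phase_jitter_sd = 0.017,
                                 cell_size = 2L,
                                 amplitude_profile = list(center = NULL,
                                                          width = 12,
                                                          peak = 60,
                                                          floor = 30),
                                 damping_time = 100,
                                 baseline = 100,
                                 trend_slope = -0.2,
                                 noise_sd = 0.5,
                                 defect_fraction = 0,
                                 seed) {
  if (missing(seed)) stop("`seed` is mandatory in a movie spec")
  if (wave_velocity <= 0) stop("invalid spec: `wave_velocity` must be > 0")
  if (sampling_interval > 1)
    stop("invalid spec: `sampling_interval` must be <= 1 h (the 6 h ",
         "smoothing window must span at least 6 samples)")
  if (duration < 3 * period)
    stop("invalid spec: `duration` must be >= 3 periods for envelope ",
         "interpolation")
  if (phase_jitter_sd < 0) stop("invalid spec: `phase_jitter_sd` must be >= 0")
  if (defect_fraction < 0 || defect_fraction > 1)
    stop("invalid spec: `defect_fraction` must lie in [0, 1]")
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 1),
            pixel_size > 0, period > 0, cell_size >= 1,
            damping_time > 0, noise_sd >= 0)
  amplitude_profile <- modifyList(
    list(center = NULL, width = 12, peak = 60, floor = 30), amplitude_profile)
  if (is.null(amplitude_profile$center))
    amplitude_profile$center <- pmax(1, round(grid_shape * 0.35))
  structure(list(grid_shape = as.integer(grid_shape), pixel_size = pixel_size,
                 sampling_interval = sampling_interval, duration = duration,
                 period = period, wave_velocity = wave_velocity,
                 wave_origin = wave_origin,
                 phase_jitter_sd = phase_jitter_sd,
                 cell_size = as.integer(cell_size),
                 amplitude_profile = amplitude_profile,
                 damping_time = damping_time, baseline = baseline,
                 trend_slope = trend_slope, noise_sd = noise_sd,
                 defect_fraction = defect_fraction,
                 seed = as.integer(seed)),
            class = "movie_spec")
}

# Cell-block index matrices for a grid.
cell_blocks <- function(grid_shape, cell_size) {
  ci <- ceiling(seq_len(grid_shape[1]) / cell_size)
  cj <- ceiling(seq_len(grid_shape[2]) / cell_size)
  list(row = ci, col = cj, n_row = max(ci), n_col = max(cj))
}

#' Generate the ground-truth phase map for a synthetic movie
#'
#' The phase offset of pixel p (in cycles) is the wave travel time from
#' the origin, \code{distance(p, origin) * pixel_size / wave_velocity},
#' divided by the period, plus a per-cell jitter drawn iid
#' Normal(0, \code{phase_jitter_sd}).  Dead cells are drawn per cell block
#' with probability \code{defect_fraction}.  Everything is deterministic
#' given the seed.
#'
#' @param spec a \code{\link{synthetic_movie_spec}}.
#' @return an object of class \code{ground_truth}: \code{phase_offset}
#'   (H x W, cycles), \code{amplitude_map} (counts), \code{defect_mask}
#'   (H x W logical), \code{true_delta} (rad/2pi; the realized detrended
#'   sd of the map itself, 7 x 7 window), \code{true_velocity} (mm/h).
#' @export
generate_phase_map <- function(spec) {
  stopifnot(inherits(spec, "movie_spec"))
  H <- spec$grid_shape[1]; W <- spec$grid_shape[2]
  set.seed(spec$seed)
  cb <- cell_blocks(spec$grid_shape, spec$cell_size)
  jit_cells <- matrix(rnorm(cb$n_row * cb$n_col, 0, spec$phase_jitter_sd),
                      cb$n_row, cb$n_col)
  def_cells <- matrix(runif(cb$n_row * cb$n_col) < spec$defect_fraction,
                      cb$n_row, cb$n_col)
  dist_px <- sqrt(outer((seq_len(H) - spec$wave_origin[1])^2,
                        (seq_len(W) - spec$wave_origin[2])^2, `+`))
  ramp <- dist_px * spec$pixel_size / spec$wave_velocity / spec$period
  jitter <- jit_cells[cbind(rep(cb$row, W), rep(cb$col, each = H))]
  phase_offset <- ramp + matrix(jitter, H, W)
  defect_mask <- matrix(def_cells[cbind(rep(cb$row, W), rep(cb$col, each = H))],
                        H, W)
  ap <- spec$amplitude_profile
  d2 <- outer((seq_len(H) - ap$center[1])^2, (seq_len(W) - ap$center[2])^2, `+`)
  amplitude_map <- ap$floor + (ap$peak - ap$floor) * exp(-d2 / (2 * ap$width^2))
  true_delta <- NA_real_
  if (H >= 7 && W >= 7) {
    dt_field <- spatial_detrend(2 * pi * phase_offset, window = 7L)
    if (sum(is.finite(dt_field)) >= 2)
      true_delta <- sd(dt_field[is.finite(dt_field)]) / (2 * pi)
  }
  structure(list(phase_offset = phase_offset, amplitude_map = amplitude_map,
                 defect_mask = defect_mask, true_delta = true_delta,
                 true_velocity = spec$wave_velocity, spec = spec),
            class = "ground_truth")
}

#' Generate a synthetic bioluminescence movie
#'
#' Pixel traces follow
#' \deqn{x_p(t) = b + s t + A(p)\, e^{-t/\tau} \cos(2\pi(t/T - \phi_p))
#'       + \epsilon,\qquad \epsilon \sim N(0, \sigma^2),}
#' with the per-pixel phase offset \eqn{\phi_p} from
#' \code{\link{generate_phase_map}}.  Dead pixels carry baseline and noise
#' only.  Deterministic given the seed.
#'
#' @param spec a \code{\link{synthetic_movie_spec}}.
#' @return list with \code{movie} (a \code{movie_grid}) and \code{truth}
#'   (the \code{ground_truth}).
#' @export
generate_movie <- function(spec) {
  truth <- generate_phase_map(spec)   # seeds the RNG; noise drawn after
  H <- spec$grid_shape[1]; W <- spec$grid_shape[2]
  tt <- seq(0, spec$duration, by = spec$sampling_interval)
  nT <- length(tt)
  damp <- if (is.finite(spec$damping_time)) exp(-tt / spec$damping_time) else rep(1, nT)
  x <- array(0, dim = c(H, W, nT))
  phi <- truth$phase_offset
  amp <- truth$amplitude_map
  amp[truth$defect_mask] <- 0
  for (k in seq_len(nT)) {
    osc <- amp * cos(2 * pi * (tt[k] / spec$period - phi)) * damp[k]
    frame <- spec$baseline + spec$trend_slope * tt[k] + osc
    frame[truth$defect_mask] <- spec$baseline   # dead cells: baseline + noise
    x[, , k] <- frame
  }
  if (spec$noise_sd > 0)
    x <- x + array(rnorm(length(x), 0, spec$noise_sd), dim = dim(x))
  movie <- movie_grid(x, time = tt, pixel_size = spec$pixel_size)
  list(movie = movie, truth = truth)
}

#' Construct a movie grid
#'
#' The container for per-pixel intensity time series: an H x W x T array
#' plus a uniform time axis (hours) and the pixel size (mm).
#'
#' @param intensities H x W x T numeric array.
#' @param time time axis in hours, strictly increasing and uniform.
#' @param pixel_size mm per pixel.
#' @param mask optional H x W logical matrix of valid pixels.
#' @return an object of class \code{movie_grid}.
#' @export
movie_grid <- function(intensities, time, pixel_size, mask = NULL) {
  stopifnot(length(dim(intensities)) == 3, dim(intensities)[3] == length(time))
  if (length(time) > 1) {
    dt <- diff(time)
    if (any(dt <= 0)) stop("`time` must be strictly increasing")
    if (max(abs(dt - dt[1])) > 1e-8 * dt[1]) stop("`time` must be uniform")
  }
  if (is.null(mask)) mask <- matrix(TRUE, dim(intensities)[1], dim(intensities)[2])
  bad <- apply(!is.finite(intensities), c(1, 2), any)
  mask <- mask & !bad
  structure(list(intensities = intensities, time = time,
                 pixel_size = pixel_size, mask = mask),
            class = "movie_grid")
}

#' @export
print.movie_grid <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<movie_grid> %d x %d pixels, %d frames (%.2g h step, %.3g mm/px)\n",
              d[1], d[2], d[3],
              if (length(x$time) > 1) diff(x$time[1:2]) else NA, x$pixel_size))
  invisible(x)
}
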