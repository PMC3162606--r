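#' Kuramoto order parameter of a phase field
#'
#' \eqn{R e^{i\Phi} = \frac{1}{N}\sum_j e^{i\theta_j}} over valid pixels.
#' R close to 1 indicates strong synchronization, close to 0 incoherence.
#'
#' @param theta phases in radians (vector, matrix, or array; non-finite
#'   entries are treated as invalid).
#' @param mask optional logical of the same shape selecting valid pixels.
#' @return list with \code{R} in [0, 1], the mean-field phase \code{Phi}
#'   (radians), and \code{n_valid}.
#' @export
#' @examples
#' order_parameter(c(0, pi / 2))$R   # cos(pi/4)
order_parameter <- function(theta, mask = NULL) {
  th <- as.numeric(theta)
  ok <- is.finite(th)
  if (!is.null(mask)) ok <- ok & as.logical(mask)
  if (!any(ok)) stop("no valid pixels in phase field")
  z <- mean(exp(1i * th[ok]))
  list(R = Mod(z), Phi = Arg(z), n_valid = sum(ok))
}

#' Spatially detrend a phase field
#'
#' Removes the locally averaged phase of the surrounding window
#' (default 7 x 7 pixels, about 3 x 3 cells at the experimental pixel
#' scale) from each pixel, using the circular (resultant-vector) mean and
#' a wrapped difference.  Only pixels whose window lies fully inside the
#' field, and with at least \code{min_frac} valid window pixels, get a
#' value; edge pixels are excluded rather than padded.
#'
#' @param theta H x W phase matrix, radians.
#' @param window odd window size in pixels (>= 3).
#' @param mask optional H x W logical matrix of valid pixels.
#' @param min_frac minimum fraction of valid pixels in the window.
#' @return H x W matrix of detrended phases (radians, in (-pi, pi]), NA
#'   where undefined.
#' @export
spatial_detrend <- function(theta, window = 7L, mask = NULL, min_frac = 0.5) {
  stopifnot(is.matrix(theta), window %% 2 == 1, window >= 3)
  H <- nrow(theta); W <- ncol(theta)
  if (H < window || W < window)
    stop("field must be larger than the detrending window")
  ok <- is.finite(theta)
  if (!is.null(mask)) ok <- ok & mask
  th0 <- ifelse(ok, theta, 0)
  Sr <- box_sum(cos(th0) * ok, window)
  Si <- box_sum(sin(th0) * ok, window)
  cnt <- box_sum(ok + 0, window)
  hw <- (window - 1L) / 2L
  ctr <- theta[(hw + 1):(H - hw), (hw + 1):(W - hw), drop = FALSE]
  ctr_ok <- ok[(hw + 1):(H - hw), (hw + 1):(W - hw), drop = FALSE]
  mu <- atan2(Si, Sr)
  d <- wrap_pi(ctr - mu)
  d[!ctr_ok | cnt < min_frac * window^2 | cnt < 2] <- NA_real_
  out <- matrix(NA_real_, H, W)
  out[(hw + 1):(H - hw), (hw + 1):(W - hw)] <- d
  if (!any(is.finite(out))) stop("no pixel has a usable detrending window")
  out
}

#' Spatial phase-fluctuation statistic Delta
#'
#' Delta is the standard deviation of the spatially detrended phase,
#' reported in rad/2pi (fractions of a cycle).
#'
#' @param dtheta detrended phase field (radians), as returned by
#'   \code{\link{spatial_detrend}}.
#' @return list with \code{delta} (rad/2pi) and \code{n_valid}.
#' @export
spatial_fluctuation <- function(dtheta) {
  v <- dtheta[is.finite(dtheta)]
  if (length(v) < 2) stop("need at least 2 valid detrended pixels")
  list(delta = sd(v) / (2 * pi), n_valid = length(v))
}

#' Convert a phase fraction to time
#'
#' A fluctuation of \code{value} rad/2pi at an oscillation period
#' \code{period} corresponds to \code{value * period} hours.
#'
#' @param value phase in rad/2pi (cycles).
#' @param period period in hours (> 0).
#' @return duration in hours.
#' @export
#' @examples
#' phase_to_time(0.017, 24) * 60   # about 25 minutes
phase_to_time <- function(value, period) {
  stopifnot(period > 0)
  value * period
}

#' Wave velocity from a sequence of phase fields
#'
#' Estimates the wave speed from the space-time structure of the phase:
#' for each frame the (spatially unwrapped) phase along a line of pixels
#' is regressed on position, and the velocity is
#' \code{pixel_size / (|slope| * period)} with the mean slope in
#' cycles/pixel.
#'
#' @param field a \code{phase_field}, or an H x W x T array of phases in
#'   radians.
#' @param pixel_size mm per pixel (taken from the field if absent).
#' @param period oscillation period in hours (taken from the field).
#' @param line list describing the pixel line: \code{type} "row" or
#'   "col" and \code{index}; defaults to the middle row.
#' @param frames which frames to use (default: frames where at least 90
#'   percent of the line is defined).
#' @param grad_tol minimum |slope| in cycles/pixel below which the
#'   velocity is flagged undefined.
#' @return list with \code{velocity} (mm/h, NA if undefined),
#'   \code{slope} (cycles/pixel), \code{defined}, \code{n_frames}.
#' @export
wave_velocity <- function(field, pixel_size = NULL, period = NULL,
                          line = NULL, frames = NULL, grad_tol = 1e-4) {
  if (inherits(field, "phase_field")) {
    theta <- field$theta
    pixel_size <- pixel_size %||% field$pixel_size
    period <- period %||% field$period
  } else theta <- field
  stopifnot(length(dim(theta)) == 3, !is.null(pixel_size), !is.null(period))
  H <- dim(theta)[1]; W <- dim(theta)[2]; nT <- dim(theta)[3]
  line <- line %||% list(type = "row", index = max(1L, H %/% 2L))
  prof <- function(k) {
    if (line$type == "row") theta[line$index, , k] else theta[, line$index, k]
  }
  npix <- if (line$type == "row") W else H
  if (is.null(frames)) {
    good <- vapply(seq_len(nT), function(k) mean(is.finite(prof(k))) >= 0.9, TRUE)
    frames <- which(good)
  }
  if (length(frames) < 1) stop("no usable frames for velocity estimation")
  slopes <- vapply(frames, function(k) {
    p <- unwrap_phase(prof(k)) / (2 * pi)   # cycles, unwrapped along the line
    ok <- is.finite(p)
    if (sum(ok) < 3) return(NA_real_)
    coef(lm(p[ok] ~ seq_len(npix)[ok]))[2]
  }, 0)
  slope <- mean(slopes, na.rm = TRUE)
  if (!is.finite(slope) || abs(slope) < grad_tol)
    return(list(velocity = NA_real_, slope = slope, defined = FALSE,
                n_frames = length(frames)))
  list(velocity = pixel_size / (abs(slope) * period), slope = slope,
       defined = TRUE, n_frames = length(frames))
}

#' Per-frame synchronization and fluctuation of an extracted movie
#'
#' Computes R(t) and Delta(t) over the frames of a \code{phase_field},
#' then aggregates Delta over the frames on which the phase is defined
#' for (almost) all oscillatory pixels, discarding half a period at each
#' end where envelope anchoring is weakest.
#'
#' @param field a \code{phase_field}.
#' @param window detrending window in pixels (default 7).
#' @param min_cover minimum fraction of oscillatory pixels that must be
#'   defined in a frame.
#' @param amp_snr_min frames whose median amplitude-to-noise ratio falls
#'   below this are dropped (damped recordings sink into the shot noise
#'   late on, where phase estimates are no longer meaningful).
#' @return list with per-frame vectors \code{R}, \code{delta}, the frame
#'   \code{time}s used, and scalars \code{delta_mean}, \code{delta_sd},
#'   \code{R_mean}.
#' @export
movie_sync_stats <- function(field, window = 7L, min_cover = 0.95,
                             amp_snr_min = 5) {
  stopifnot(inherits(field, "phase_field"))
  nT <- dim(field$theta)[3]
  n_osc <- sum(field$oscillatory)
  if (n_osc < 2) stop("fewer than 2 oscillatory pixels")
  cover <- vapply(seq_len(nT), function(k) {
    sum(is.finite(field$theta[, , k])) / n_osc
  }, 0)
  usable <- which(cover >= min_cover)
  if (!is.null(field$noise_est) && any(is.finite(field$noise_est))) {
    snr <- vapply(usable, function(k) {
      a <- field$amplitude[, , k]
      median(a[is.finite(a)]) / median(field$noise_est, na.rm = TRUE)
    }, 0)
    if (any(snr >= amp_snr_min)) usable <- usable[snr >= amp_snr_min]
  }
  if (!length(usable)) stop("no frame has sufficient phase coverage")
  half <- (field$period %||% 24) / 2
  tt <- field$time
  lo <- tt[usable[1]] + half
  hi <- tt[usable[length(usable)]] - half
  use <- usable[tt[usable] >= lo & tt[usable] <= hi]
  if (!length(use)) use <- usable
  R <- delta <- rep(NA_real_, length(use))
  for (m in seq_along(use)) {
    th <- field$theta[, , use[m]]
    R[m] <- order_parameter(th)$R
    dt_f <- spatial_detrend(th, window = window)
    delta[m] <- spatial_fluctuation(dt_f)$delta
  }
  list(R = R, delta = delta, time = tt[use],
       delta_mean = mean(delta), delta_sd = sd(delta), R_mean = mean(R))
}
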