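#' Moving-average smoothing of an intensity trace
#'
#' Centered moving average with the window expressed in hours (default
#' 6 h, matching the pre-filtering used before peak/trough detection).
#' At the boundaries the window shrinks one-sidedly so the trace keeps its
#' length, which preserves the anchoring of the envelopes.
#'
#' @param x numeric trace, uniformly sampled.
#' @param dt sampling interval in hours.
#' @param window smoothing window in hours; must span >= 2 samples and not
#'   exceed the trace.
#' @return smoothed trace of the same length.
#' @export
#' @examples
#' smooth_series(rep(1, 10), dt = 0.5)        # constant stays constant
smooth_series <- function(x, dt, window = 6) {
  n <- length(x)
  if (!n) stop("empty trace")
  half <- round(window / (2 * dt))
  if (2 * half + 1 < 2 && window / dt < 2)
    stop("`window` must span at least 2 samples")
  if (window > (n - 1) * dt) stop("`window` is longer than the trace")
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Detect peaks and troughs of a smoothed trace
#'
#' Local maxima and minima; plateaus are resolved to their midpoint, and
#' alternation is enforced by keeping the more extreme of two consecutive
#' same-type extrema.  A trace with fewer than 2 peaks or 2 troughs is
#' flagged non-oscillatory (no error is thrown).
#'
#' @param xs smoothed trace (length >= 3).
#' @return list with integer vectors \code{peaks} and \code{troughs},
#'   the merged alternating index/type sequence \code{extrema}, and the
#'   logical \code{oscillatory}.
#' @export
detect_extrema <- function(xs) {
  stopifnot(length(xs) >= 3)
  r <- rle(xs)
  k <- length(r$values)
  start <- cumsum(c(1L, r$lengths[-k]))
  mid <- start + (r$lengths - 1L) %/% 2L
  peaks <- troughs <- integer(0)
  if (k >= 3) {
    for (j in 2:(k - 1)) {
      if (r$values[j] > r$values[j - 1] && r$values[j] > r$values[j + 1])
        peaks <- c(peaks, mid[j])
      else if (r$values[j] < r$values[j - 1] && r$values[j] < r$values[j + 1])
        troughs <- c(troughs, mid[j])
    }
  }
  idx <- c(peaks, troughs)
  type <- rep(c(1L, -1L), c(length(peaks), length(troughs)))
  o <- order(idx)
  idx <- idx[o]; type <- type[o]
  # enforce alternation: among consecutive same-type runs keep the extreme
  keep <- rep(TRUE, length(idx))
  j <- 1L
  while (j < length(idx)) {
    nxt <- j + 1L
    if (keep[j] && keep[nxt] && type[j] == type[nxt]) {
      a <- xs[idx[j]]; b <- xs[idx[nxt]]
      drop <- if (type[j] == 1L) {
        if (b > a) j else nxt
      } else {
        if (b < a) j else nxt
      }
      keep[drop] <- FALSE
      if (drop == j) j <- nxt else j <- j  # re-test current survivor
      if (drop == nxt) next
    } else {
      j <- nxt
    }
  }
  idx <- idx[keep]; type <- type[keep]
  peaks <- idx[type == 1L]; troughs <- idx[type == -1L]
  list(peaks = peaks, troughs = troughs,
       extrema = data.frame(index = idx, type = type),
       oscillatory = length(peaks) >= 2 && length(troughs) >= 2)
}

#' Build the peak and trough envelopes of a trace
#'
#' Piecewise-linear interpolation through the detected peaks gives the
#' upper envelope h(t), through the troughs the lower envelope l(t); each
#' is defined only between its first and last anchor (no extrapolation).
#' Envelope values are taken from the smoothed trace.
#'
#' @param xs smoothed trace.
#' @param time time axis (hours).
#' @param peaks,troughs extremum indices (each length >= 2).
#' @return an \code{envelope_pair}: vectors \code{h}, \code{l} (NA outside
#'   their domains) and the anchor times/values.
#' @export
build_envelopes <- function(xs, time, peaks, troughs) {
  stopifnot(length(peaks) >= 2, length(troughs) >= 2)
  h <- approx(time[peaks], xs[peaks], xout = time)$y
  l <- approx(time[troughs], xs[troughs], xout = time)$y
  structure(list(h = h, l = l,
                 peak_times = time[peaks], trough_times = time[troughs],
                 peak_values = xs[peaks], trough_values = xs[troughs],
                 peaks = peaks, troughs = troughs),
            class = "envelope_pair")
}

#' Amplitude from an envelope pair
#'
#' A(t) = (h(t) - l(t)) / 2 on the intersection of the two envelope
#' domains; NA elsewhere.
#'
#' @param env an \code{\link{build_envelopes}} result.
#' @return numeric amplitude vector.
#' @export
envelope_amplitude <- function(env) {
  A <- (env$h - env$l) / 2
  A[!is.finite(env$h) | !is.finite(env$l)] <- NA_real_
  A
}

# Merged alternating extrema restricted to where both envelopes exist.
merged_extrema <- function(env) {
  idx <- c(env$peaks, env$troughs)
  type <- rep(c(1L, -1L), c(length(env$peaks), length(env$troughs)))
  o <- order(idx)
  data.frame(index = idx[o], type = type[o])
}

#' Envelope-normalized phase of a trace
#'
#' The smoothed signal is normalized between its envelopes,
#' \eqn{y(t) = (2 x_s(t) - h - l) / (h - l)}, clipped to [-1, 1], and the
#' phase is \eqn{\theta = \arccos(y)} on descending (peak to trough)
#' segments and \eqn{2\pi k - \arccos(y)} on ascending segments,
#' accumulated so that theta is continuous, increases by 2pi per cycle,
#' and is 0 (mod 2pi) at every detected peak and pi at every trough.
#' Defined between the first and last extremum covered by both envelopes.
#'
#' @param xs smoothed trace.
#' @param time time axis.
#' @param env an \code{envelope_pair}.
#' @return list with \code{theta} (radians, unwrapped, NA outside the
#'   domain) and \code{ok} (FALSE if the pixel is non-oscillatory, e.g.
#'   zero amplitude anywhere on the domain).
#' @export
envelope_phase <- function(xs, time, env) {
  A <- envelope_amplitude(env)
  ex <- merged_extrema(env)
  dom <- which(is.finite(A))
  theta <- rep(NA_real_, length(xs))
  ex <- ex[ex$index >= dom[1] & ex$index <= dom[length(dom)], , drop = FALSE]
  if (nrow(ex) < 2) return(list(theta = theta, ok = FALSE))
  if (any(A[dom] <= 0)) return(list(theta = theta, ok = FALSE))
  # cumulative phase at each extremum: peaks = 0 mod 2pi, troughs = pi
  base <- numeric(nrow(ex))
  base[1] <- if (ex$type[1] == 1L) 0 else pi
  for (j in 2:nrow(ex)) base[j] <- base[j - 1] + pi
  y <- (2 * xs - env$h - env$l) / (env$h - env$l)
  y <- pmin(1, pmax(-1, y))
  for (j in seq_len(nrow(ex) - 1)) {
    i0 <- ex$index[j]; i1 <- ex$index[j + 1]
    seg <- i0:i1
    if (ex$type[j] == 1L) {            # descending: peak -> trough
      theta[seg] <- base[j] + acos(y[seg])
    } else {                           # ascending: trough -> peak
      theta[seg] <- base[j + 1] - acos(y[seg])
    }
  }
  theta[ex$index] <- base               # exact at anchors
  list(theta = theta, ok = TRUE)
}

# Unwrap a phase sequence (radians) by accumulating wrapped increments.
unwrap_phase <- function(th) {
  ok <- is.finite(th)
  v <- th[ok]
  if (length(v) > 1) v <- v[1] + cumsum(c(0, wrap_pi(diff(v))))
  th[ok] <- v
  th
}

#' Hilbert-transform phase and amplitude
#'
#' Analytic-signal phase and magnitude of the midline-detrended smoothed
#' trace, used as an independent cross-check of the envelope-based
#' extraction (the two agree closely on well-behaved oscillatory traces).
#'
#' @param x raw trace.
#' @param time time axis.
#' @param window smoothing window in hours passed to
#'   \code{\link{smooth_series}}.
#' @return list with \code{theta} (radians, unwrapped, NA outside the
#'   envelope domain), \code{amplitude}, and the index \code{domain}.
#' @export
hilbert_phase <- function(x, time, window = 6) {
  dt <- time[2] - time[1]
  xs <- smooth_series(x, dt, window)
  ext <- detect_extrema(xs)
  n <- length(xs)
  if (ext$oscillatory) {
    env <- build_envelopes(xs, time, ext$peaks, ext$troughs)
    mid <- (env$h + env$l) / 2
    dom <- which(is.finite(mid))
  } else {
    mid <- rep(mean(xs), n)
    dom <- seq_len(n)
  }
  z <- xs[dom] - mid[dom]
  m <- length(z)
  X <- fft(z)
  w <- numeric(m)
  if (m %% 2 == 0) {
    w[1] <- 1; w[m / 2 + 1] <- 1
    if (m > 2) w[2:(m / 2)] <- 2
  } else {
    w[1] <- 1
    if (m > 1) w[2:((m + 1) / 2)] <- 2
  }
  a <- fft(X * w, inverse = TRUE) / m
  theta <- rep(NA_real_, n); amp <- rep(NA_real_, n)
  theta[dom] <- unwrap_phase(Arg(a))    # cos(wt) -> analytic e^{iwt}, phase wt
  amp[dom] <- Mod(a)
  list(theta = theta, amplitude = amp, domain = dom)
}

# Full envelope chain for a single pixel trace.  A pixel counts as
# oscillatory only if it has >= 2 peaks and troughs, positive amplitude on
# the whole envelope domain, and a median amplitude at least `min_snr`
# times the residual (trace minus smoothed) noise level: rhythmless traces
# otherwise produce spurious tiny extrema from smoothed noise.
extract_pixel <- function(x, time, window = 6, min_snr = 3) {
  fail <- list(theta = rep(NA_real_, length(x)),
               amplitude = rep(NA_real_, length(x)),
               oscillatory = FALSE)
  dt <- time[2] - time[1]
  xs <- smooth_series(x, dt, window)
  ext <- detect_extrema(xs)
  if (!ext$oscillatory) return(fail)
  env <- build_envelopes(xs, time, ext$peaks, ext$troughs)
  ph <- envelope_phase(xs, time, env)
  if (!ph$ok) return(fail)
  A <- envelope_amplitude(env)
  resid <- sd(x - xs)
  if (resid > 0 && median(A[is.finite(A)]) < min_snr * resid) return(fail)
  list(theta = ph$theta, amplitude = A,
       oscillatory = TRUE, envelope = env, smoothed = xs)
}

#' Extract per-pixel phase and amplitude from a movie
#'
#' Runs the envelope chain (smooth, detect extrema, build envelopes,
#' normalize) on every valid pixel of a movie.  Pixels with fewer than two
#' peaks or troughs, or with vanishing amplitude, are flagged
#' non-oscillatory and masked, not imputed.
#'
#' @param movie a \code{\link{movie_grid}}.
#' @param window smoothing window, hours.
#' @param min_snr minimum ratio of the median envelope amplitude to the
#'   residual noise level for a pixel to count as oscillatory.
#' @return a \code{phase_field} object: arrays \code{theta} (radians,
#'   unwrapped in time, NA outside each pixel's domain) and
#'   \code{amplitude}; matrix \code{oscillatory}; \code{time};
#'   \code{pixel_size}; \code{period} (median peak-to-peak interval).
#' @export
#' @examples
#' mv <- generate_movie(synthetic_movie_spec(grid_shape = c(12, 12), seed = 1))
#' pf <- extract_phase_amplitude(mv$movie)
#' mean(pf$oscillatory)
extract_phase_amplitude <- function(movie, window = 6, min_snr = 3) {
  stopifnot(inherits(movie, "movie_grid"))
  d <- dim(movie$intensities)
  H <- d[1]; W <- d[2]; nT <- d[3]
  theta <- array(NA_real_, d)
  amplitude <- array(NA_real_, d)
  oscillatory <- matrix(FALSE, H, W)
  noise_est <- matrix(NA_real_, H, W)
  periods <- c()
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!movie$mask[i, j]) next
    px <- extract_pixel(movie$intensities[i, j, ], movie$time, window, min_snr)
    if (!px$oscillatory) next
    theta[i, j, ] <- px$theta
    amplitude[i, j, ] <- px$amplitude
    oscillatory[i, j] <- TRUE
    noise_est[i, j] <- sd(movie$intensities[i, j, ] - px$smoothed)
    periods <- c(periods, diff(px$envelope$peak_times))
  }
  structure(list(theta = theta, amplitude = amplitude,
                 oscillatory = oscillatory, noise_est = noise_est,
                 time = movie$time, pixel_size = movie$pixel_size,
                 period = if (length(periods)) median(periods) else NA_real_),
            class = "phase_field")
}

#' @export
print.phase_field <- function(x, ...) {
  cat(sprintf("<phase_field> %d x %d pixels, %d frames; %.0f%% oscillatory; period ~%.1f h\n",
              dim(x$theta)[1], dim(x$theta)[2], dim(x$theta)[3],
              100 * mean(x$oscillatory), x$period))
  invisible(x)
}
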