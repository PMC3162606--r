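test_that("smoothing preserves constants and matches the box-filter gain", {
  expect_equal(smooth_series(rep(3.5, 30), dt = 0.5), rep(3.5, 30))
  # cosine attenuation: closed-form Dirichlet gain of the centred window
  tt <- seq(0, 120, by = 0.5)
  x <- cos(2 * pi * tt / 24)
  xs <- smooth_series(x, dt = 0.5, window = 6)
  n_win <- 2 * round(6 / (2 * 0.5)) + 1
  g <- ma_gain(n_win, 0.5, 24)
  interior <- 20:(length(tt) - 20)
  expect_equal(xs[interior], g * x[interior], tolerance = 1e-10)
})

test_that("an impulse smears into a bump of window width", {
  x <- c(rep(0, 20), 1, rep(0, 20))
  xs <- smooth_series(x, dt = 1, window = 6)
  expect_equal(sum(xs > 0), 7)          # 2*3+1 samples at 1 h spacing
  expect_equal(max(xs), 1 / 7)
})

test_that("smoothing rejects bad windows", {
  expect_error(smooth_series(rep(1, 5), dt = 1, window = 10), "longer")
  expect_error(smooth_series(c(1, 2, 3), dt = 2, window = 1), "2 samples")
})

test_that("extrema of a cosine fall on the analytic times", {
  tt <- seq(0, 72, by = 0.5)
  ext <- detect_extrema(cos(2 * pi * tt / 24))
  expect_equal(tt[ext$peaks], c(24, 48), tolerance = 0.5)   # interior maxima
  expect_equal(tt[ext$troughs], c(12, 36, 60), tolerance = 0.5)
  expect_true(ext$oscillatory)
})

test_that("monotone ramps and plateaus are handled", {
  expect_false(detect_extrema(seq_len(50))$oscillatory)
  # plateau at the top: midpoint taken
  x <- c(1, 2, 3, 3, 3, 2, 1)
  ext <- detect_extrema(x)
  expect_equal(ext$peaks, 4L)
})

test_that("alternation keeps the more extreme of same-type neighbours", {
  # two local maxima (4 at i=4, 5 at i=8) with no trough between after the
  # shallow dip is not a strict minimum of the run sequence
  x <- c(0, 2, 4, 3.9, 4.5, 5, 3, 0.5, 3, 0)
  ext <- detect_extrema(x)
  types <- ext$extrema$type
  expect_true(all(abs(diff(types)) == 2))   # strict alternation
})

test_that("damped-cosine extrema match the analytic maxima", {
  tau <- 100; period <- 24
  tt <- seq(0, 120, by = 0.5)
  x <- damped_cosine(tt, tau = tau)
  ext <- detect_extrema(smooth_series(x, 0.5))
  # oracle: numerically locate the maxima of the closed form
  oracle <- vapply(c(24, 48, 72, 96), function(t0) {
    optimize(function(t) damped_cosine(t, tau = tau),
             c(t0 - 6, t0 + 6), maximum = TRUE)$maximum
  }, 0)
  found <- tt[ext$peaks]
  found <- found[found > 6 & found < 114]
  expect_equal(length(found), 4)
  expect_lt(max(abs(found - oracle)), 0.5 + 1e-9)  # within one sample
  # same count as the undamped reference
  ext0 <- detect_extrema(smooth_series(damped_cosine(tt, tau = Inf), 0.5))
  n_int <- function(e, idx) sum(tt[e$peaks] > 6 & tt[e$peaks] < 114)
  expect_equal(n_int(ext), n_int(ext0))
})

test_that("envelopes of a pure cosine are flat at baseline +/- amplitude", {
  tt <- seq(0, 120, by = 0.5)
  x <- damped_cosine(tt, baseline = 100, A0 = 30, tau = Inf)
  ext <- detect_extrema(x)          # unsmoothed: no attenuation
  env <- build_envelopes(x, tt, ext$peaks, ext$troughs)
  dom <- is.finite(env$h) & is.finite(env$l)
  expect_equal(unname(env$h[dom]), rep(130, sum(dom)), tolerance = 1e-3)
  expect_equal(unname(env$l[dom]), rep(70, sum(dom)), tolerance = 1e-3)
  A <- envelope_amplitude(env)
  expect_equal(unname(A[dom]), rep(30, sum(dom)), tolerance = 1e-3)
})

test_that("linearly decaying peaks give the straight chord through them", {
  # synthetic anchor points: peaks at t = 0, 10, 20 with values 10 - k
  tt <- seq(0, 20, by = 1)
  xs <- rep(0, 21); xs[c(1, 11, 21)] <- c(10, 9, 8); xs[c(6, 16)] <- -5
  env <- build_envelopes(xs, tt, peaks = c(1, 11, 21), troughs = c(6, 16))
  expect_equal(env$h, 10 - 0.1 * tt, tolerance = 1e-12)
})

test_that("damped-cosine envelope stays within the chord error bound", {
  tau <- 100; A0 <- 30
  tt <- seq(0, 120, by = 0.5)
  x <- damped_cosine(tt, tau = tau, A0 = A0)
  ext <- detect_extrema(x)
  env <- build_envelopes(x, tt, ext$peaks, ext$troughs)
  true_env <- 100 + A0 * exp(-tt / tau)
  dom <- is.finite(env$h)
  # oracle bound: worst chord deviation of exp(-t/tau) over one period,
  # plus the (tiny) offset of the damped maxima below the envelope
  chord_bound <- A0 * max(abs(exp(-tt / tau) -
    approx(c(0, 24), exp(-c(0, 24) / tau), xout = tt)$y), na.rm = TRUE)
  peak_offset <- A0 - max(x - 100)
  expect_lt(max(abs(env$h[dom] - true_env[dom])),
            chord_bound + peak_offset + 1e-6)
  A <- envelope_amplitude(env)
  dom2 <- is.finite(A)
  expect_lt(max(abs(A[dom2] - A0 * exp(-tt[dom2] / tau))),
            2 * (chord_bound + peak_offset) + 1e-6)
})

test_that("phase of a pure cosine is linear, zero at peaks, pi at troughs", {
  tt <- seq(0, 120, by = 0.5)
  x <- damped_cosine(tt, tau = Inf)
  ext <- detect_extrema(x)
  env <- build_envelopes(x, tt, ext$peaks, ext$troughs)
  ph <- envelope_phase(x, tt, env)
  expect_true(ph$ok)
  dom <- which(is.finite(ph$theta))
  # theta - 2 pi t / 24 constant on the domain
  resid <- ph$theta[dom] - 2 * pi * tt[dom] / 24
  expect_lt(diff(range(resid)), 5e-3)
  # anchors exact
  expect_equal(ph$theta[ext$troughs[2]] %% (2 * pi), pi, tolerance = 1e-12)
  expect_equal(ph$theta[ext$peaks[2]] %% (2 * pi), 0, tolerance = 1e-12)
})

test_that("theta advances by exactly 2 pi between consecutive peaks", {
  for (s in 1:3) {
    set.seed(s)
    tt <- seq(0, 120, by = 0.5)
    x <- damped_cosine(tt, tau = 100) + rnorm(length(tt), 0, 0.5)
    px <- extract_pixel(x, tt)
    expect_true(px$oscillatory)
    pk <- px$envelope$peaks
    pk <- pk[is.finite(px$theta[pk])]
    expect_equal(diff(px$theta[pk]), rep(2 * pi, length(pk) - 1),
                 tolerance = 1e-9)
  }
})

test_that("phase and scaled amplitude are invariant under affine intensity maps", {
  tt <- seq(0, 120, by = 0.5)
  set.seed(11)
  x <- damped_cosine(tt, tau = 100) + rnorm(length(tt), 0, 0.3)
  a <- 3.7; b <- 250
  p1 <- extract_pixel(x, tt)
  p2 <- extract_pixel(a * x + b, tt)
  expect_equal(p2$theta, p1$theta, tolerance = 1e-9)
  expect_equal(p2$amplitude, a * p1$amplitude, tolerance = 1e-9)
})

test_that("envelope phase agrees with the Hilbert transform on damped fixtures", {
  tt <- seq(0, 120, by = 0.5)
  for (s in 1:3) {
    set.seed(s)
    x <- damped_cosine(tt, tau = 100) + rnorm(length(tt), 0, 0.3)
    px <- extract_pixel(x, tt)
    hb <- hilbert_phase(x, tt)
    # discard half a period at each end, compare circular difference
    ok <- is.finite(px$theta) & is.finite(hb$theta) & tt > 12 & tt < 108
    d <- atan2(sin(px$theta[ok] - hb$theta[ok]),
               cos(px$theta[ok] - hb$theta[ok]))
    rms <- sqrt(mean(d^2)) / (2 * pi)
    expect_lt(rms, 0.05)
    # amplitudes agree within 5 percent away from the boundaries
    rel <- abs(hb$amplitude[ok] / px$amplitude[ok] - 1)
    expect_lt(median(rel), 0.05)
  }
})

test_that("hilbert phase of a pure cosine is linear with matching amplitude", {
  tt <- seq(0, 120, by = 0.5)
  hb <- hilbert_phase(damped_cosine(tt, A0 = 30, tau = Inf), tt)
  ok <- is.finite(hb$theta) & tt > 12 & tt < 108
  fit <- lm(hb$theta[ok] ~ tt[ok])
  expect_equal(unname(coef(fit)[2]), 2 * pi / 24, tolerance = 1e-3)
  # amplitude of the smoothed trace: attenuated by the box-filter gain
  g <- ma_gain(2 * round(6 / (2 * 0.5)) + 1, 0.5, 24)
  expect_equal(median(hb$amplitude[ok]), g * 30, tolerance = 0.02)
})

test_that("non-oscillatory pixels are masked, not imputed", {
  tt <- seq(0, 120, by = 0.5)
  set.seed(9)
  x <- array(0, dim = c(2, 1, length(tt)))
  x[1, 1, ] <- damped_cosine(tt, tau = 100)
  x[2, 1, ] <- 100 + rnorm(length(tt), 0, 0.1) + 0.05 * tt  # trend, no rhythm
  mv <- movie_grid(x, tt, pixel_size = 0.01)
  pf <- extract_phase_amplitude(mv)
  expect_true(pf$oscillatory[1, 1])
  expect_true(all(is.na(pf$theta[2, 1, ])))
})
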