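# Fixtures and independent oracles shared across the suite.

# Closed-form damped cosine trace: baseline + A0 exp(-t/tau) cos(2 pi t / T).
damped_cosine <- function(time, baseline = 100, A0 = 30, tau = Inf, period = 24,
                          phase0 = 0) {
  damp <- if (is.finite(tau)) exp(-time / tau) else rep(1, length(time))
  baseline + A0 * damp * cos(2 * pi * (time / period - phase0))
}

# Moving-average gain of a cosine of period `period` for a centred window
# of n samples at spacing dt (Dirichlet kernel), the closed-form frequency
# response of the box filter.
ma_gain <- function(n, dt, period) {
  r <- pi * dt / period
  sin(n * r) / (n * sin(r))
}

# Brute-force circular window detrend: the O(H W w^2) double loop the fast
# implementation must reproduce exactly.
brute_detrend <- function(theta, w) {
  H <- nrow(theta); W <- ncol(theta); hw <- (w - 1) / 2
  out <- matrix(NA_real_, H, W)
  for (i in (hw + 1):(H - hw)) for (j in (hw + 1):(W - hw)) {
    win <- theta[(i - hw):(i + hw), (j - hw):(j + hw)]
    mu <- atan2(mean(sin(win)), mean(cos(win)))
    d <- theta[i, j] - mu
    out[i, j] <- atan2(sin(d), cos(d))
  }
  out
}

# Small, fast lattice configuration for machinery tests.
tiny_config <- function(K, ..., seed = 1) {
  sim_config(K = K, N1 = 8L, N2 = 8L, NL = 2L, t_end = 60, transient = 30,
             seed = seed, ...)
}

# Fabricate a surface_trace with prescribed per-pixel frequencies, for
# testing the run classifier without simulating.
fake_trace <- function(nu, n1 = 5, n2 = 5, t_end = 100, delta_level = 0.01) {
  stopifnot(length(nu) == n1 * n2)
  time <- seq(0, t_end, by = 1)
  surface <- array(0, dim = c(n1, n2, length(time)))
  for (k in seq_along(time)) surface[, , k] <- matrix(nu * time[k], n1, n2)
  structure(list(time = time,
                 delta = rep(delta_level, length(time)),
                 R = rep(0.99, length(time)),
                 surface = surface,
                 config = sim_config(K = 0.1, N1 = n1, N2 = n2, NL = 1L,
                                     t_end = t_end, transient = t_end / 2,
                                     seed = 1),
                 defect = matrix(FALSE, n1, n2), n_live = n1 * n2),
            class = "surface_trace")
}
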