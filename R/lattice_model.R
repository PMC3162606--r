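#' Configuration of the lattice oscillator model
#'
#' Parameters of the 3-D lattice of nearest-neighbour coupled phase
#' oscillators: N1 x N2 x NL sites, natural frequencies drawn
#' Normal(\code{omega_mean}, \code{sigma_omega}), a pacemaker plane at
#' x = 1 whose frequencies are multiplied by \code{pacemaker_boost},
#' dead-cell defects on the imaged surface layer (z = 1) with probability
#' \code{gamma}, coupling constant K over the six von-Neumann neighbours
#' (open boundaries), and white dynamical noise of intensity D.
#' Integration is fourth-order Runge-Kutta with time step \code{dt} from
#' the completely synchronized initial condition theta = 0.
#'
#' The noise term can be integrated under two conventions.  The default
#' \code{"forcing"} treats the noise as a per-step-constant random forcing
#' with variance 2D (so each step adds sd \code{sqrt(2 D) * dt}), the
#' convention under which the published robustness thresholds for this
#' class of model are of the observed magnitude.  \code{"ito"} is the
#' consistent stochastic-integral convention (each step adds sd
#' \code{sqrt(2 D dt)}), which realizes the nominal covariance
#' \eqn{\langle\xi_i(t)\xi_j(s)\rangle = 2D\delta_{ij}\delta(t-s)}
#' exactly, with phase variance growing as 2 D t.  Both schemes coincide
#' when D = 0.
#'
#' @param K coupling constant (>= 0).
#' @param N1,N2,NL lattice width, length and number of layers.
#' @param omega_mean mean natural frequency (rad per time unit); one model
#'   cycle 2 pi / omega_mean corresponds to 24 h.
#' @param sigma_omega standard deviation of the natural frequencies.
#' @param gamma defect probability on the surface layer, in [0, 1].
#' @param D dynamical noise intensity.
#' @param pacemaker_boost factor applied to each drawn omega_i on the
#'   x = 1 plane (1.04 = 4 percent faster).
#' @param dt integration step.
#' @param t_end simulation horizon (time units).
#' @param transient initial duration discarded by steady-state summaries.
#' @param obs_interval interval between recorded surface fields.
#' @param seed integer seed (frequencies, defects, and noise stream).
#' @param normalize_coupling if TRUE the coupling sum is divided by the
#'   live-neighbour count; the default FALSE uses the plain
#'   nearest-neighbour sum.
#' @param noise_scheme "forcing" (default) or "ito"; see Details.
#' @return an object of class \code{sim_config}.
#' @export
#' @examples
#' cfg <- sim_config(K = 0.12, seed = 1, NL = 2, t_end = 20)
#' tr <- simulate_lattice(cfg)
#' range(tr$delta)
sim_config <- function(K, N1 = 20L, N2 = 20L, NL = 10L,
                       omega_mean = 1, sigma_omega = 0.05,
                       gamma = 0, D = 0, pacemaker_boost = 1.04,
                       dt = 0.02, t_end = 500, transient = 250,
                       obs_interval = 1, seed = 1,
                       normalize_coupling = FALSE,
                       noise_scheme = c("forcing", "ito")) {
  noise_scheme <- match.arg(noise_scheme)
  stopifnot(K >= 0, N1 >= 1, N2 >= 1, NL >= 1, dt > 0,
            gamma >= 0, gamma <= 1, pacemaker_boost > 0,
            sigma_omega >= 0, D >= 0, t_end > 0,
            transient >= 0, transient < t_end, obs_interval >= dt)
  structure(list(K = K, N1 = as.integer(N1), N2 = as.integer(N2),
                 NL = as.integer(NL), omega_mean = omega_mean,
                 sigma_omega = sigma_omega, gamma = gamma, D = D,
                 pacemaker_boost = pacemaker_boost, dt = dt,
                 t_end = t_end, transient = transient,
                 obs_interval = obs_interval, seed = as.integer(seed),
                 normalize_coupling = normalize_coupling,
                 noise_scheme = noise_scheme),
            class = "sim_config")
}

#' Build a lattice state from a configuration
#'
#' Draws the natural frequencies (iid normal; pacemaker plane multiplied
#' by the boost), draws the surface defects, deletes them from the
#' dynamics entirely, and assembles the padded arrays used by the
#' integrator.  Deterministic given the seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @param omega_override optional N1 x N2 x NL array replacing the drawn
#'   frequencies (after which the pacemaker boost is NOT applied); used
#'   for controlled experiments and tests.
#' @return an object of class \code{lattice_state} with, among others,
#'   \code{omega} (N1 x N2 x NL array, NA at defects), \code{defect}
#'   (N1 x N2 logical), \code{n_live}, and the current phases.
#' @export
build_lattice <- function(config, omega_override = NULL) {
  stopifnot(inherits(config, "sim_config"))
  N1 <- config$N1; N2 <- config$N2; NL <- config$NL
  P1 <- N1 + 2L; P2 <- N2 + 2L; PL <- NL + 2L
  m <- P1 * P2 * PL
  sx <- 1L; sy <- P1; sz <- P1 * P2
  set.seed(config$seed)
  omega_int <- array(rnorm(N1 * N2 * NL, config$omega_mean, config$sigma_omega),
                     dim = c(N1, N2, NL))
  omega_int[1, , ] <- omega_int[1, , ] * config$pacemaker_boost
  defect <- matrix(runif(N1 * N2) < config$gamma, N1, N2)
  noise_seed <- sample.int(.Machine$integer.max - 1L, 1)
  if (!is.null(omega_override)) {
    stopifnot(all(dim(omega_override) == c(N1, N2, NL)))
    omega_int <- array(omega_override, dim = c(N1, N2, NL))
  }
  live <- array(FALSE, dim = c(P1, P2, PL))
  live[2:(N1 + 1), 2:(N2 + 1), 2:(NL + 1)] <- TRUE
  dd <- array(FALSE, dim = c(P1, P2, PL))
  dd[2:(N1 + 1), 2:(N2 + 1), 2][defect] <- TRUE
  live[dd] <- FALSE
  om_pad <- array(0, dim = c(P1, P2, PL))
  om_pad[2:(N1 + 1), 2:(N2 + 1), 2:(NL + 1)] <- omega_int
  om_pad[!live] <- 0
  omega <- as.numeric(om_pad)
  lv <- array(as.numeric(live), dim = c(P1, P2, PL))
  deg <- array(0, dim = c(P1, P2, PL))
  deg[2:(P1 - 1), , ] <- deg[2:(P1 - 1), , ] + lv[1:(P1 - 2), , ] + lv[3:P1, , ]
  deg[, 2:(P2 - 1), ] <- deg[, 2:(P2 - 1), ] + lv[, 1:(P2 - 2), ] + lv[, 3:P2, ]
  deg[, , 2:(PL - 1)] <- deg[, , 2:(PL - 1)] + lv[, , 1:(PL - 2)] + lv[, , 3:PL]
  isolated <- live & deg == 0
  kn <- array(0, dim = c(P1, P2, PL))
  if (config$normalize_coupling) {
    kn[live & deg > 0] <- config$K / deg[live & deg > 0]
  } else {
    kn[live] <- config$K
  }
  kn[isolated] <- 0   # isolated sites drift at their own frequency
  # surface display: z = 1 where live, else the shallowest live site below
  surf_index <- matrix(NA_integer_, N1, N2)
  for (y in seq_len(N2)) for (x in seq_len(N1)) {
    zl <- which(live[x + 1, y + 1, ])
    if (length(zl)) surf_index[x, y] <- (zl[1] - 1L) * sz + y * sy + x
  }
  structure(list(config = config,
                 theta = numeric(m),          # padded; synchronized init
                 omega_array = {oa <- omega_int; oa[, , 1][defect] <- NA; oa},
                 defect = defect,
                 live = live, omega = omega, kn = as.numeric(kn),
                 mask = as.numeric(lv), deg = deg,
                 strides = c(sx = sx, sy = sy, sz = sz),
                 pad_dim = c(P1, P2, PL),
                 n_live = sum(live), n_isolated = sum(isolated),
                 surf_index = surf_index, noise_seed = noise_seed,
                 time = 0),
            class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<lattice_state> %d x %d x %d, %d live oscillators (%d surface defects), t = %.1f\n",
              cfg$N1, cfg$N2, cfg$NL, x$n_live, sum(x$defect), x$time))
  invisible(x)
}

# Per-step noise increment sd for a config.
noise_increment_sd <- function(config) {
  if (config$D <= 0) return(0)
  switch(config$noise_scheme,
         forcing = sqrt(2 * config$D) * config$dt,
         ito     = sqrt(2 * config$D * config$dt))
}

#' Advance a lattice state
#'
#' Integrates the deterministic drift
#' \eqn{\dot\theta_i = \omega_i + K \sum_{j \in nbr(i)} \sin(\theta_j - \theta_i)}
#' by one or more RK4 steps of length dt, adding the white-noise increment
#' after each step.
#'
#' @param state a \code{\link{build_lattice}} result.
#' @param n_steps number of RK4 steps.
#' @return the updated \code{lattice_state}.
#' @export
step_lattice <- function(state, n_steps = 1L) {
  stopifnot(inherits(state, "lattice_state"), n_steps >= 1)
  cfg <- state$config
  live_idx0 <- which(state$live) - 1L
  out <- .lattice_integrate(state$theta, state$omega, state$kn, state$mask,
                            state$strides["sx"], state$strides["sy"],
                            state$strides["sz"],
                            noise_increment_sd(cfg), cfg$dt,
                            as.integer(n_steps), as.integer(n_steps),
                            live_idx0,
                            state$noise_seed + round(state$time / cfg$dt))
  state$theta[live_idx0 + 1L] <- out[, ncol(out)]
  state$time <- state$time + n_steps * cfg$dt
  state
}

#' Surface phase field of a lattice state
#'
#' The displayed z = 1 field: at defect pixels the phase of the live
#' oscillator directly beneath (smallest z > 1), emulating the
#' bioluminescence of interior neurons showing through; pixels whose
#' whole column is dead are NA.
#'
#' @param state a \code{lattice_state}.
#' @param theta optional padded phase vector (defaults to the state's
#'   current phases).
#' @return N1 x N2 matrix of phases (radians).
#' @export
surface_phase <- function(state, theta = NULL) {
  th <- theta %||% state$theta
  out <- matrix(NA_real_, state$config$N1, state$config$N2)
  ok <- !is.na(state$surf_index)
  out[ok] <- th[state$surf_index[ok] + 1L]
  out
}

#' Spatial fluctuation of a model surface field
#'
#' Delta of a model phase field, computed with the same detrend/std
#' machinery as the imaging pipeline but with a 3 x 3 window, since model
#' cells are single oscillators.
#'
#' @param theta_mat N1 x N2 phase matrix (radians).
#' @param window detrending window (default 3).
#' @return Delta in rad/2pi.
#' @export
model_delta <- function(theta_mat, window = 3L) {
  spatial_fluctuation(spatial_detrend(theta_mat, window = window))$delta
}

#' Simulate the lattice model
#'
#' Builds the lattice, integrates to \code{t_end}, and records the
#' displayed surface field, Delta(t) (3 x 3 window) and R(t) at every
#' observation interval.  Reproducible given the config seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @param theta0 optional initial padded phase vector or a single number
#'   added to the synchronized initial condition.
#' @param keep "surface" (default) records the N1 x N2 surface fields;
#'   "all" additionally records the phases of every live oscillator.
#' @param omega_override passed to \code{\link{build_lattice}}.
#' @return an object of class \code{surface_trace}: \code{time},
#'   \code{delta}, \code{R}, array \code{surface} (N1 x N2 x n_obs),
#'   optionally \code{theta_live} (n_live x n_obs), the \code{config} and
#'   the defect mask.
#' @export
simulate_lattice <- function(config, theta0 = NULL,
                             keep = c("surface", "all"),
                             omega_override = NULL) {
  keep <- match.arg(keep)
  state <- build_lattice(config, omega_override = omega_override)
  if (!is.null(theta0)) {
    if (length(theta0) == 1) {
      state$theta[state$live] <- theta0
    } else {
      stopifnot(length(theta0) == length(state$theta))
      state$theta <- theta0 * state$mask
    }
  }
  n_steps <- round(config$t_end / config$dt)
  stride <- max(1L, round(config$obs_interval / config$dt))
  live_idx0 <- which(state$live) - 1L
  out <- .lattice_integrate(state$theta, state$omega, state$kn, state$mask,
                            state$strides["sx"], state$strides["sy"],
                            state$strides["sz"],
                            noise_increment_sd(config), config$dt,
                            as.integer(n_steps), stride, live_idx0,
                            state$noise_seed)
  n_obs <- ncol(out)
  time <- seq(0, by = stride * config$dt, length.out = n_obs)
  # map live rows back into padded positions to extract surface fields
  pos <- integer(length(state$theta))
  pos[live_idx0 + 1L] <- seq_along(live_idx0)
  N1 <- config$N1; N2 <- config$N2
  surf_rows <- matrix(NA_integer_, N1, N2)
  ok <- !is.na(state$surf_index)
  surf_rows[ok] <- pos[state$surf_index[ok] + 1L]
  surface <- array(NA_real_, dim = c(N1, N2, n_obs))
  for (k in seq_len(n_obs)) {
    f <- matrix(NA_real_, N1, N2)
    f[ok] <- out[surf_rows[ok], k]
    surface[, , k] <- f
  }
  delta <- if (N1 >= 3 && N2 >= 3)
    vapply(seq_len(n_obs), function(k) model_delta(surface[, , k]), 0)
  else rep(NA_real_, n_obs)
  R <- vapply(seq_len(n_obs), function(k) order_parameter(surface[, , k])$R, 0)
  res <- list(time = time, delta = delta, R = R, surface = surface,
              config = config, defect = state$defect, n_live = state$n_live)
  if (keep == "all") res$theta_live <- out
  structure(res, class = "surface_trace")
}

#' @export
print.surface_trace <- function(x, ...) {
  cat(sprintf("<surface_trace> K = %.3g, gamma = %.2g: %d frames to t = %.0f; final Delta = %.4f, R = %.3f\n",
              x$config$K, x$config$gamma, length(x$time),
              max(x$time), x$delta[length(x$delta)], x$R[length(x$R)]))
  invisible(x)
}
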