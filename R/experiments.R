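#' Classify a Delta(t) trajectory as bounded or growing
#'
#' Implements the trajectory rule for loss of synchrony: over the
#' post-transient half of the series, a run is \emph{growing} if the
#' least-squares slope exceeds \code{slope_tol} and the trajectory rises
#' materially (the final value exceeds \code{growth_factor} times the
#' post-transient median, or the fitted rise across the window exceeds
#' half the median level); it is also growing if the post-transient
#' median exceeds \code{delta_max} (a saturated, fully desynchronized
#' field is stationary but certainly not synchronized), or if the series
#' is non-finite.  Otherwise bounded.
#'
#' @param delta Delta(t) series in rad/2pi.
#' @param time matching time axis.
#' @param transient duration to discard.
#' @param slope_tol slope threshold, rad/2pi per time unit.
#' @param growth_factor final-to-median ratio threshold.
#' @param delta_max saturation guard on the post-transient median.
#' @return list with \code{class} ("bounded"/"growing"), \code{slope},
#'   \code{post_median}, \code{final}.
#' @export
classify_trajectory <- function(delta, time, transient,
                                slope_tol = 2e-5, growth_factor = 2,
                                delta_max = 0.15) {
  stopifnot(length(delta) == length(time))
  post <- time >= transient
  if (sum(post) < 3) stop("series not longer than the transient")
  d <- delta[post]; tt <- time[post]
  if (any(!is.finite(d)))
    return(list(class = "growing", slope = NA_real_,
                post_median = NA_real_, final = NA_real_))
  slope <- unname(coef(lm(d ~ tt))[2])
  med <- median(d)
  fin <- mean(d[tt >= (max(tt) - 0.05 * (max(tt) - min(tt)))])
  rise <- slope * (max(tt) - min(tt))
  growing <- (slope > slope_tol &&
                (fin > growth_factor * med || rise > 0.5 * med)) ||
    med > delta_max
  list(class = if (growing) "growing" else "bounded",
       slope = slope, post_median = med, final = fin)
}

#' Per-cell frequency entrainment of a simulated run
#'
#' Fits each surface pixel's phase against time over the post-transient
#' half and counts cells whose mean frequency deviates from the ensemble
#' median by more than half a cycle of relative drift over the window
#' (tolerance pi / T_post).  A fully synchronized lattice has zero such
#' cells; persistent phase slips show up as drifting cells.
#'
#' @param trace a \code{surface_trace}.
#' @return list with \code{n_slip}, \code{n_cells}, \code{nu_spread}
#'   (max |nu_i - median|), and the per-cell frequencies \code{nu}.
#' @export
frequency_entrainment <- function(trace) {
  cfg <- trace$config
  post <- trace$time >= cfg$transient
  tt <- trace$time[post]
  th <- matrix(trace$surface[, , post],
               nrow = cfg$N1 * cfg$N2, ncol = sum(post))
  ok <- is.finite(th[, 1])
  X <- cbind(1, tt)
  cf <- solve(crossprod(X), crossprod(X, t(th[ok, , drop = FALSE])))
  nu <- cf[2, ]
  tol <- pi / (max(tt) - min(tt))
  dev <- abs(nu - median(nu))
  list(n_slip = sum(dev > tol), n_cells = length(nu),
       nu_spread = max(dev), nu = nu, tol = tol)
}

#' Classify a simulated run as synchronized (bounded) or not (growing)
#'
#' Combines the Delta-trajectory rule of
#' \code{\link{classify_trajectory}} with the frequency-entrainment
#' check: a run is growing if the trajectory rule fires or if more than
#' \code{straggler_max} cells drift in frequency.  A single drifting
#' straggler (typically an extreme-frequency cell with few live bonds,
#' e.g. in a lattice corner) is tolerated because one wrapped pixel
#' cannot move the field statistic.
#'
#' @param trace a \code{surface_trace}.
#' @param straggler_max maximum number of drifting cells still counted
#'   as synchronized (default 1).
#' @param ... passed to \code{\link{classify_trajectory}}.
#' @return list with \code{class}, \code{steady_delta} (post-transient
#'   mean), the trajectory diagnostics and \code{n_slip}.
#' @export
classify_run <- function(trace, straggler_max = 1L, ...) {
  cfg <- trace$config
  tr <- classify_trajectory(trace$delta, trace$time, cfg$transient, ...)
  fe <- frequency_entrainment(trace)
  growing <- tr$class == "growing" || fe$n_slip > straggler_max
  post <- trace$time >= cfg$transient
  list(class = if (growing) "growing" else "bounded",
       steady_delta = mean(trace$delta[post]),
       slope = tr$slope, post_median = tr$post_median, final = tr$final,
       n_slip = fe$n_slip, nu_spread = fe$nu_spread)
}

#' Sweep one model parameter with replicates
#'
#' Runs \code{replicates} seeded simulations at every value of one
#' parameter of a template configuration, classifies each run, and
#' summarizes steady-state Delta per value.  All randomness derives from
#' \code{base_seed}, so sweeps are reproducible bit for bit.
#'
#' @param template a \code{\link{sim_config}} (its \code{seed} is used as
#'   \code{base_seed} unless given).
#' @param param name of the swept field ("K", "sigma_omega", "gamma",
#'   "D", "NL", "pacemaker_boost").
#' @param values grid of parameter values.
#' @param replicates runs per value (default 5).
#' @param base_seed seed from which all run seeds derive.
#' @param ... passed to \code{\link{classify_run}}.
#' @return a \code{param_sweep}: data frame \code{runs} (one row per
#'   run), data frame \code{summary} (per value: mean/sd of steady Delta,
#'   n bounded, majority class), the template and seeds.
#' @export
sweep_param <- function(template, param, values, replicates = 5L,
                        base_seed = NULL, ...) {
  stopifnot(inherits(template, "sim_config"),
            param %in% c("K", "sigma_omega", "gamma", "D", "NL",
                         "pacemaker_boost"))
  base_seed <- base_seed %||% template$seed
  seeds <- matrix(derive_seeds(base_seed, length(values) * replicates),
                  nrow = replicates)
  runs <- vector("list", length(values) * replicates)
  n <- 0L
  for (v in seq_along(values)) {
    for (r in seq_len(replicates)) {
      cfg <- template
      cfg[[param]] <- if (param == "NL") as.integer(values[v]) else values[v]
      cfg$seed <- seeds[r, v]
      tr <- simulate_lattice(cfg)
      cl <- classify_run(tr, ...)
      n <- n + 1L
      runs[[n]] <- data.frame(value = values[v], replicate = r,
                              seed = cfg$seed, class = cl$class,
                              steady_delta = cl$steady_delta,
                              slope = cl$slope, n_slip = cl$n_slip)
    }
  }
  runs <- do.call(rbind, runs)
  summ <- do.call(rbind, lapply(split(runs, runs$value), function(g) {
    data.frame(value = g$value[1],
               delta_mean = mean(g$steady_delta),
               delta_sd = sd(g$steady_delta),
               n_bounded = sum(g$class == "bounded"),
               n = nrow(g),
               majority = if (sum(g$class == "bounded") > nrow(g) / 2)
                 "bounded" else "growing")
  }))
  summ <- summ[order(summ$value), ]
  rownames(summ) <- NULL
  structure(list(param = param, runs = runs, summary = summ,
                 template = template, base_seed = base_seed,
                 replicates = replicates),
            class = "param_sweep")
}

#' @export
print.param_sweep <- function(x, ...) {
  cat(sprintf("<param_sweep> %s over %d values x %d replicates\n",
              x$param, nrow(x$summary), x$replicates))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# Merge two sweeps of the same parameter/template (used by refinement).
merge_sweeps <- function(a, b) {
  stopifnot(a$param == b$param)
  a$runs <- rbind(a$runs, b$runs)
  a$summary <- rbind(a$summary, b$summary)
  a$summary <- a$summary[order(a$summary$value), ]
  rownames(a$summary) <- NULL
  a
}

#' Estimate the critical coupling K_c
#'
#' K_c is the smallest coupling on the grid whose runs are classified
#' bounded in a majority of replicates.  When \code{refine_step} is
#' given, the grid is refined between the last majority-growing and the
#' first majority-bounded value down to that step.
#'
#' @param template a \code{\link{sim_config}}.
#' @param K_grid ascending grid of couplings.
#' @param replicates runs per value.
#' @param refine_step target grid resolution near the transition
#'   (NULL for no refinement).
#' @param base_seed seed for the sweep.
#' @param sweep optionally, a precomputed \code{param_sweep} over K to
#'   reuse instead of simulating the initial grid.
#' @param ... passed to \code{\link{classify_run}}.
#' @return list with \code{Kc} (NA with a \code{bound} note if the grid
#'   is one-sided), the (possibly refined) \code{sweep}, and the
#'   transition bracket.
#' @export
estimate_kc <- function(template, K_grid, replicates = 5L,
                        refine_step = 0.005, base_seed = NULL,
                        sweep = NULL, ...) {
  stopifnot(!is.unsorted(K_grid))
  if (is.null(sweep))
    sweep <- sweep_param(template, "K", K_grid, replicates, base_seed, ...)
  repeat {
    s <- sweep$summary
    bounded <- s$majority == "bounded"
    if (all(bounded)) return(list(Kc = NA_real_, bound = "below",
                                  note = "all grid values bounded",
                                  sweep = sweep))
    if (!any(bounded)) return(list(Kc = NA_real_, bound = "above",
                                   note = "all grid values growing",
                                   sweep = sweep))
    first_b <- min(which(bounded))
    last_g <- if (first_b > 1) first_b - 1L else NA_integer_
    gap <- if (!is.na(last_g)) s$value[first_b] - s$value[last_g] else 0
    if (is.null(refine_step) || is.na(last_g) ||
        gap <= refine_step + 1e-12) break
    new_K <- setdiff(
      round(seq(s$value[last_g], s$value[first_b], by = refine_step), 10),
      round(s$value, 10))
    if (!length(new_K)) break
    extra <- sweep_param(sweep$template, "K", new_K, sweep$replicates,
                         sweep$base_seed + 1L, ...)
    sweep <- merge_sweeps(sweep, extra)
  }
  s <- sweep$summary
  bounded <- s$majority == "bounded"
  first_b <- min(which(bounded))
  list(Kc = s$value[first_b],
       bracket = c(if (first_b > 1) s$value[first_b - 1] else NA, s$value[first_b]),
       sweep = sweep)
}

#' Bracket the biological coupling strength
#'
#' Interpolates, on each of two steady-state Delta(K) curves (typically
#' defect-free and gamma = 0.5), the coupling at which Delta crosses the
#' experimentally measured fluctuation level, giving an interval for the
#' coupling strength of the real tissue.  Interpolation is linear in
#' log K vs log Delta by default (the curves decay roughly geometrically);
#' only majority-bounded grid points enter.
#'
#' @param sweeps list of \code{param_sweep}s over K (one per curve).
#' @param delta_target target fluctuation in rad/2pi (> 0).
#' @param interp "loglog" (default) or "linear".
#' @return list with \code{crossings} (one K per curve, NA with a flag if
#'   the target is outside the curve), \code{interval} (range of the
#'   crossings) and per-curve flags.
#' @export
estimate_coupling_interval <- function(sweeps, delta_target = 0.02,
                                       interp = c("loglog", "linear")) {
  interp <- match.arg(interp)
  stopifnot(delta_target > 0)
  one <- function(sw) {
    s <- sw$summary[sw$summary$majority == "bounded", ]
    s <- s[order(s$value), ]
    if (nrow(s) < 2) return(list(K = NA_real_, flag = "too-few-bounded"))
    d <- s$delta_mean; K <- s$value
    if (all(d > delta_target)) return(list(K = NA_real_, flag = "upper-unbounded"))
    if (all(d < delta_target)) return(list(K = NA_real_, flag = "lower-unbounded"))
    i <- max(which(d > delta_target))   # curves decay in K
    if (interp == "loglog") {
      f <- (log(delta_target) - log(d[i])) / (log(d[i + 1]) - log(d[i]))
      Kx <- exp(log(K[i]) + f * (log(K[i + 1]) - log(K[i])))
    } else {
      f <- (delta_target - d[i]) / (d[i + 1] - d[i])
      Kx <- K[i] + f * (K[i + 1] - K[i])
    }
    list(K = Kx, flag = "ok")
  }
  res <- lapply(sweeps, one)
  ks <- vapply(res, `[[`, 0, "K")
  list(crossings = ks,
       interval = if (all(is.finite(ks))) range(ks) else c(NA_real_, NA_real_),
       flags = vapply(res, `[[`, "", "flag"))
}

#' Delta over a sigma_omega x gamma grid
#'
#' Steady-state Delta (mean over replicates) for every combination of
#' frequency heterogeneity and defect ratio at fixed K and NL, the map
#' of how heterogeneity and defects jointly roughen the wave.
#'
#' @param template a \code{\link{sim_config}} fixing K, NL, D.
#' @param sigma_grid,gamma_grid grids.
#' @param replicates runs per cell.
#' @param base_seed sweep seed.
#' @return data frame with one row per (sigma_omega, gamma): Delta mean,
#'   sd, and the majority classification.
#' @export
sweep_delta_surface <- function(template, sigma_grid, gamma_grid,
                                replicates = 5L, base_seed = NULL) {
  base_seed <- base_seed %||% template$seed
  out <- list(); n <- 0L
  for (g in gamma_grid) {
    tpl <- template; tpl$gamma <- g
    sw <- sweep_param(tpl, "sigma_omega", sigma_grid, replicates,
                      base_seed + n)
    s <- sw$summary
    s$gamma <- g
    n <- n + 1L
    out[[n]] <- s
  }
  res <- do.call(rbind, out)
  names(res)[names(res) == "value"] <- "sigma_omega"
  rownames(res) <- NULL
  res
}

#' Delta as a function of the number of layers
#'
#' @param template a \code{\link{sim_config}}.
#' @param NL_values layer counts (>= 2 values).
#' @param replicates runs per value.
#' @param base_seed sweep seed.
#' @return a \code{param_sweep} over NL.
#' @export
sweep_layers <- function(template, NL_values, replicates = 5L,
                         base_seed = NULL) {
  stopifnot(length(NL_values) >= 2)
  sweep_param(template, "NL", NL_values, replicates, base_seed)
}

#' Critical frequency heterogeneity per coupling strength
#'
#' For each K, sweeps sigma_omega and reports the largest grid value
#' whose runs stay synchronized (majority bounded).
#'
#' @param template a \code{\link{sim_config}} (D and gamma typically 0).
#' @param K_values couplings to test.
#' @param sigma_grid ascending sigma_omega grid.
#' @param replicates runs per cell.
#' @param base_seed sweep seed.
#' @return list with \code{critical} (named by K) and the per-K sweeps.
#' @export
robustness_sigma <- function(template, K_values, sigma_grid,
                             replicates = 5L, base_seed = NULL) {
  stopifnot(!is.unsorted(sigma_grid))
  base_seed <- base_seed %||% template$seed
  sweeps <- list()
  critical <- setNames(rep(NA_real_, length(K_values)), K_values)
  for (i in seq_along(K_values)) {
    tpl <- template; tpl$K <- K_values[i]
    sw <- sweep_param(tpl, "sigma_omega", sigma_grid, replicates,
                      base_seed + i)
    b <- sw$summary$majority == "bounded"
    if (any(b)) critical[i] <- max(sw$summary$value[b])
    sweeps[[as.character(K_values[i])]] <- sw
  }
  list(critical = critical, sweeps = sweeps)
}

#' Critical dynamical noise per coupling strength
#'
#' For each K, sweeps the noise intensity D and reports the largest grid
#' value whose runs stay synchronized (majority bounded).
#'
#' @param template a \code{\link{sim_config}} (sigma_omega per the study
#'   design, gamma = 0).
#' @param K_values couplings to test.
#' @param D_grids a single ascending grid, or a list of grids named by K.
#' @param replicates runs per cell.
#' @param base_seed sweep seed.
#' @return list with \code{critical} (named by K) and the per-K sweeps.
#' @export
robustness_noise <- function(template, K_values, D_grids,
                             replicates = 5L, base_seed = NULL) {
  base_seed <- base_seed %||% template$seed
  if (!is.list(D_grids))
    D_grids <- setNames(rep(list(D_grids), length(K_values)), K_values)
  sweeps <- list()
  critical <- setNames(rep(NA_real_, length(K_values)), K_values)
  for (i in seq_along(K_values)) {
    tpl <- template; tpl$K <- K_values[i]
    grid <- D_grids[[as.character(K_values[i])]] %||% D_grids[[i]]
    sw <- sweep_param(tpl, "D", grid, replicates, base_seed + 100L + i)
    b <- sw$summary$majority == "bounded"
    if (any(b)) critical[i] <- max(sw$summary$value[b])
    sweeps[[as.character(K_values[i])]] <- sw
  }
  list(critical = critical, sweeps = sweeps)
}

#' Delta(K) curves for different pacemaker frequency boosts
#'
#' Compares the steady-state Delta(K) curve (and the mean phase gradient
#' along the wave axis) between pacemaker planes running e.g. 4 percent
#' and 2.7 percent faster than the rest of the tissue.
#'
#' @param template a \code{\link{sim_config}}.
#' @param boosts pacemaker boost factors (> 1 for a wave; 1 = no wave).
#' @param K_values coupling grid.
#' @param replicates runs per cell.
#' @param base_seed sweep seed.
#' @return list with per-boost \code{param_sweep}s over K and a data
#'   frame \code{gradients} of mean surface phase gradients
#'   (cycles/site along x).
#' @export
pacemaker_variant <- function(template, boosts = c(1.04, 1.027),
                              K_values, replicates = 5L, base_seed = NULL) {
  base_seed <- base_seed %||% template$seed
  sweeps <- list(); grads <- list(); n <- 0L
  for (b in boosts) {
    tpl <- template; tpl$pacemaker_boost <- b
    sw <- sweep_param(tpl, "K", K_values, replicates, base_seed + 200L + n)
    sweeps[[as.character(b)]] <- sw
    # mean steady gradient along x on one representative run per K
    g <- vapply(K_values, function(K) {
      cfg <- tpl; cfg$K <- K; cfg$seed <- base_seed + 300L + n
      tr <- simulate_lattice(cfg)
      post <- which(tr$time >= cfg$transient)
      mean(vapply(post, function(k) {
        prof <- apply(tr$surface[, , k], 1, circ_mean)
        mean(wrap_pi(diff(prof))) / (2 * pi)
      }, 0))
    }, 0)
    n <- n + 1L
    grads[[as.character(b)]] <- data.frame(boost = b, K = K_values,
                                           gradient = g)
  }
  list(sweeps = sweeps, gradients = do.call(rbind, grads))
}
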