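test_that("lattice construction counts live oscillators and draws frequencies", {
  st <- build_lattice(sim_config(K = 0.1, seed = 1))
  expect_equal(st$n_live, 20 * 20 * 10)
  # drawn frequency sd close to sigma_omega (pacemaker plane excluded)
  om <- st$omega_array[-1, , ]
  se <- 0.05 / sqrt(2 * (length(om) - 1))
  expect_lt(abs(sd(om) - 0.05), 4 * se)
  # pacemaker plane 4 percent faster on average
  expect_equal(mean(st$omega_array[1, , ]) / mean(om), 1.04, tolerance = 0.01)
})

test_that("a fully defective surface falls back to the layer beneath", {
  cfg <- sim_config(K = 0.1, gamma = 1, NL = 3L, N1 = 6L, N2 = 6L,
                    t_end = 10, transient = 5, seed = 2)
  st <- build_lattice(cfg)
  expect_equal(st$n_live, 6 * 6 * 2)
  st <- step_lattice(st, 50)
  surf <- surface_phase(st)
  # displayed field must equal the z = 2 layer verbatim
  sz <- st$strides["sz"]; sy <- st$strides["sy"]
  below <- matrix(0, 6, 6)
  for (y in 1:6) for (x in 1:6)
    below[x, y] <- st$theta[2 * sz + y * sy + x + 1]
  expect_equal(surf, below, tolerance = 1e-12)
})

test_that("defect pixels display the oscillator directly beneath", {
  cfg <- sim_config(K = 0.1, gamma = 0.3, N1 = 10L, N2 = 10L, NL = 2L,
                    t_end = 10, transient = 5, seed = 3)
  st <- build_lattice(cfg)
  expect_gt(sum(st$defect), 0)
  st <- step_lattice(st, 25)
  surf <- surface_phase(st)
  sz <- st$strides["sz"]; sy <- st$strides["sy"]
  for (y in 1:10) for (x in 1:10) {
    z_expect <- if (st$defect[x, y]) 2L else 1L
    expect_equal(surf[x, y], st$theta[z_expect * sz + y * sy + x + 1])
  }
})

test_that("uncoupled noiseless oscillators drift at their natural frequency", {
  cfg <- sim_config(K = 0, N1 = 6L, N2 = 6L, NL = 2L, sigma_omega = 0.05,
                    t_end = 20, transient = 10, seed = 4)
  tr <- simulate_lattice(cfg, keep = "all")
  st <- build_lattice(cfg)
  om_live <- st$omega[st$live]
  expect_equal(tr$theta_live[, ncol(tr$theta_live)], om_live * 20,
               tolerance = 1e-10)
})

test_that("identical oscillators stay exactly synchronized at any coupling", {
  for (K in c(0.05, 0.3)) {
    cfg <- sim_config(K = K, N1 = 8L, N2 = 8L, NL = 2L, sigma_omega = 0,
                      pacemaker_boost = 1, t_end = 30, transient = 10, seed = 5)
    tr <- simulate_lattice(cfg)
    expect_true(all(abs(tr$delta) < 1e-12))
    expect_true(all(tr$R > 1 - 1e-12))
  }
})

test_that("two coupled oscillators obey the closed-form lock threshold and lag", {
  # d phi / dt = d_omega - 2 K sin(phi): locked iff |d_omega| <= 2K,
  # with stationary lag arcsin(d_omega / (2 K))
  K <- 0.1
  base <- sim_config(K = K, N1 = 2L, N2 = 1L, NL = 1L, t_end = 400,
                     transient = 200, seed = 6)
  om <- function(dw) array(c(1, 1 + dw), dim = c(2, 1, 1))
  locked <- simulate_lattice(base, keep = "all", omega_override = om(0.15))
  th <- locked$theta_live
  post <- locked$time >= 200
  lag <- th[2, post] - th[1, post]
  expect_equal(mean(lag), asin(0.15 / (2 * K)), tolerance = 1e-6)
  expect_lt(diff(range(lag)), 1e-6)
  # just above threshold: persistent drift at the beat frequency
  drift <- simulate_lattice(base, keep = "all", omega_override = om(0.25))
  th2 <- drift$theta_live
  beat <- (th2[2, ncol(th2)] - th2[1, ncol(th2)] -
           (th2[2, sum(post)] - th2[1, sum(post)])) / 200
  expect_gt(abs(beat), 0.01)
  expect_equal(abs(beat), sqrt(0.25^2 - (2 * K)^2), tolerance = 0.05)
})

test_that("global rotation of the initial condition shifts every phase exactly", {
  cfg <- sim_config(K = 0.15, N1 = 8L, N2 = 8L, NL = 2L, t_end = 40,
                    transient = 20, seed = 7)
  a <- simulate_lattice(cfg)
  b <- simulate_lattice(cfg, theta0 = 1.234)
  expect_equal(b$surface, a$surface + 1.234, tolerance = 1e-9)
  expect_equal(b$delta, a$delta, tolerance = 1e-9)
})

test_that("the integrator converges at fourth order in dt", {
  mk <- function(dt) {
    cfg <- sim_config(K = 0.3, N1 = 5L, N2 = 5L, NL = 2L, t_end = 2,
                      transient = 1, dt = dt, obs_interval = 2, seed = 8)
    tr <- simulate_lattice(cfg, keep = "all")
    tr$theta_live[, ncol(tr$theta_live)]
  }
  ref <- mk(0.00125)
  e1 <- max(abs(mk(0.02) - ref))
  e2 <- max(abs(mk(0.01) - ref))
  expect_gt(e1 / e2, 10)      # ~16 for a clean O(dt^4) scheme
  expect_lt(e2, 1e-8)
})

test_that("noise-only phase variance grows like 2 D t under the ito scheme", {
  D <- 0.5
  cfg <- sim_config(K = 0, N1 = 20L, N2 = 20L, NL = 1L, sigma_omega = 0,
                    pacemaker_boost = 1, D = D, noise_scheme = "ito",
                    t_end = 50, transient = 10, seed = 9)
  tr <- simulate_lattice(cfg, keep = "all")
  v <- apply(tr$theta_live, 2, var)
  fit <- lm(v ~ tr$time)
  expect_equal(unname(coef(fit)[2]), 2 * D, tolerance = 0.15)
})

test_that("the forcing scheme injects variance 2 D dt per unit time", {
  D <- 5
  cfg <- sim_config(K = 0, N1 = 20L, N2 = 20L, NL = 1L, sigma_omega = 0,
                    pacemaker_boost = 1, D = D, noise_scheme = "forcing",
                    t_end = 50, transient = 10, seed = 10)
  tr <- simulate_lattice(cfg, keep = "all")
  v <- apply(tr$theta_live, 2, var)
  fit <- lm(v ~ tr$time)
  expect_equal(unname(coef(fit)[2]), 2 * D * cfg$dt, tolerance = 0.15)
})

test_that("simulations are reproducible given the seed", {
  cfg <- tiny_config(0.1, D = 1, seed = 11)
  a <- simulate_lattice(cfg)
  b <- simulate_lattice(cfg)
  expect_identical(a$surface, b$surface)
  expect_identical(a$delta, b$delta)
})

test_that("model_delta matches the metrics machinery with a 3 x 3 window", {
  set.seed(12)
  th <- matrix(rnorm(64, 0, 0.2), 8, 8)
  expect_equal(model_delta(th),
               spatial_fluctuation(spatial_detrend(th, window = 3L))$delta)
})
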