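test_that("trajectory classification separates flat, growing and saturated", {
  tt <- seq(0, 100, by = 1)
  flat <- classify_trajectory(rep(0.01, 101), tt, transient = 50)
  expect_equal(flat$class, "bounded")
  grow <- classify_trajectory(0.001 * tt, tt, transient = 50)
  expect_equal(grow$class, "growing")
  sat <- classify_trajectory(rep(0.2, 101), tt, transient = 50)
  expect_equal(sat$class, "growing")     # saturated field is not synchronized
  bad <- classify_trajectory(c(rep(0.01, 100), NaN), tt, transient = 50)
  expect_equal(bad$class, "growing")
  expect_error(classify_trajectory(rep(1, 5), seq_len(5), transient = 10),
               "transient")
})

test_that("a single frequency straggler is tolerated, a cluster is not", {
  nu <- rep(1, 25)
  expect_equal(classify_run(fake_trace(nu))$class, "bounded")
  nu1 <- nu; nu1[7] <- 1.2
  expect_equal(classify_run(fake_trace(nu1))$class, "bounded")   # 1 cell
  nu3 <- nu; nu3[c(3, 7, 11)] <- 1.2
  r3 <- classify_run(fake_trace(nu3))
  expect_equal(r3$class, "growing")
  expect_equal(r3$n_slip, 3L)
})

test_that("parameter sweeps are reproducible bit for bit given the seed", {
  tpl <- tiny_config(0.1)
  a <- sweep_param(tpl, "K", c(0.05, 0.2), replicates = 2, base_seed = 42)
  b <- sweep_param(tpl, "K", c(0.05, 0.2), replicates = 2, base_seed = 42)
  expect_identical(a$runs, b$runs)
  expect_identical(a$summary, b$summary)
  # different seed, different draws
  c2 <- sweep_param(tpl, "K", c(0.05, 0.2), replicates = 2, base_seed = 43)
  expect_false(identical(a$runs$steady_delta, c2$runs$steady_delta))
})

test_that("K_c estimation brackets the pacemaker flux threshold on a small lattice", {
  # a thin slab driven by a 4 percent faster plane locks once the first
  # bond can carry the pacemaker's excess frequency (~0.04 here)
  tpl <- sim_config(K = 0.05, N1 = 12L, N2 = 3L, NL = 2L, sigma_omega = 0.02,
                    t_end = 300, transient = 150, seed = 13)
  est <- estimate_kc(tpl, K_grid = c(0.01, 0.02, 0.04, 0.08, 0.16),
                     replicates = 3, refine_step = NULL, base_seed = 99)
  expect_true(is.finite(est$Kc))
  expect_gte(est$Kc, 0.02)
  expect_lte(est$Kc, 0.16)
  s <- est$sweep$summary
  expect_equal(s$majority[s$value == 0.01], "growing")
  expect_equal(s$majority[s$value == 0.16], "bounded")
})

test_that("one-sided grids report a bound instead of a critical value", {
  tpl <- sim_config(K = 0.3, N1 = 6L, N2 = 6L, NL = 2L, sigma_omega = 0,
                    pacemaker_boost = 1, t_end = 40, transient = 20, seed = 14)
  est <- estimate_kc(tpl, K_grid = c(0.1, 0.3), replicates = 2,
                     refine_step = NULL, base_seed = 7)
  expect_true(is.na(est$Kc))
  expect_equal(est$bound, "below")
})

test_that("coupling-interval interpolation matches the closed form", {
  # fabricate two sweeps with exactly geometric Delta(K) = a / K
  mk <- function(a) {
    K <- c(0.05, 0.1, 0.2, 0.4)
    structure(list(summary = data.frame(value = K, delta_mean = a / K,
                                        delta_sd = 0, n_bounded = 5, n = 5,
                                        majority = "bounded")),
              class = "param_sweep")
  }
  res <- estimate_coupling_interval(list(mk(0.004), mk(0.008)),
                                    delta_target = 0.02, interp = "loglog")
  # log-log interpolation is exact for a power law: crossing at a / 0.02
  expect_equal(unname(res$crossings), c(0.2, 0.4), tolerance = 1e-9)
  expect_equal(res$interval, c(0.2, 0.4), tolerance = 1e-9)
  # a target below the whole curve flags the unbounded side
  res2 <- estimate_coupling_interval(list(mk(0.004)), delta_target = 0.005)
  expect_equal(unname(res2$flags), "upper-unbounded")
  res3 <- estimate_coupling_interval(list(mk(0.004)), delta_target = 0.2)
  expect_equal(unname(res3$flags), "lower-unbounded")
})

test_that("robustness sweeps report the largest bounded grid value", {
  # sigma_omega = 0 with no pacemaker is bounded for any K; large sigma at
  # tiny K is not.  Use a small lattice for speed.
  tpl <- sim_config(K = 0.3, N1 = 8L, N2 = 8L, NL = 2L, t_end = 120,
                    transient = 60, seed = 15)
  rs <- robustness_sigma(tpl, K_values = 0.3, sigma_grid = c(0.02, 0.6),
                         replicates = 3)
  expect_equal(unname(rs$critical["0.3"]), 0.02)
  sw <- rs$sweeps[["0.3"]]$summary
  expect_equal(sw$majority, c("bounded", "growing"))
})

test_that("pacemaker boost steepens the steady surface gradient", {
  tpl <- sim_config(K = 0.12, N1 = 12L, N2 = 6L, NL = 2L, sigma_omega = 0.02,
                    t_end = 200, transient = 100, seed = 16)
  pv <- pacemaker_variant(tpl, boosts = c(1.027, 1.04), K_values = 0.12,
                          replicates = 2, base_seed = 5)
  g <- pv$gradients
  expect_equal(nrow(g), 2)
  expect_gt(abs(g$gradient[g$boost == 1.04]),
            abs(g$gradient[g$boost == 1.027]))
  # boost = 1: no wave, flat steady gradient
  pv1 <- pacemaker_variant(tpl, boosts = 1, K_values = 0.12,
                           replicates = 2, base_seed = 6)
  expect_lt(abs(pv1$gradients$gradient), abs(g$gradient[g$boost == 1.027]))
})
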