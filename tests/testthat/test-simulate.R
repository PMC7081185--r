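test_that("zero field gives unit signal for both echo types", {
  n <- 24
  fm <- list(delta_omega = array(0, c(n, n, n)), voxel_size = 1,
             grid_dims = c(n, n, n), periodic = TRUE)
  sim <- sim_config(grid_dims = c(n, n, n), n_walkers = 500, n_reps = 1)
  expect_equal(simulate_echo(fm, NULL, sim, "spin_echo", 8, seed = 1), 1)
  expect_equal(simulate_echo(fm, NULL, sim, "gradient_echo", 3, seed = 1), 1)
})

test_that("a spatially uniform field is refocused or a pure global phase", {
  n <- 24
  fm <- list(delta_omega = array(250, c(n, n, n)), voxel_size = 1,
             grid_dims = c(n, n, n), periodic = TRUE)
  sim <- sim_config(grid_dims = c(n, n, n), n_walkers = 500, n_reps = 1)
  expect_equal(simulate_echo(fm, NULL, sim, "spin_echo", 8, seed = 1), 1,
               tolerance = 1e-12)
  expect_equal(simulate_echo(fm, NULL, sim, "gradient_echo", 4, seed = 1), 1,
               tolerance = 1e-12)
})

test_that("rates follow -ln(S)/TE with input validation", {
  rt <- rates_from_signals(0.8521, 0.9, 8, 3)
  expect_equal(rt$delta_r2, 20.00642, tolerance = 1e-6)
  expect_equal(rt$delta_r2_star, 35.12017, tolerance = 1e-6)
  expect_equal(rates_from_signals(1, 1, 8, 3)$delta_r2, 0)
  expect_error(rates_from_signals(0, 0.9, 8, 3), "positive")
  expect_error(rates_from_signals(-0.1, 0.9, 8, 3), "positive")
  expect_error(rates_from_signals(0.9, 1.2, 8, 3), "exceed")
})

test_that("echo simulation is reproducible and validates timing", {
  sub <- generate_cylinder_substrate(c(48, 48, 48), 1, 3, 0.04, seed = 5)
  fm <- compute_field_shift(sub)
  sim <- sim_config(grid_dims = c(48, 48, 48), n_walkers = 2000, n_reps = 1)
  s1 <- simulate_echo(fm, sub, sim, "spin_echo", 8, seed = 9)
  s2 <- simulate_echo(fm, sub, sim, "spin_echo", 8, seed = 9)
  expect_identical(s1, s2)
  expect_error(simulate_echo(fm, sub, sim, "spin_echo", 8.5, seed = 1),
               "multiple")
  expect_error(simulate_echo(fm, sub, sim, "spin_echo", 3, seed = 1),
               "te/2")
})

test_that("spin echo refocuses more signal than gradient echo", {
  # same substrate, same TE: dephasing unrecovered by the 180 pulse is
  # smaller, so S_se >= S_gre up to Monte Carlo noise
  sub <- generate_cylinder_substrate(c(48, 48, 48), 1, 4, 0.04, seed = 21)
  fm <- compute_field_shift(sub)
  sim <- sim_config(grid_dims = c(48, 48, 48), n_walkers = 20000, n_reps = 1)
  s_se <- simulate_echo(fm, sub, sim, "spin_echo", 8, seed = 31)
  s_gre <- simulate_echo(fm, sub, sim, "gradient_echo", 8, seed = 32)
  expect_gt(s_se, s_gre - 0.02)
})

test_that("lattice stepping realizes the same diffusivity as sphere stepping", {
  sub <- generate_cylinder_substrate(c(48, 48, 48), 1, 3, 0.04, seed = 13)
  fm <- compute_field_shift(sub)
  rate_of <- function(mode) {
    sim <- sim_config(grid_dims = c(48, 48, 48), n_walkers = 30000,
                      n_reps = 1, step_mode = mode)
    s <- simulate_echo(fm, sub, sim, "spin_echo", 8, seed = 77)
    -log(s) / 0.008
  }
  r_sphere <- rate_of("sphere")
  r_lattice <- rate_of("lattice")
  expect_equal(r_lattice, r_sphere, tolerance = 0.25)
})

test_that("static gradient-echo decay approaches the dilute closed form", {
  # D -> 0; ensemble signal over repetitions in the asymptotic window
  ph <- physics_config()
  sim <- sim_config(grid_dims = rep(96L, 3), voxel_size = 2,
                    n_walkers = 10000, d_water = 0, te_gre = 6, n_reps = 1)
  S <- numeric(0)
  for (rep in 1:6) {
    sub <- generate_cylinder_substrate(sim$grid_dims, 2, 10, 0.02,
                                       seed = 50 + rep)
    fm <- compute_field_shift(sub, ph)
    S <- c(S, simulate_echo(fm, sub, sim, "gradient_echo", 6,
                            seed = 60 + rep))
  }
  rate <- -log(mean(S)) / 0.006
  expect_equal(rate, static_dephasing_rate(0.02, ph), tolerance = 0.3)
})
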