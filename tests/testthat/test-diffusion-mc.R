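test_that("Stokes-Einstein helpers obey their scaling laws and formulas", {
  # equivalent-sphere radius: cube-root law and direct evaluation
  expect_equal(molecule_radius(80) / molecule_radius(10), 2, tolerance = 1e-12)
  for (pair in list(c(5, 40), c(10, 100), c(7, 3))) {
    expect_equal(molecule_radius(pair[1]) / molecule_radius(pair[2]),
                 (pair[1] / pair[2])^(1 / 3), tolerance = 1e-12)
  }
  N <- 6.02214076e23
  expect_equal(molecule_radius(10, eta = 1e-3, N = N),
               (3 * 1e-3 * 10 / (10 * pi * N))^(1 / 3), tolerance = 1e-14)

  # diffusion coefficient: D = kB T / (6 pi eta R)
  expect_equal(diffusion_coefficient(310, 1e-3, 2e-9) /
                 diffusion_coefficient(310, 1e-3, 1e-9), 0.5, tolerance = 1e-12)
  expect_equal(diffusion_coefficient(620, 1e-3, 1e-9) /
                 diffusion_coefficient(310, 1e-3, 1e-9), 2, tolerance = 1e-12)
  expect_equal(diffusion_coefficient(310, 1e-3, 1e-9),
               1.380649e-23 * 310 / (6 * pi * 1e-3 * 1e-9), tolerance = 1e-14)

  # step scale: inverse cube root of molecular weight
  expect_identical(step_scale(10, 10, 0.7), 0.7)
  expect_equal(step_scale(5, 10, 1) / step_scale(40, 10, 1), 2, tolerance = 1e-12)
  expect_equal(step_scale(10, 10, 1) / step_scale(100, 10, 1), 10^(1 / 3),
               tolerance = 1e-12)
  expect_error(molecule_radius(-1), "positive")
  expect_error(diffusion_coefficient(0, 1e-3, 1e-9), "positive")
  expect_error(step_scale(10, 10, 0), "positive")
})

test_that("geometry constructors validate their invariants", {
  expect_equal(sqrt(sum(pore_spec(c(1, 1, 1))$direction^2)), 1, tolerance = 1e-12)
  expect_error(pore_spec(c(0, 0, 0)), "non-zero")
  expect_error(pore_spec(angular_radius = 2), "pi/2")
  expect_error(cell_model(cell_radius = 2, domain_radius = 1), "exceed")
  expect_error(cell_model(pores = list(pore_spec(c(0, 0, 1), 0.3),
                                       pore_spec(c(0, 0.1, 1), 0.3))),
               "overlap")
})

test_that("degenerate simulations return exactly zero loading", {
  cell <- cell_model()
  mol <- molecule_spec(10, 10, 1)
  sim <- sim_params(n_particles = 50, n_replicates = 2, seed = 1)
  expect_identical(simulate_loading(cell, mol, sim, open_time = 0)$loading_efficiency, 0)
  open_cell <- cell_model(pores = list())
  expect_identical(simulate_loading(open_cell, mol, sim, open_time = 10)$loading_efficiency, 0)
  expect_warning(simulate_loading(cell, mol, sim_params(50, dt = 5, seed = 1),
                                  open_time = 1),
                 "shorter than one time step")
})

test_that("the walk is seeded-deterministic and conserves particles", {
  cell <- cell_model()
  mol <- molecule_spec(10, 10, 1.9)
  sim <- sim_params(n_particles = 400, n_replicates = 3, seed = 13)
  a <- simulate_loading(cell, mol, sim, open_time = 10)
  b <- simulate_loading(cell, mol, sim, open_time = 10)
  expect_identical(a$delivered_count, b$delivered_count)
  expect_identical(a$per_replicate, b$per_replicate)
  expect_gte(a$loading_efficiency, 0)
  expect_lte(a$loading_efficiency, 1)
  # conservation at the kernel level
  res <- optopore:::mc_walk(200, 5000, 0.05, 1, 5,
                            matrix(c(0, 0, 1), 1), 0.2,
                            FALSE, FALSE, FALSE, TRUE, 99)
  expect_identical(res$delivered + res$remaining, res$n)
})

test_that("a fully absorbing sphere captures essentially all walkers", {
  cell <- cell_model()
  mol <- molecule_spec(10, 10, 0.1)          # per-axis sd 0.1 at dt = 1
  sim <- sim_params(n_particles = 1000, n_replicates = 2, dt = 1, seed = 17)
  res <- simulate_loading(cell, mol, sim, open_time = 50000, absorb_all = TRUE)
  expect_gte(res$loading_efficiency, 0.99)
  # independent dense-step endpoint-testing oracle on 100 particles at the
  # same diffusion time (sd^2 * steps matched)
  oracle <- brute_force_absorbing(100, 100000, sd_axis = 0.1 / sqrt(2),
                                  seed = 31)
  expect_gte(oracle, 0.99)
})

test_that("leap-accelerated and plain stepping agree statistically", {
  cell <- cell_model()
  mol <- molecule_spec(10, 10, 1.9)
  base <- function(leap, seed) {
    sim <- sim_params(n_particles = 800, n_replicates = 4, seed = seed,
                      leap = leap)
    simulate_loading(cell, mol, sim, open_time = 25)
  }
  with_leap <- base(TRUE, 5)
  without <- base(FALSE, 5)
  # replicate means differ only by Monte Carlo error (~3 sem)
  pooled_sem <- sqrt(with_leap$sem_over_replicates^2 + without$sem_over_replicates^2)
  expect_lt(abs(with_leap$loading_efficiency - without$loading_efficiency),
            4 * pooled_sem + 0.01)
})

test_that("loading is invariant under rotation of the pore configuration", {
  mol <- molecule_spec(10, 10, 1.9)
  sim <- sim_params(n_particles = 1200, n_replicates = 5, seed = 23)
  up <- cell_model(pores = list(pore_spec(c(0, 0, 1), 0.2)))
  tilted <- cell_model(pores = list(pore_spec(c(1, 1, -0.5), 0.2)))
  a <- simulate_loading(up, mol, sim, open_time = 30)
  b <- simulate_loading(tilted, mol, sim, open_time = 30)
  pooled <- sqrt(a$sem_over_replicates^2 + b$sem_over_replicates^2)
  expect_lt(abs(a$loading_efficiency - b$loading_efficiency), 4 * pooled + 0.01)
})

test_that("adding a second disjoint pore does not decrease loading", {
  mol <- molecule_spec(10, 10, 1.9)
  sim <- sim_params(n_particles = 1200, n_replicates = 5, seed = 29)
  one <- cell_model(pores = list(pore_spec(c(0, 0, 1), 0.2)))
  two <- cell_model(pores = list(pore_spec(c(0, 0, 1), 0.2),
                                 pore_spec(c(0, 0, -1), 0.2)))
  a <- simulate_loading(one, mol, sim, open_time = 30)
  b <- simulate_loading(two, mol, sim, open_time = 30)
  expect_gte(b$loading_efficiency,
             a$loading_efficiency - 3 * a$sem_over_replicates)
})

test_that("free-walk mean squared displacement scales as M^(-2/3)", {
  mws <- c(5, 10, 20, 40, 70, 100)
  set.seed(41)
  msd <- vapply(mws, function(m) {
    s <- step_scale(m, 10, 1)
    steps <- matrix(rnorm(3 * 10000, sd = s * sqrt(1)), ncol = 3)
    mean(rowSums(steps^2))
  }, 0)
  slope <- unname(coef(lm(log(msd) ~ log(mws)))[2])
  expect_lt(abs(slope - (-2 / 3)), 0.05)
})

test_that("capture grows linearly at early times before depletion", {
  cell <- cell_model()
  mol <- molecule_spec(10, 10, 1.9)
  sim <- sim_params(n_particles = 2000, n_replicates = 20, seed = 37)
  times <- c(2, 4, 6, 8)                 # first ~10% of an 88.7 s open time
  curve <- loading_vs_time(times, mol, cell, sim)
  fit <- lm(loading_mean ~ open_time_s, data = curve)
  expect_gte(summary(fit)$r.squared, 0.95)
})

test_that("single-point grids match simulate_loading exactly", {
  cell <- cell_model()
  mol <- molecule_spec(10, 10, 1.5)
  sim <- sim_params(n_particles = 500, n_replicates = 3, seed = 19)
  grid <- loading_vs_time(15, mol, cell, sim)
  direct <- simulate_loading(cell, mol, sim, open_time = 15)
  expect_identical(grid$loading_mean, direct$loading_efficiency)
  gm <- loading_vs_mw(40, 15, cell, sim, M_ref = 10, s_ref = 1.5)
  direct_m <- simulate_loading(cell, molecule_spec(40, 10, 1.5), sim, 15)
  expect_identical(gm$loading_mean, direct_m$loading_efficiency)
  # a time grid beginning at zero starts exactly at zero loading
  z <- loading_vs_time(c(0, 15), mol, cell, sim)
  expect_identical(z$loading_mean[1], 0)
})

test_that("step-scale calibration hits its anchor reproducibly and monotonically", {
  cell <- cell_model()
  sim <- sim_params(n_particles = 800, n_replicates = 3, seed = 43)
  s1 <- calibrate_step(10, 30, 0.12, cell, sim, tol = 0.01, bracket = c(0.3, 5))
  s2 <- calibrate_step(10, 30, 0.12, cell, sim, tol = 0.01, bracket = c(0.3, 5))
  expect_identical(s1, s2)
  achieved <- simulate_loading(cell, molecule_spec(10, 10, s1), sim, 30)
  expect_lt(abs(achieved$loading_efficiency - 0.12), 0.01 + 1e-12)
  # loading increases with the step scale at fixed geometry and time
  loadings <- vapply(c(0.8, 1.6, 3.2), function(s) {
    simulate_loading(cell, molecule_spec(10, 10, s),
                     sim_params(n_particles = 1000, n_replicates = 10, seed = 47),
                     open_time = 20)$loading_efficiency
  }, 0)
  expect_true(all(diff(loadings) > 0))
  # unattainable anchors report the achieved bracket
  expect_error(calibrate_step(10, 5, 0.9, cell, sim, bracket = c(0.2, 1)),
               "unattainable")
})

test_that("fixed-length and shrinking-pore variants run and stay bounded", {
  cell <- cell_model()
  mol <- molecule_spec(10, 10, 1.9)
  simf <- sim_params(n_particles = 400, n_replicates = 2, seed = 53,
                     step_model = "fixed")
  rf <- simulate_loading(cell, mol, simf, open_time = 10)
  expect_gte(rf$loading_efficiency, 0)
  expect_lte(rf$loading_efficiency, 1)
  sims <- sim_params(n_particles = 800, n_replicates = 3, seed = 53,
                     shrink_pores = TRUE)
  simc <- sim_params(n_particles = 800, n_replicates = 3, seed = 53)
  rs <- simulate_loading(cell, mol, sims, open_time = 20)
  rc <- simulate_loading(cell, mol, simc, open_time = 20)
  # a shrinking pore can only reduce the absorbing area
  expect_lte(rs$loading_efficiency, rc$loading_efficiency + 0.01)
})
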