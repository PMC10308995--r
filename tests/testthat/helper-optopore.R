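# Shared fixtures and independent oracles for the test suite.

# Closed-form noiseless trace: mirrors the documented construction so tests
# can check generated traces against an explicit formula.
expected_trace <- function(resting, slope, n_bg, n_post, dt, dip, t_reseal) {
  n <- n_bg + n_post
  frames <- seq_len(n) - 1L
  baseline <- resting + slope * frames
  g <- rep(1, n)
  tau <- t_reseal / log((1 - dip) / 0.1)
  t_post <- (frames[(n_bg + 1L):n] - n_bg) * dt
  g[(n_bg + 1L):n] <- 1 - (1 - dip) * exp(-t_post / tau)
  baseline * g
}

# Brute-force Brownian walker, independent of the package kernel: plain R,
# endpoint-only absorption at dense steps, radial fold at the outer
# boundary. Valid for the fully absorbing sphere, where endpoint testing at
# small step size is adequate.
brute_force_absorbing <- function(n_particles, n_steps, sd_axis,
                                  cell_radius = 1, domain_radius = 5,
                                  seed = 1) {
  set.seed(seed)
  shell <- domain_radius^3 - cell_radius^3
  r <- (runif(n_particles) * shell + cell_radius^3)^(1 / 3)
  dir <- matrix(rnorm(3 * n_particles), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  pos <- dir * r
  alive <- rep(TRUE, n_particles)
  for (s in seq_len(n_steps)) {
    idx <- which(alive)
    if (!length(idx)) break
    pos[idx, ] <- pos[idx, ] + matrix(rnorm(3 * length(idx), sd = sd_axis),
                                      ncol = 3)
    rr <- sqrt(rowSums(pos[idx, , drop = FALSE]^2))
    out <- rr > domain_radius
    if (any(out)) {
      f <- (2 * domain_radius - rr[out]) / rr[out]
      pos[idx[out], ] <- pos[idx[out], ] * f
      rr[out] <- abs(2 * domain_radius - rr[out])
    }
    alive[idx[rr < cell_radius]] <- FALSE
  }
  sum(!alive) / n_particles
}

# Coarse independent grid search over (a, b, c) for the exponential forms;
# the fitted SS must never exceed this oracle's SS.
grid_search_ss <- function(x, y, form, n_grid = 15) {
  sgn <- if (form == "growth") 1 else -1
  yr <- range(y); xr <- diff(range(x))
  a_grid <- seq(-2 * diff(yr) - 1, 2 * diff(yr) + 1, length.out = n_grid)
  b_grid <- exp(seq(log(0.1 * xr), log(10 * xr), length.out = n_grid))
  if (form == "growth") b_grid <- c(b_grid, -b_grid)
  c_grid <- seq(yr[1] - diff(yr) - 1, yr[2] + diff(yr) + 1, length.out = n_grid)
  best <- Inf
  for (a in a_grid) for (b in b_grid) for (cc in c_grid) {
    ss <- sum((y - (a * exp(sgn * x / b) + cc))^2)
    if (ss < best) best <- ss
  }
  best
}

# Small noiseless experiment used by several recovery tests.
noiseless_design <- function(cells = 10L, seed = 1L) {
  experiment_design(cells_per_condition = cells, unperforated_per_condition = 0L,
                    jitter_sd = 0,
                    trace = trace_spec(noise_sd = 0), seed = seed)
}
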