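#' Stokes-Einstein helpers: molecule radius, diffusion coefficient, step scale
#'
#' `molecule_radius` evaluates the equivalent-sphere radius
#' `R = (3 eta M / (10 pi N))^(1/3)` from the Einstein viscosity relation;
#' `diffusion_coefficient` is the Stokes-Einstein relation
#' `D = kB T / (6 pi eta R)`; `step_scale` is the simulation-unit consequence
#' of the two: the Brownian step scale varies as the inverse cube root of
#' molecular weight, `s(M) = s_ref * (M_ref / M)^(1/3)`.
#'
#' @param M Molecular weight in kDa (numerically equal to kg/mol).
#' @param eta Fluid viscosity in Pa s.
#' @param N Avogadro's number (1/mol).
#' @return `molecule_radius`: radius in metres (for SI inputs).
#' @export
molecule_radius <- function(M, eta = 1e-3, N = .N_A) {
  stop_if_not_positive(M = M, eta = eta, N = N)
  (3 * eta * M / (10 * pi * N))^(1 / 3)
}

#' @rdname molecule_radius
#' @param Temp Temperature in kelvin.
#' @param R Particle radius (m).
#' @param kB Boltzmann constant (J/K).
#' @return `diffusion_coefficient`: D in m^2/s (for SI inputs).
#' @export
diffusion_coefficient <- function(Temp, eta, R, kB = .kB) {
  stop_if_not_positive(Temp = Temp, eta = eta, R = R, kB = kB)
  kB * Temp / (6 * pi * eta * R)
}

#' @rdname molecule_radius
#' @param M_ref Reference molecular weight (kDa).
#' @param s_ref Step scale of the reference molecule, in cell-radius units
#'   per square-root second.
#' @return `step_scale`: step scale of molecule `M` in the same units.
#' @export
step_scale <- function(M, M_ref, s_ref) {
  stop_if_not_positive(M = M, M_ref = M_ref, s_ref = s_ref)
  s_ref * (M_ref / M)^(1 / 3)
}

#' Spherical-cap pore on the model cell
#'
#' @param direction Length-3 vector pointing at the cap centre; normalised
#'   internally (must be non-zero).
#' @param angular_radius Cap half-angle in radians, in (0, pi/2).
#' @return Object of class `pore_spec`.
#' @export
pore_spec <- function(direction = c(0, 0, 1), angular_radius = 0.2) {
  stopifnot(length(direction) == 3, all(is.finite(direction)))
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("pore direction must be a non-zero vector")
  if (!is.finite(angular_radius) || angular_radius <= 0 || angular_radius >= pi / 2)
    stop("angular_radius must lie in (0, pi/2)")
  structure(list(direction = direction / nrm, angular_radius = angular_radius),
            class = "pore_spec")
}

#' Spherical cell with absorbing surface pores inside a reflecting domain
#'
#' The simulation runs in nondimensional units with `cell_radius = 1` by
#' default; the outer sphere reflects walkers back (keeping the tracer
#' concentration finite), and each pore is a spherical cap through which
#' walkers are absorbed while the pore is open.
#'
#' @param cell_radius Cell radius (simulation length unit; default 1).
#' @param domain_radius Outer reflecting boundary radius (default 5x cell).
#' @param pores List of [pore_spec()] objects; caps must be pairwise
#'   disjoint. An empty list means no pores (loading is identically zero).
#' @return Object of class `cell_model`.
#' @export
cell_model <- function(cell_radius = 1, domain_radius = 5 * cell_radius,
                       pores = list(pore_spec())) {
  stop_if_not_positive(cell_radius = cell_radius, domain_radius = domain_radius)
  if (domain_radius <= cell_radius) stop("domain_radius must exceed cell_radius")
  for (p in pores) stopifnot(inherits(p, "pore_spec"))
  if (length(pores) > 1) {
    for (i in seq_len(length(pores) - 1)) for (j in seq(i + 1, length(pores))) {
      ang <- acos(max(-1, min(1, sum(pores[[i]]$direction * pores[[j]]$direction))))
      if (ang <= pores[[i]]$angular_radius + pores[[j]]$angular_radius)
        stop(sprintf("pore caps %d and %d overlap", i, j))
    }
  }
  structure(list(cell_radius = cell_radius, domain_radius = domain_radius,
                 pores = pores),
            class = "cell_model")
}

#' Tracer molecule for the Monte Carlo walk
#'
#' @param mol_weight Molecular weight in kDa.
#' @param M_ref Reference molecular weight the step scale is anchored at
#'   (default 10 kDa, the tracer used for the time-course calibration).
#' @param s_ref Step scale of the reference molecule (cell radii per sqrt
#'   second); obtained from [calibrate_step()].
#' @return Object of class `molecule_spec`.
#' @export
molecule_spec <- function(mol_weight, M_ref = 10, s_ref = 1) {
  stop_if_not_positive(mol_weight = mol_weight, M_ref = M_ref, s_ref = s_ref)
  structure(list(mol_weight = mol_weight, M_ref = M_ref, s_ref = s_ref,
                 step = step_scale(mol_weight, M_ref, s_ref)),
            class = "molecule_spec")
}

#' Monte Carlo simulation parameters
#'
#' When `dt` is `NULL` it is chosen per molecule so that the per-axis step
#' sd does not exceed one tenth of the smallest pore-cap chord, which keeps
#' the cap boundary well resolved by single steps.
#'
#' @param n_particles Walkers per replicate (default 5000).
#' @param dt Time step in seconds, or `NULL` for the automatic rule.
#' @param n_replicates Independent replicates averaged (default 10).
#' @param seed Base seed; replicate `r` uses a sub-seed derived from it that
#'   is shared across grid points (common random numbers).
#' @param step_model `"gaussian"` (isotropic Gaussian displacement, the
#'   default, which converges to Brownian motion at any dt) or `"fixed"`
#'   (fixed-length isotropic steps of matching mean-squared displacement).
#' @param shrink_pores If `TRUE`, cap half-angles decay linearly to zero
#'   over the open time instead of closing instantaneously.
#' @param leap If `TRUE` (default), merge steps far from the membrane into
#'   single Gaussian draws of matching variance (exact in distribution for
#'   free diffusion; large constant-factor speedup).
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(n_particles = 5000L, dt = NULL, n_replicates = 10L,
                       seed = 1L, step_model = c("gaussian", "fixed"),
                       shrink_pores = FALSE, leap = TRUE) {
  step_model <- match.arg(step_model)
  stopifnot(n_particles >= 1, n_replicates >= 1)
  if (!is.null(dt)) stop_if_not_positive(dt = dt)
  structure(list(n_particles = as.integer(n_particles), dt = dt,
                 n_replicates = as.integer(n_replicates), seed = seed,
                 step_model = step_model, shrink_pores = isTRUE(shrink_pores),
                 leap = isTRUE(leap)),
            class = "sim_params")
}

# Automatic dt: per-axis sd = step * sqrt(dt) <= 0.1 * smallest cap chord.
auto_dt <- function(cell, step, absorb_all = FALSE) {
  chord <- if (absorb_all || length(cell$pores) == 0) {
    2 * cell$cell_radius
  } else {
    2 * cell$cell_radius * sin(min(vapply(cell$pores, `[[`, 0, "angular_radius")))
  }
  (0.1 * chord / step)^2
}

#' Simulate macromolecule loading through transient membrane pores
#'
#' Point tracers start uniformly at random in the shell between the cell
#' surface and the outer reflecting boundary, random-walk with per-axis
#' Gaussian step sd `step_scale(M) * sqrt(dt)`, are absorbed when a step
#' crosses the cell sphere inside an open pore cap (segment-sphere
#' intersection, never endpoint testing), reflect off the membrane
#' elsewhere and off the outer boundary, and the run ends when the pores
#' close at `open_time`. Loading efficiency is the delivered fraction,
#' averaged over replicates with distinct sub-seeds.
#'
#' @param cell A [cell_model()].
#' @param mol A [molecule_spec()].
#' @param sim A [sim_params()].
#' @param open_time Pore lifetime in seconds (the resealing time).
#' @param absorb_all If `TRUE` the entire sphere absorbs (validation mode).
#' @return Object of class `loading_result`: `loading_efficiency`,
#'   `delivered_count`, `total_count`, `sem_over_replicates`,
#'   `per_replicate`, plus the `dt` and step count used.
#' @export
simulate_loading <- function(cell, mol, sim, open_time, absorb_all = FALSE) {
  stopifnot(inherits(cell, "cell_model"), inherits(mol, "molecule_spec"),
            inherits(sim, "sim_params"), open_time >= 0)
  dt <- if (is.null(sim$dt)) auto_dt(cell, mol$step, absorb_all) else sim$dt
  n_steps <- floor(open_time / dt + 1e-9)
  if (open_time > 0 && n_steps == 0)
    warning("open_time shorter than one time step; no diffusion steps taken")
  no_pores <- !absorb_all && length(cell$pores) == 0
  per_rep <- numeric(sim$n_replicates)
  delivered_total <- 0
  if (n_steps > 0 && !no_pores) {
    pd <- if (length(cell$pores)) {
      do.call(rbind, lapply(cell$pores, `[[`, "direction"))
    } else matrix(0, 0, 3)
    ph <- vapply(cell$pores, `[[`, 0, "angular_radius")
    sd_step <- mol$step * sqrt(dt)
    for (r in seq_len(sim$n_replicates)) {
      rep_seed <- derive_seed(sim$seed, "mc_replicate", r)
      res <- mc_walk(sim$n_particles, n_steps, sd_step,
                     cell$cell_radius, cell$domain_radius,
                     pd, ph, absorb_all, sim$step_model == "fixed",
                     sim$shrink_pores, sim$leap, rep_seed)
      stopifnot(res$delivered + res$remaining == res$n)   # conservation
      per_rep[r] <- res$delivered / res$n
      delivered_total <- delivered_total + res$delivered
    }
  }
  eff <- mean(per_rep)
  sem <- if (sim$n_replicates > 1) sd(per_rep) / sqrt(sim$n_replicates) else NA_real_
  structure(list(loading_efficiency = eff, delivered_count = delivered_total,
                 total_count = sim$n_particles * sim$n_replicates,
                 sem_over_replicates = sem, per_replicate = per_rep,
                 dt = dt, n_steps = n_steps, open_time = open_time),
            class = "loading_result")
}

#' Calibrate the reference step scale against an experimental anchor
#'
#' Monotone bisection on `s_ref` until the simulated loading at
#' (`anchor_mw`, `anchor_time`) matches `anchor_loading` within `tol`
#' (absolute, on the replicate mean). The same sub-seeds are reused at
#' every bisection step, so the target function is deterministic and the
#' calibration is reproducible.
#'
#' @param anchor_mw Molecular weight of the anchor condition (kDa).
#' @param anchor_time Pore-open time of the anchor condition (s).
#' @param anchor_loading Measured loading fraction in (0, 1) to match.
#' @param cell A [cell_model()].
#' @param sim A [sim_params()] used for every bisection evaluation.
#' @param M_ref Reference molecular weight `s_ref` is defined at.
#' @param tol Absolute tolerance on the matched loading (default 0.01).
#' @param bracket Initial `c(lo, hi)` bracket for `s_ref`.
#' @param max_iter Bisection iteration cap.
#' @return The calibrated `s_ref` (cell radii per sqrt second).
#' @export
calibrate_step <- function(anchor_mw, anchor_time, anchor_loading, cell, sim,
                           M_ref = anchor_mw, tol = 0.01,
                           bracket = c(0.05, 6), max_iter = 40L) {
  stopifnot(anchor_loading > 0, anchor_loading < 1, anchor_time > 0,
            bracket[1] > 0, bracket[2] > bracket[1])
  f <- function(s_ref) {
    mol <- molecule_spec(anchor_mw, M_ref = M_ref, s_ref = s_ref)
    simulate_loading(cell, mol, sim, open_time = anchor_time)$loading_efficiency
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- f(lo); f_hi <- f(hi)
  if (f_lo > anchor_loading || f_hi < anchor_loading)
    stop(sprintf(
      "anchor loading %.4f unattainable: bracket [%.3g, %.3g] achieves [%.4f, %.4f]",
      anchor_loading, lo, hi, f_lo, f_hi))
  for (i in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    f_mid <- f(mid)
    if (abs(f_mid - anchor_loading) <= tol) return(mid)
    if (f_mid < anchor_loading) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Loading-efficiency curves over pore-open time or molecular weight
#'
#' Both helpers evaluate [simulate_loading()] on a grid with a common seed
#' policy: replicate `r` uses the same sub-seed at every grid point
#' (common random numbers, reducing the variance of curve shapes).
#'
#' @param times Pore-open times in seconds (for `loading_vs_time`).
#' @param mol A [molecule_spec()] (fixed molecule for the time curve).
#' @param cell A [cell_model()].
#' @param sim A [sim_params()].
#' @return Data frame with one row per grid point: the grid value,
#'   `loading_mean`, `loading_sem`, `n_particles`, `n_replicates`, `seed`.
#' @export
loading_vs_time <- function(times, mol, cell, sim) {
  stopifnot(length(times) >= 1)
  rows <- lapply(times, function(tt) {
    res <- simulate_loading(cell, mol, sim, open_time = tt)
    data.frame(open_time_s = tt, loading_mean = res$loading_efficiency,
               loading_sem = res$sem_over_replicates,
               n_particles = sim$n_particles, n_replicates = sim$n_replicates,
               seed = sim$seed)
  })
  do.call(rbind, rows)
}

#' @rdname loading_vs_time
#' @param mws Molecular weights in kDa (for `loading_vs_mw`).
#' @param open_time Fixed pore-open time in seconds.
#' @param M_ref,s_ref Step-scale anchoring (see [molecule_spec()]).
#' @export
loading_vs_mw <- function(mws, open_time, cell, sim, M_ref = 10, s_ref = 1) {
  stopifnot(length(mws) >= 1)
  rows <- lapply(mws, function(m) {
    res <- simulate_loading(cell, molecule_spec(m, M_ref, s_ref), sim, open_time)
    data.frame(mw_kDa = m, loading_mean = res$loading_efficiency,
               loading_sem = res$sem_over_replicates,
               n_particles = sim$n_particles, n_replicates = sim$n_replicates,
               seed = sim$seed)
  })
  do.call(rbind, rows)
}
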