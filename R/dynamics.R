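#' Langevin dynamics settings
#'
#' @param dt Timestep in fs (default 10).
#' @param temperature Target temperature in K.
#' @param tau Thermostat damping time in ps (default 10, i.e. 1000 timesteps
#'   at dt = 10 fs); `tau <= 0` disables the thermostat (NVE).
#' @param n_steps Number of integration steps.
#' @param stride Sampling stride in steps for frames/energies (0 = none).
#' @param seed Integer seed; identical seeds give bitwise-identical runs.
#' @param cv_stride Stride for recording the umbrella collective variable.
#' @return A `cg_langevin_settings` list.
#' @export
langevin_settings <- function(dt = 10, temperature = 300, tau = 10,
                              n_steps = 10000, stride = 100, seed = 1,
                              cv_stride = 100) {
  stopifnot(dt > 0, n_steps >= 1)
  structure(list(dt = dt, temperature = temperature, tau = tau,
                 n_steps = n_steps, stride = as.integer(stride),
                 seed = seed, cv_stride = as.integer(cv_stride)),
            class = "cg_langevin_settings")
}

.as_frames <- function(flat, n_beads, n_frames) {
  if (n_frames == 0) return(array(numeric(0), dim = c(n_beads, 3, 0)))
  # flat layout: frame-major, bead rows of (x, y, z)
  a <- array(flat[seq_len(n_beads * 3 * n_frames)], dim = c(3, n_beads, n_frames))
  aperm(a, c(2, 1, 3))
}

#' Run Langevin dynamics (NVT, BAOAB splitting)
#'
#' Integrates the system with a BAOAB Langevin scheme; with the thermostat
#' disabled (`tau <= 0`) the scheme reduces to velocity Verlet (NVE).
#' Optionally applies a harmonic umbrella restraint `k (d - d0)^2` on the
#' mass-weighted COM-COM distance of two bead groups.
#'
#' @param topology A `cg_topology`.
#' @param coords Starting `cg_coordinates`.
#' @param settings A [langevin_settings()] object.
#' @param dna_params,hps_params,elec Parameter sets.
#' @param velocities Optional n x 3 starting velocities (A/fs); drawn from the
#'   Maxwell-Boltzmann distribution at the target temperature when `NULL`.
#' @param pbc Periodic minimum-image convention (default `TRUE`).
#' @param umbrella Optional list with `groupA`, `groupB` (1-based bead
#'   indices), `k` (kcal/(mol A^2)) and `d0` (A).
#' @param system Optional precompiled `cg_system`.
#' @return A `cg_trajectory`: list with `frames` (n x 3 x n_frames array),
#'   `energies` (data frame of per-term energies, kinetic energy, kinetic
#'   temperature and bias at each sampled frame), `cv` (umbrella distance
#'   series), `positions`/`velocities` (final state), `settings`, `box`.
#' @export
run_langevin <- function(topology, coords, settings,
                         dna_params = dna_parameters(),
                         hps_params = hps_parameters(),
                         elec = electrostatics_context(),
                         velocities = NULL, pbc = TRUE, umbrella = NULL,
                         system = NULL) {
  if (is.null(system)) {
    system <- interaction_system(topology, dna_params, hps_params, elec)
  }
  s <- unclass(settings)
  s$pbc <- isTRUE(pbc)
  s$box <- as.numeric(if (length(coords$box) == 1) rep(coords$box, 3) else coords$box)
  if (!is.null(umbrella)) {
    stopifnot(length(umbrella$groupA) >= 1, length(umbrella$groupB) >= 1)
    s$umbrella <- list(groupA = as.integer(umbrella$groupA) - 1L,
                       groupB = as.integer(umbrella$groupB) - 1L,
                       k = umbrella$k, d0 = umbrella$d0)
  }
  out <- .cg_run_langevin(coords$positions, velocities, system$masses,
                          unclass(system), s)
  n <- nrow(topology$beads)
  structure(list(
    frames = .as_frames(out$frames, n, out$n_frames),
    energies = out$energies,
    cv = out$cv,
    positions = out$positions, velocities = out$velocities,
    settings = settings, box = s$box, topology_variant = topology$variant
  ), class = "cg_trajectory")
}

#' Temperature replica-exchange molecular dynamics
#'
#' Runs one Langevin replica per ladder temperature and attempts neighbour
#' swaps every `swap_interval` steps with the Metropolis probability
#' `min(1, exp((beta_i - beta_j) (E_i - E_j)))`. Swaps exchange
#' configurations between temperature slots, rescaling velocities by
#' `sqrt(T_new/T_old)`.
#'
#' @param topology A `cg_topology`.
#' @param coords Starting coordinates (shared by all replicas).
#' @param temperatures Strictly increasing ladder (K), length >= 2.
#' @param n_steps Total steps per replica.
#' @param swap_interval Steps between swap attempts (default 100).
#' @param stride Sampling stride in steps (must be a multiple of
#'   `swap_interval`; samples are taken at segment boundaries).
#' @param dt,tau,seed See [langevin_settings()].
#' @param dna_params,hps_params,elec Parameter sets.
#' @param pbc Periodic boundary conditions.
#' @return A `cg_remd` list: `temperatures`; `samples` - per-temperature list
#'   with `energies` (potential, kcal/mol), `frames` (n x 3 x k array) and
#'   `replica` (which walker produced each sample); `swap_attempts`,
#'   `swap_accepts`, `acceptance` (per neighbour pair); `replica_trace`
#'   (temperature-slot occupancy per cycle).
#' @export
run_remd <- function(topology, coords, temperatures, n_steps,
                     swap_interval = 100, stride = 1000, dt = 10, tau = 10,
                     seed = 1,
                     dna_params = dna_parameters(),
                     hps_params = hps_parameters(),
                     elec = electrostatics_context(), pbc = TRUE) {
  m <- length(temperatures)
  # non-decreasing: equal neighbour temperatures are allowed (the swap then
  # accepts with probability 1), which is useful for validating the move
  stopifnot(m >= 2, all(diff(temperatures) >= 0))
  if (stride %% swap_interval != 0) stop("stride must be a multiple of swap_interval")
  n_cycles <- floor(n_steps / swap_interval)
  sample_every <- stride / swap_interval
  system <- interaction_system(topology, dna_params, hps_params, elec)
  n <- nrow(topology$beads)
  kB <- cg_constants$kB

  # slot s holds the state currently simulated at temperatures[s]
  states <- lapply(seq_len(m), function(s) {
    list(positions = coords$positions, velocities = NULL, replica = s, E = NA_real_)
  })
  set.seed(seed %% .Machine$integer.max)
  samples <- lapply(seq_len(m), function(s)
    list(energies = numeric(0), frames = list(), replica = integer(0)))
  attempts <- accepts <- integer(m - 1)
  trace <- matrix(NA_integer_, n_cycles, m)

  for (cyc in seq_len(n_cycles)) {
    for (s in seq_len(m)) {
      st <- states[[s]]
      seg_seed <- (seed * 7919 + cyc * 104729 + s * 611) %% 2^52
      setl <- langevin_settings(dt = dt, temperature = temperatures[s], tau = tau,
                                n_steps = swap_interval, stride = swap_interval,
                                seed = seg_seed)
      setl$pbc <- isTRUE(pbc)
      setl$box <- as.numeric(if (length(coords$box) == 1) rep(coords$box, 3) else coords$box)
      out <- .cg_run_langevin(st$positions, st$velocities, system$masses,
                              unclass(system), unclass(setl))
      states[[s]]$positions <- out$positions
      states[[s]]$velocities <- out$velocities
      states[[s]]$E <- out$energies$potential[nrow(out$energies)]
      if (cyc %% sample_every == 0) {
        samples[[s]]$energies <- c(samples[[s]]$energies, states[[s]]$E)
        samples[[s]]$frames <- c(samples[[s]]$frames, list(out$positions))
        samples[[s]]$replica <- c(samples[[s]]$replica, states[[s]]$replica)
      }
    }
    trace[cyc, ] <- vapply(states, function(st) st$replica, integer(1))
    first <- if (cyc %% 2 == 1) 1 else 2
    for (s in (if (first > m - 1) integer(0) else seq(first, m - 1, by = 2))) {
      attempts[s] <- attempts[s] + 1L
      bi <- 1 / (kB * temperatures[s]); bj <- 1 / (kB * temperatures[s + 1])
      delta <- (bi - bj) * (states[[s]]$E - states[[s + 1]]$E)
      if (log(stats::runif(1)) < min(0, delta)) {
        accepts[s] <- accepts[s] + 1L
        a <- states[[s]]; b <- states[[s + 1]]
        scale_up <- sqrt(temperatures[s + 1] / temperatures[s])
        a$velocities <- a$velocities * scale_up
        b$velocities <- b$velocities / scale_up
        states[[s]] <- b; states[[s + 1]] <- a
      }
    }
  }
  samples <- lapply(samples, function(sm) {
    k <- length(sm$frames)
    fr <- array(NA_real_, dim = c(n, 3, k))
    for (t in seq_len(k)) fr[, , t] <- sm$frames[[t]]
    list(energies = sm$energies, frames = fr, replica = sm$replica)
  })
  structure(list(temperatures = temperatures, samples = samples,
                 swap_attempts = attempts, swap_accepts = accepts,
                 acceptance = ifelse(attempts > 0, accepts / attempts, NA_real_),
                 replica_trace = trace),
            class = "cg_remd")
}

#' Harmonic COM umbrella-sampling windows
#'
#' Runs one restrained Langevin simulation per window centre, chaining the
#' final configuration of each window into the next to keep adjacent windows
#' overlapping, and records the COM-COM distance time series. The bias is
#' `k_u (d - d0)^2` on the mass-weighted COM distance (the convention
#' [wham_pmf()] also uses).
#'
#' @param topology A `cg_topology`.
#' @param coords Starting coordinates.
#' @param groupA,groupB Disjoint 1-based bead index vectors.
#' @param centers Window centres d0 (A).
#' @param k_u Spring constant in kcal/(mol A^2) (default 0.5975).
#' @param n_steps Steps per window.
#' @param equilibration Initial steps per window discarded from the series.
#' @param temperature,dt,tau,seed,cv_stride See [langevin_settings()].
#' @param dna_params,hps_params,elec Parameter sets.
#' @param pbc Periodic boundary conditions.
#' @return A `cg_umbrella` list: `centers`, `k_u`, `temperature`, `series`
#'   (list of numeric COM-distance series, one per window).
#' @export
run_umbrella <- function(topology, coords, groupA, groupB, centers,
                         k_u = 0.5975, n_steps = 50000, equilibration = 5000,
                         temperature = 300, dt = 10, tau = 10, seed = 1,
                         cv_stride = 100,
                         dna_params = dna_parameters(),
                         hps_params = hps_parameters(),
                         elec = electrostatics_context(), pbc = TRUE) {
  stopifnot(length(groupA) >= 1, length(groupB) >= 1,
            length(intersect(groupA, groupB)) == 0)
  system <- interaction_system(topology, dna_params, hps_params, elec)
  state <- coords
  vel <- NULL
  series <- vector("list", length(centers))
  for (w in seq_along(centers)) {
    setl <- langevin_settings(dt = dt, temperature = temperature, tau = tau,
                              n_steps = n_steps, stride = 0,
                              seed = (seed * 2654435761 + w) %% 2^52,
                              cv_stride = cv_stride)
    traj <- run_langevin(topology, state, setl, velocities = vel, pbc = pbc,
                         umbrella = list(groupA = groupA, groupB = groupB,
                                         k = k_u, d0 = centers[w]),
                         system = system)
    keep <- seq_along(traj$cv) > floor(equilibration / cv_stride)
    series[[w]] <- traj$cv[keep]
    state$positions <- traj$positions
    vel <- traj$velocities
  }
  structure(list(centers = centers, k_u = k_u, temperature = temperature,
                 series = series),
            class = "cg_umbrella")
}
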