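kB <- cg_constants$kB

# two-bead protein dimer: a single harmonic bond (K = 10, r0 = 3.8), no
# nonbonded terms once the HPS strength is zeroed
dimer <- build_protein_topology("GG")
dimer_coords <- structure(list(positions = rbind(c(0, 0, 0), c(3.8, 0, 0)),
                               box = c(200, 200, 200)), class = "cg_coordinates")
hps_off <- hps_parameters(eps = 0)

bond_series <- function(traj) {
  apply(traj$frames, 3, function(p) sqrt(sum((p[1, ] - p[2, ])^2)))
}

# oracle moments of the bond length under P(r) ~ r^2 exp(-beta K (r-r0)^2)
bond_oracle <- function(temperature, K = 10, r0 = 3.8) {
  r <- seq(max(1e-3, r0 - 3), r0 + 3, length.out = 20001)
  w <- r^2 * exp(-(K * (r - r0)^2) / (kB * temperature))
  w <- w / sum(w)
  m <- sum(w * r)
  list(mean = m, var = sum(w * (r - m)^2))
}

test_that("identical seeds give bitwise-identical trajectories", {
  top <- make_duplex("two_bead")
  crd <- build_bdna_coordinates(top)
  s <- langevin_settings(temperature = 300, n_steps = 2000, stride = 100, seed = 123)
  t1 <- run_langevin(top, crd, s)
  t2 <- run_langevin(top, crd, s)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$energies, t2$energies)
  t3 <- run_langevin(top, crd, langevin_settings(temperature = 300, n_steps = 2000,
                                                 stride = 100, seed = 124))
  expect_false(identical(t1$frames, t3$frames))
})

test_that("a free bead equipartitions to the target temperature", {
  top <- build_protein_topology("G")
  crd <- structure(list(positions = matrix(0, 1, 3), box = c(100, 100, 100)),
                   class = "cg_coordinates")
  tr <- run_langevin(top, crd, langevin_settings(temperature = 300, tau = 1,
                                                 n_steps = 100000, stride = 50,
                                                 seed = 5),
                     hps_params = hps_off)
  # kinetic temperature estimator: mean within 5% of the target
  expect_lt(abs(mean(tr$energies$kinetic_temperature) - 300) / 300, 0.05)
})

test_that("bond lengths sample the Boltzmann distribution at 300 K", {
  tr <- run_langevin(dimer, dimer_coords,
                     langevin_settings(temperature = 300, tau = 1,
                                       n_steps = 300000, stride = 100, seed = 11),
                     hps_params = hps_off, pbc = FALSE)
  r <- bond_series(tr)
  o <- bond_oracle(300)
  se_mean <- cgdna:::.block_se(r, 10)
  expect_lt(abs(mean(r) - o$mean), 3 * se_mean + 1e-6)
  # variance within 3 sigma (block jackknife of the variance)
  blocks <- split(r, cut(seq_along(r), 10, labels = FALSE))
  v_b <- vapply(blocks, var, numeric(1))
  expect_lt(abs(var(r) - o$var), 3 * sd(v_b) / sqrt(length(v_b)) + 1e-8)
})

test_that("with the thermostat off the integrator conserves energy", {
  top <- make_duplex("two_bead")
  crd <- build_bdna_coordinates(top)
  tr <- run_langevin(top, crd, langevin_settings(dt = 1, temperature = 300,
                                                 tau = 0, n_steps = 10000,
                                                 stride = 100, seed = 17),
                     velocities = matrix(0, nrow(top$beads), 3))
  etot <- tr$energies$potential + tr$energies$kinetic
  drift <- abs(etot[length(etot)] - etot[1]) / 10000
  expect_lt(drift, 1e-3)
})

test_that("equilibrium observables are insensitive to the damping time", {
  means <- ses <- numeric(3)
  taus <- c(1, 10, 100)
  for (i in seq_along(taus)) {
    tr <- run_langevin(dimer, dimer_coords,
                       langevin_settings(temperature = 300, tau = taus[i],
                                         n_steps = 400000, stride = 200,
                                         seed = 20 + i),
                       hps_params = hps_off, pbc = FALSE)
    r <- bond_series(tr)
    means[i] <- mean(r)
    ses[i] <- cgdna:::.block_se(r, 5)
  }
  for (i in 1:2) for (j in (i + 1):3) {
    expect_lt(abs(means[i] - means[j]), 3 * sqrt(ses[i]^2 + ses[j]^2))
  }
})

test_that("numeric blow-up aborts naming the step", {
  top <- build_dna_topology("AT", "two_bead", duplex = TRUE)
  crd <- build_bdna_coordinates(top)
  crd$positions[2, ] <- crd$positions[6, ] + c(0.05, 0, 0)  # deep overlap
  expect_error(
    run_langevin(top, crd, langevin_settings(dt = 50, temperature = 300,
                                             n_steps = 1000, stride = 0, seed = 1)),
    "step")
})

test_that("replica exchange: acceptance is 1 at equal temperatures", {
  remd <- run_remd(dimer, dimer_coords, c(300, 300), n_steps = 5000,
                   swap_interval = 100, stride = 500, seed = 3,
                   hps_params = hps_off, pbc = FALSE)
  expect_equal(unname(remd$acceptance), 1)
})

test_that("replica exchange preserves per-temperature Boltzmann statistics", {
  temps <- c(250, 300, 360, 430)
  remd <- run_remd(dimer, dimer_coords, temps, n_steps = 250000,
                   swap_interval = 100, stride = 200, seed = 7,
                   hps_params = hps_off, pbc = FALSE)
  for (i in seq_along(temps)) {
    r <- apply(remd$samples[[i]]$frames, 3,
               function(p) sqrt(sum((p[1, ] - p[2, ])^2)))
    o <- bond_oracle(temps[i])
    se <- cgdna:::.block_se(r, 5)
    expect_lt(abs(mean(r) - o$mean), 3 * se + 1e-6)
    blocks <- split(r, cut(seq_along(r), 5, labels = FALSE))
    v_b <- vapply(blocks, var, numeric(1))
    expect_lt(abs(var(r) - o$var), 3 * sd(v_b) / sqrt(5) + 1e-8)
  }
  # swaps actually happen on this ladder
  expect_true(all(remd$acceptance > 0.2))
  # replica random walk: every walker visits both ladder extremes
  for (rep_id in seq_along(temps)) {
    expect_true(rep_id %in% remd$replica_trace[, 1])
    expect_true(rep_id %in% remd$replica_trace[, length(temps)])
  }
})

test_that("the swap rule satisfies detailed balance on a two-state toy", {
  # two replicas at beta1, beta2; each system has states {0, dE}; moves:
  # independent single-system Metropolis flips + the replica swap move.
  # The empirical joint distribution must match the product Boltzmann law.
  set.seed(42)
  dE <- 1.0
  b <- 1 / (kB * c(280, 400))
  s <- c(0L, 1L)  # state of system in slot 1, 2 (0 = ground, 1 = excited)
  counts <- matrix(0, 2, 2)
  for (it in 1:40000) {
    for (k in 1:2) {  # single-system flips
      prop <- 1L - s[k]
      dU <- (prop - s[k]) * dE
      if (log(runif(1)) < -b[k] * dU) s[k] <- prop
    }
    delta <- (b[1] - b[2]) * (s[1] - s[2]) * dE  # swap move
    if (log(runif(1)) < min(0, delta)) s <- rev(s)
    counts[s[1] + 1, s[2] + 1] <- counts[s[1] + 1, s[2] + 1] + 1
  }
  p1 <- c(1, exp(-b[1] * dE)); p1 <- p1 / sum(p1)
  p2 <- c(1, exp(-b[2] * dE)); p2 <- p2 / sum(p2)
  expected <- outer(p1, p2)
  n <- sum(counts)
  for (i in 1:2) for (j in 1:2) {
    se <- sqrt(expected[i, j] * (1 - expected[i, j]) / n)
    # 3 sigma with a correlation-inflation factor for the Markov chain
    expect_lt(abs(counts[i, j] / n - expected[i, j]), 3 * 3 * se)
  }
})

test_that("umbrella restraint samples the biased Boltzmann distribution", {
  two <- combine_topologies(build_protein_topology("G"), build_protein_topology("G"))
  crd <- structure(list(positions = rbind(c(0, 0, 0), c(10, 0, 0)),
                        box = c(400, 400, 400)), class = "cg_coordinates")
  k_u <- 0.5975; d0 <- 10
  um <- run_umbrella(two, crd, groupA = 1, groupB = 2, centers = d0,
                     k_u = k_u, n_steps = 400000, equilibration = 20000,
                     temperature = 300, tau = 1, seed = 13, cv_stride = 50,
                     hps_params = hps_off, pbc = FALSE)
  d <- um$series[[1]]
  # oracle: P(d) ~ d^2 exp(-beta k (d - d0)^2)
  grid <- seq(0.1, 25, length.out = 20001)
  w <- grid^2 * exp(-k_u * (grid - d0)^2 / (kB * 300)); w <- w / sum(w)
  mo <- sum(w * grid)
  se <- cgdna:::.block_se(d, 5)
  # small absolute allowance for the finite-timestep configurational bias of
  # the discretised Langevin scheme
  expect_lt(abs(mean(d) - mo), 3 * se + 0.01)
  # mean restraint energy is finite and on the kT scale
  eb <- mean(k_u * (d - d0)^2)
  expect_gt(eb, 0)
  expect_lt(eb, 3 * kB * 300)
})

test_that("windows 5 A apart with the printed spring constant overlap", {
  two <- combine_topologies(build_protein_topology("G"), build_protein_topology("G"))
  crd <- structure(list(positions = rbind(c(0, 0, 0), c(10, 0, 0)),
                        box = c(400, 400, 400)), class = "cg_coordinates")
  um <- run_umbrella(two, crd, groupA = 1, groupB = 2, centers = c(10, 15),
                     k_u = 0.5975, n_steps = 200000, equilibration = 10000,
                     temperature = 300, tau = 1, seed = 29, cv_stride = 20,
                     hps_params = hps_off, pbc = FALSE)
  # 1 A bins: shared support between the 3.5-sigma tails of adjacent windows
  rng <- range(unlist(um$series))
  breaks <- seq(floor(rng[1]) - 1e-9, ceiling(rng[2]) + 1, by = 1)
  h1 <- hist(um$series[[1]], breaks = breaks, plot = FALSE)$counts
  h2 <- hist(um$series[[2]], breaks = breaks, plot = FALSE)$counts
  expect_gt(sum(h1 * h2), 0)  # nonzero product integral = shared support
})

test_that("empty umbrella groups are rejected", {
  two <- combine_topologies(build_protein_topology("G"), build_protein_topology("G"))
  crd <- structure(list(positions = rbind(c(0, 0, 0), c(10, 0, 0)),
                        box = c(100, 100, 100)), class = "cg_coordinates")
  expect_error(run_umbrella(two, crd, groupA = integer(0), groupB = 2,
                            centers = 10))
})
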