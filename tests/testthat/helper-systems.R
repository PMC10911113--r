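# Shared fixtures and oracles, all generated in code.

SEQ_S1 <- "GCGTCATACAGTGC"                     # 14 bp parametrisation duplex
SEQ_32 <- "ATACAAAGGTGCGAGGTTTCTATGCTCCCACG"  # 32 bp structure sequence

# synthetic stand-in for the 111-residue histone H1 C-terminal domain:
# 45 Lys/Arg, 2 Asp/Glu, net +43 (the real SI sequence is not distributed
# with the package)
H1_CTD_SYNTHETIC <- paste0(
  paste(rep("KAPKSA", 15), collapse = ""),  # 90 res, 30 K
  "RKRKRKRKRKRKRKR",                        # 15 res, 15 K/R
  "DEGSAT"                                  # 6 res, 2 D/E
)

make_duplex <- function(variant = "two_bead", seq = SEQ_S1) {
  build_dna_topology(seq, variant, duplex = TRUE)
}

# deterministic coordinate jitter
jitter_positions <- function(coords, sd = 0.1, seed = 1) {
  set.seed(seed)
  coords$positions <- coords$positions +
    matrix(rnorm(length(coords$positions), 0, sd), ncol = 3)
  coords
}

# central-difference gradient of the total energy
numeric_forces <- function(topology, coords, system, h = 1e-4, beads = NULL) {
  pos <- coords$positions
  if (is.null(beads)) beads <- seq_len(nrow(pos))
  g <- matrix(NA_real_, length(beads), 3)
  for (bi in seq_along(beads)) {
    i <- beads[bi]
    for (c in 1:3) {
      p1 <- pos; p1[i, c] <- p1[i, c] + h
      p2 <- pos; p2[i, c] <- p2[i, c] - h
      e1 <- total_energy_forces(topology, p1, box = coords$box, system = system)$total
      e2 <- total_energy_forces(topology, p2, box = coords$box, system = system)$total
      g[bi, c] <- -(e1 - e2) / (2 * h)
    }
  }
  g
}

# draw exact samples from a 1D density given on a grid (inverse CDF)
sample_from_density <- function(r, dens, n, seed = 1) {
  set.seed(seed)
  cdf <- cumsum(dens) / sum(dens)
  ok <- !duplicated(cdf)
  stats::approx(cdf[ok], r[ok], runif(n), rule = 2)$y
}

# run_langevin with deterministic seed-derived retries on the (rare)
# integrator blow-up of the stiff dummy-bead pair at dt = 10 fs
run_langevin_retry <- function(topology, coords, settings, ...) {
  for (attempt in 0:4) {
    s <- settings
    s$seed <- settings$seed + 131071 * attempt
    out <- tryCatch(run_langevin(topology, coords, s, ...),
                    error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  stop("Langevin run failed repeatedly")
}

# equilibration protocol used for structural runs: cold staged anneal from the
# ideal fixture, then production at the target temperature
anneal_equilibrate <- function(topology, coords, temperature, elec, seed,
                               stage_steps = 15000) {
  vel <- NULL
  stages <- c(150, 190, 230, 260, temperature)
  for (i in seq_along(stages)) {
    t1 <- run_langevin_retry(topology, coords,
                             langevin_settings(temperature = stages[i],
                                               n_steps = stage_steps, stride = 0,
                                               seed = seed + i),
                             elec = elec, velocities = vel)
    coords$positions <- t1$positions
    vel <- t1$velocities
  }
  list(coords = coords, velocities = vel)
}
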