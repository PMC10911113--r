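test_that("closed-form bonded potentials match the printed constants", {
  expect_equal(u_harmonic_bond(5.5, "bb_bb"), 0)
  expect_equal(u_harmonic_bond(6.5, "bb_bb"), 50)
  expect_equal(u_harmonic_bond(5.5 + 0.3, "bb_bb"),
               u_harmonic_bond(5.5 - 0.3, "bb_bb"))
  expect_equal(u_harmonic_bond(4.8, "bb_base"), 50 * (4.8 - 5.75)^2)
  expect_equal(u_harmonic_bond(4.0, "protein"), 10 * 0.2^2)
  expect_error(u_harmonic_bond(5, "nope"), "unknown bond class")

  expect_equal(u_cosine_sq_angle(180, "backbone"), 0)
  expect_equal(u_cosine_sq_angle(90, "backbone"), 40)
  expect_equal(u_cosine_sq_angle(90, "hb"), 80)
  expect_equal(u_cosine_sq_angle(0, "backbone"), 160)  # (1 - (-1))^2 K
})

test_that("12-10 potential has depth -delta at sigma and respects its cutoff", {
  expect_equal(u_lj1210(3.6, 3.6, 9.7, 6.2), -9.7)
  # numerical minimisation confirms the minimum location and depth
  opt <- optimize(function(r) u_lj1210(r, 3.6, 9.7, Inf), c(2, 6))
  expect_equal(opt$minimum, 3.6, tolerance = 1e-4)
  expect_equal(opt$objective, -9.7, tolerance = 1e-8)
  expect_equal(u_lj1210(6.2, 3.6, 9.7, 6.2), 0)
  expect_equal(u_lj1210(100, 3.6, 9.7, Inf), 0, tolerance = 1e-10)
  # monotonically increasing beyond the minimum
  r <- seq(3.6, 6.19, length.out = 50)
  expect_true(all(diff(u_lj1210(r, 3.6, 9.7, 6.2)) > 0))
  # plain truncation: residuals at the stated cutoffs are a few percent of
  # the well depth (0.019 delta at r_stack, 0.04 delta at r_HB) and documented
  expect_lt(abs(u_lj1210(6.199, 3.6, 9.7, Inf)) / 9.7, 0.05)
  expect_lt(abs(u_lj1210(9.499, 6.0, 2.7, Inf)) / 2.7, 0.05)
})

test_that("WCA potential is purely repulsive with the printed constants", {
  expect_equal(u_wca(5.5), 4)                      # r = sigma_ex
  expect_equal(u_wca(2^(1 / 6) * 5.5), 0)
  expect_equal(u_wca(7.0), 0)
  r <- seq(3.5, 8, length.out = 200)
  expect_true(all(u_wca(r) >= 0))
  # vanishes continuously at the cutoff
  expect_lt(u_wca(2^(1 / 6) * 5.5 - 1e-6), 1e-4)
})

test_that("Debye-Hueckel potential matches its closed form and cutoff", {
  ctx <- electrostatics_context(100)
  expect_equal(ctx$kappa, 10)
  expect_equal(electrostatics_context(120)$kappa, 8.8)
  expect_equal(u_debye_huckel(0, -1, 5, ctx), 0)
  expect_equal(u_debye_huckel(-1, -1, 10, ctx),
               332.06 * exp(-1) / (80 * 10), tolerance = 1e-12)
  expect_equal(round(u_debye_huckel(-1, -1, 10, ctx), 3), 0.153)
  expect_equal(u_debye_huckel(-1, -1, 36, ctx), 0)  # beyond 3.5 kappa
  expect_lt(u_debye_huckel(-1, -1, 35 - 1e-6, ctx), 5e-3)
})

test_that("HPS pair potential has the Ashbaugh-Hatch branch structure", {
  # lambda = 0 pair: zero at the branch point and purely repulsive
  p0 <- hps_parameters(lambda_scale = 0)
  sig <- p0$species$sigma[p0$species$species == "G"]
  rmin <- 2^(1 / 6) * sig
  expect_equal(u_hps_pair("G", "G", rmin, p0), 0, tolerance = 1e-12)
  r <- seq(3, 15, length.out = 300)
  u0 <- u_hps_pair("G", "G", r, p0)
  expect_true(all(u0 >= 0))
  expect_true(all(u0[r > rmin] == 0))

  # lambda = 1 pair: plain LJ, continuous at the branch point
  p1 <- hps_parameters()
  p1$species$lambda[] <- 1
  eps <- p1$eps
  u_at <- u_hps_pair("G", "G", rmin, p1)
  expect_equal(u_at, -eps, tolerance = 1e-12)
  expect_equal(u_hps_pair("G", "G", rmin + 1e-9, p1), u_at, tolerance = 1e-6)

  # protein vs dummy HB bead: zero at all distances
  expect_equal(u_hps_pair("K", "hb_a", c(2, 4, 8), hps_parameters()),
               c(0, 0, 0))
  expect_error(u_hps_pair("K", "ZZ", 5), "no HPS entry")

  # both hydropathy scales are selectable and differ
  expect_false(isTRUE(all.equal(hps_parameters("urry")$species$lambda,
                                hps_parameters("kr")$species$lambda)))
})

test_that("parameter tables carry the calibrated constants exactly", {
  p <- dna_parameters()
  stk <- setNames(p$stacking$delta, p$stacking$pair)
  expect_equal(stk[["A-A"]], 9.7)
  expect_equal(stk[["G-G"]], 11.0)
  expect_equal(stk[["C-G"]], 8.3)
  expect_equal(unique(p$stacking$sigma), 3.6)
  expect_equal(p$r_stack, 6.2)
  expect_equal(p$hb2$sigma, c(6.0, 5.5))
  expect_equal(p$hb2$delta, c(2.7, 3.3))
  expect_equal(p$r_hb2, 9.5)
  expect_equal(p$hb3$delta, c(8.5, 10.4))
  expect_equal(p$r_hb3, 3.3)
  expect_equal(p$eps_ex, 4); expect_equal(p$sigma_ex, 5.5)
  # scaling factors are relative to the folded-in calibration
  expect_equal(dna_parameters(delta_stack = 4.2)$stacking$delta,
               2 * p$stacking$delta)
  expect_equal(dna_parameters(delta_hb = 0.475)$hb2$delta, p$hb2$delta / 2)
  hl <- hps_parameters()$species
  expect_equal(hl$lambda[match(c("BB", "dA", "dT", "dC", "dG"), hl$species)],
               c(0.38, 0.40, 0.54, 0.59, 0.35))
})

test_that("forces are the exact negative gradient on mixed systems", {
  # DNA duplex (bond, angle, stacking, HB, WCA, DH), both variants
  for (variant in c("two_bead", "three_bead")) {
    top <- build_dna_topology("GCGTCATAC", variant, duplex = TRUE)
    crd <- jitter_positions(build_bdna_coordinates(top), 0.15, seed = 3)
    sys <- interaction_system(top)
    er <- total_energy_forces(top, crd$positions, box = crd$box, system = sys)
    idx <- seq(1, nrow(crd$positions), by = 5)
    num <- numeric_forces(top, crd, sys, beads = idx)
    scale <- max(1, max(abs(er$forces[idx, ])))
    expect_lt(max(abs(num - er$forces[idx, ])) / scale, 1e-5)
  }
  # protein-DNA complex (adds HPS and cross electrostatics)
  dna <- build_dna_topology("ACGTAC", "two_bead", duplex = TRUE)
  prot <- build_protein_topology("KRWEDGK")
  sys_top <- combine_topologies(dna, prot)
  cd <- build_bdna_coordinates(dna)
  cp <- build_extended_protein_coordinates(prot, origin = c(12, 0, 5))
  crd <- jitter_positions(combine_coordinates(cd, cp, box = cd$box), 0.1, seed = 4)
  sys <- interaction_system(sys_top)
  er <- total_energy_forces(sys_top, crd$positions, box = crd$box, system = sys)
  num <- numeric_forces(sys_top, crd, sys)
  scale <- max(1, max(abs(er$forces)))
  expect_lt(max(abs(num - er$forces)) / scale, 1e-5)
})

test_that("energy is invariant under rigid motions; net force and torque vanish", {
  top <- make_duplex("three_bead")
  crd <- jitter_positions(build_bdna_coordinates(top, box = 1e5), 0.1, seed = 5)
  sys <- interaction_system(top)
  e0 <- total_energy_forces(top, crd$positions, box = crd$box, system = sys,
                            pbc = FALSE)
  # translation
  e1 <- total_energy_forces(top, sweep(crd$positions, 2, c(13.3, -7.1, 2.2), "+"),
                            box = crd$box, system = sys, pbc = FALSE)
  expect_equal(e1$total, e0$total, tolerance = 1e-10)
  # rotation
  th <- 0.83
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  e2 <- total_energy_forces(top, crd$positions %*% Rz, box = crd$box,
                            system = sys, pbc = FALSE)
  expect_equal(e2$total, e0$total, tolerance = 1e-10)
  # Newton's third law and zero net torque in vacuum
  expect_lt(max(abs(colSums(e0$forces))), 1e-9)
  tq <- colSums(cbind(
    crd$positions[, 2] * e0$forces[, 3] - crd$positions[, 3] * e0$forces[, 2],
    crd$positions[, 3] * e0$forces[, 1] - crd$positions[, 1] * e0$forces[, 3],
    crd$positions[, 1] * e0$forces[, 2] - crd$positions[, 2] * e0$forces[, 1]))
  expect_lt(max(abs(tq)), 1e-7)
})

test_that("widely separated strands have zero interstrand energy", {
  top <- make_duplex("two_bead")
  crd <- build_bdna_coordinates(top, box = 2000)
  n2 <- top$beads$index[top$beads$chain == 2]
  far <- crd
  far$positions[n2, 1] <- far$positions[n2, 1] + 500  # beyond every cutoff
  e_far <- total_energy_forces(top, far)
  # single strands retain their intrastrand terms; all interstrand terms vanish
  single <- build_dna_topology(SEQ_S1, "two_bead")
  e1 <- total_energy_forces(single, far$positions[top$beads$chain == 1, ],
                            box = far$box)
  s2 <- build_dna_topology(dna_complement(SEQ_S1), "two_bead")
  e2 <- total_energy_forces(s2, far$positions[top$beads$chain == 2, ], box = far$box)
  expect_equal(e_far$total, e1$total + e2$total, tolerance = 1e-9)
})

test_that("minimum-image convention makes energy invariant to box wrapping", {
  top <- make_duplex("two_bead")
  crd <- build_bdna_coordinates(top, box = 150)
  e0 <- total_energy_forces(top, crd)
  wrapped <- crd
  wrapped$positions[, 1] <- wrapped$positions[, 1] + 150  # full box shift
  e1 <- total_energy_forces(top, wrapped)
  expect_equal(e1$total, e0$total, tolerance = 1e-9)
})

test_that("overlapping beads are rejected with the pair identity", {
  top <- build_dna_topology("AT", "two_bead", duplex = TRUE)
  crd <- build_bdna_coordinates(top)
  crd$positions[6, ] <- crd$positions[2, ]
  expect_error(total_energy_forces(top, crd), "overlapping")
})

test_that("toggling a pair's class changes exactly one term", {
  top <- make_duplex("two_bead")
  crd <- jitter_positions(build_bdna_coordinates(top), 0.05, seed = 8)
  e0 <- total_energy_forces(top, crd)
  # move the closest excluded-volume pair (inside both cutoffs) into the
  # stacking class
  top2 <- top
  dd <- sqrt(rowSums((crd$positions[top2$pairs$excluded$i, ] -
                        crd$positions[top2$pairs$excluded$j, ])^2))
  k <- which.min(dd)
  mv <- top2$pairs$excluded[k, ]
  top2$pairs$excluded <- top2$pairs$excluded[-k, ]
  top2$pairs$stacking <- rbind(top2$pairs$stacking, mv)
  e1 <- total_energy_forces(top2, crd)
  changed <- names(which(abs(e1$terms - e0$terms) > 1e-12))
  expect_setequal(changed, c("stacking", "excluded"))
  expect_equal(e1$terms[["bond"]], e0$terms[["bond"]])
  expect_equal(e1$terms[["hb"]], e0$terms[["hb"]])
  expect_equal(e1$terms[["electrostatics"]], e0$terms[["electrostatics"]])
})
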