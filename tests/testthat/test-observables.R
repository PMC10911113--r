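test_that("hybridization classification counts engaged sites per strand", {
  for (variant in c("two_bead", "three_bead")) {
    top <- make_duplex(variant)
    crd <- build_bdna_coordinates(top)
    h <- classify_hybridized(crd, top)
    expect_true(h$hybridized)
    expect_equal(h$engaged, c(14, 14))
    # displace strand 2 far away: fully melted
    far <- crd
    i2 <- top$beads$index[top$beads$chain == 2]
    far$positions[i2, ] <- far$positions[i2, ] + 100
    far$box <- c(1e4, 1e4, 1e4)
    h2 <- classify_hybridized(far, top)
    expect_false(h2$hybridized)
    expect_equal(h2$engaged, c(0, 0))
  }
  expect_error(classify_hybridized(matrix(0, 2, 3),
                                   build_dna_topology("A", "two_bead")),
               "duplex")
})

test_that("half-engaged strands sit exactly on the hybridized boundary", {
  # synthetic positions: isolated base-pair slots 40 A apart; the first k
  # partners are placed 5 A apart (engaged), the rest 30 A (not engaged)
  top <- make_duplex("two_bead")
  b <- top$beads; n <- 14
  place <- function(k_engaged) {
    pos <- matrix(0, nrow(b), 3)
    for (i in 1:n) {
      s1 <- b$index[b$chain == 1 & b$residue == i & b$kind == "dna_base"]
      p1 <- b$index[b$chain == 1 & b$residue == i & b$kind == "dna_backbone"]
      s2 <- b$index[b$chain == 2 & b$residue == (n + 1 - i) & b$kind == "dna_base"]
      p2 <- b$index[b$chain == 2 & b$residue == (n + 1 - i) & b$kind == "dna_backbone"]
      x <- 40 * i
      gap <- if (i <= k_engaged) 5 else 30
      pos[s1, ] <- c(x, 0, 0);   pos[p1, ] <- c(x, -6, 0)
      pos[s2, ] <- c(x, gap, 0); pos[p2, ] <- c(x, gap + 6, 0)
    }
    pos
  }
  h7 <- classify_hybridized(place(7), top, box = NULL)
  expect_equal(h7$engaged, c(7, 7))
  expect_true(h7$hybridized)   # "at least half" is inclusive
  h6 <- classify_hybridized(place(6), top, box = NULL)
  expect_false(h6$hybridized)
})

test_that("melting analysis recovers a sharp transition and zero-variance Cv", {
  temps <- seq(300, 360, by = 5)
  tstar <- 332.5
  melted <- lapply(temps, function(Tk) rep(Tk > tstar, 100))
  energies <- lapply(temps, function(Tk) rep(-50, 100))
  res <- melting_analysis(temps, melted, energies)
  expect_equal(res$tm_fraction, (330 + 335) / 2)  # midpoint of the jump
  expect_true(all(res$heat_capacity$cv == 0))
  expect_true(all(res$curve$fraction_melted %in% c(0, 1)))
  expect_error(melting_analysis(300, list(TRUE), list(1)), "at least 2")
})

test_that("two-state ensembles give consistent fraction- and Cv-based Tm", {
  # exact two-state model: ground state 0 (hybridized), excited dE with
  # degeneracy g (melted); Tm* = dE / (kB ln g)
  kB <- cg_constants$kB
  dE <- 30; g <- 1e6
  tstar <- dE / (kB * log(g))
  temps <- seq(tstar - 40, tstar + 40, by = 5)
  set.seed(99)
  melted <- list(); energies <- list()
  for (i in seq_along(temps)) {
    p <- g * exp(-dE / (kB * temps[i])) / (1 + g * exp(-dE / (kB * temps[i])))
    m <- runif(4000) < p
    melted[[i]] <- m
    energies[[i]] <- ifelse(m, dE, 0)
  }
  res <- melting_analysis(temps, melted, energies)
  expect_lt(abs(res$tm_fraction - tstar), 3 * res$tm_fraction_se + 1)
  # Cv-based Tm must agree with the analytic Cv maximum of the same model
  cv_exact <- function(Tk) {
    p <- g * exp(-dE / (kB * Tk)) / (1 + g * exp(-dE / (kB * Tk)))
    dE^2 * p * (1 - p) / (kB * Tk^2)
  }
  t_cv_star <- optimize(cv_exact, range(temps), maximum = TRUE)$maximum
  expect_lt(abs(res$tm_cv - t_cv_star), 3 * res$tm_cv_se + 5)
  # the two definitions agree within their mutual uncertainties plus the
  # analytic offset between the Cv maximum and the half-population point
  # (the Schottky peak of a finite-degeneracy two-state system sits slightly
  # off the p = 0.5 temperature)
  expect_lt(abs(res$tm_cv - res$tm_fraction),
            abs(t_cv_star - tstar) +
              3 * sqrt(res$tm_cv_se^2 + res$tm_fraction_se^2) + 5)
})

test_that("helical analysis recovers the construction parameters exactly", {
  for (variant in c("two_bead", "three_bead")) {
    top <- build_dna_topology(SEQ_32, variant, duplex = TRUE)
    crd <- build_bdna_coordinates(top)          # 36 deg, 3.4 A
    hp <- helical_parameters(crd, top)
    expect_lt(abs(hp$rise[["mean"]] - 3.4), 0.01)
    expect_lt(abs(hp$bp_per_turn[["mean"]] - 10), 0.05)
    # width equals the builder's steric diameter: 2 r_backbone + sigma_ex
    g <- cgdna:::.bdna_geometry(variant)
    # tetrad-centroid axis carries a small (<= ~6%) radial bias when the
    # backbone phases are strongly asymmetric
    expect_lt(abs(hp$width[["mean"]] - (2 * g$R + 5.5)) / (2 * g$R + 5.5), 0.08)
    # unwound fixture
    crd2 <- build_bdna_coordinates(top, twist = 360 / 11)
    hp2 <- helical_parameters(crd2, top)
    expect_lt(abs(hp2$bp_per_turn[["mean"]] - 11), 0.05)
  }
})

test_that("structural reports are invariant under rigid-body motion", {
  top <- build_dna_topology(SEQ_32, "two_bead", duplex = TRUE)
  crd <- build_bdna_coordinates(top)
  hp0 <- helical_parameters(crd, top)
  gw0 <- groove_widths(crd, top, 19)
  th <- 1.1
  Ry <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  moved <- crd
  moved$positions <- sweep(crd$positions %*% Ry, 2, c(31, -4, 17), "+")
  hp1 <- helical_parameters(moved, top)
  gw1 <- groove_widths(moved, top, 19)
  expect_equal(hp1$rise, hp0$rise, tolerance = 1e-8)
  expect_equal(hp1$bp_per_turn, hp0$bp_per_turn, tolerance = 1e-8)
  expect_equal(hp1$width, hp0$width, tolerance = 1e-8)
  expect_equal(gw1$minor, gw0$minor, tolerance = 1e-8)
  expect_equal(gw1$major, gw0$major, tolerance = 1e-8)
})

test_that("groove widths on the rigid fixture are constant and ordered", {
  top <- build_dna_topology(SEQ_32, "three_bead", duplex = TRUE)
  crd <- build_bdna_coordinates(top)
  frames <- array(rep(crd$positions, 4), dim = c(nrow(crd$positions), 3, 4))
  gw <- groove_widths(frames, top, 19)
  expect_lt(gw$minor[["sd"]], 0.05)
  expect_lt(gw$major[["sd"]], 0.05)
  # bead-centre convention: the "minor groove" separation is the larger one
  expect_gt(gw$minor[["mean"]], gw$major[["mean"]])
  expect_error(groove_widths(crd, top, 2), "termini")
  expect_error(groove_widths(crd, top, 31), "termini")
})

test_that("melted frames are excluded from helical statistics and counted", {
  top <- build_dna_topology(SEQ_32, "two_bead", duplex = TRUE)
  crd <- build_bdna_coordinates(top)
  melted <- crd$positions
  i2 <- top$beads$index[top$beads$chain == 2]
  melted[i2, ] <- melted[i2, ] + 200
  frames <- array(c(crd$positions, melted, crd$positions),
                  dim = c(nrow(crd$positions), 3, 3))
  hp <- helical_parameters(frames, top)
  expect_equal(hp$n_frames_used, 2)
  expect_equal(hp$n_frames_melted, 1)
  expect_lt(abs(hp$rise[["mean"]] - 3.4), 0.01)
})

test_that("contact maps report per-frame any-contact probabilities", {
  top <- combine_topologies(build_protein_topology("GG"),
                            build_protein_topology("GG"))
  # 3 frames: groups in contact in 2 of 3
  near <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(5, 0, 0), c(8.8, 0, 0))
  far <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(60, 0, 0), c(63.8, 0, 0))
  frames <- array(c(near, far, near), dim = c(4, 3, 3))
  cm <- contact_map(frames, top, list(a = 1:2), list(b = 3:4), cutoff = 6)
  expect_equal(cm[1, 1], 2 / 3)
  cm_far <- contact_map(far, top, list(a = 1:2), list(b = 3:4), cutoff = 6)
  expect_equal(cm_far[1, 1], 0)
  cm_near <- contact_map(near, top, list(a = 1:2), list(b = 3:4), cutoff = 6)
  expect_equal(cm_near[1, 1], 1)
  # default cutoff rule: 1.5 x mean pair diameter
  cm_def <- contact_map(near, top, list(a = 1:2), list(b = 3:4))
  expect_equal(cm_def[1, 1], 1)  # 4.5 - 3.8 gap < 1.5 * 4.5
  expect_error(contact_map(frames, top, list(integer(0)), list(b = 3:4)),
               "empty")
})
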