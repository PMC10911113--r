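# Ideal B-form duplex construction.
#
# The helix axis is z. Base pair k (0-based) sits at twist angle theta = k*twist
# and height z = k*rise. Within the base-pair plane the strand-1 backbone is at
# radius R and phase +delta, the strand-2 backbone at -delta; base beads at
# radius r_s and phases +/- phi1. The backbone radius R is fixed by closing the
# backbone-backbone bond (r0 = 5.5 A) over one helical step; (r_s, phi1, delta)
# are solved numerically once per model variant so that
#   * the backbone-base bond equals its r0,
#   * complementary HB sites sit inside the engagement band,
#   * diagonal cross-strand base contacts stay outside the strongly repulsive
#     core of their excluded-volume / 12-10 potentials.
# For the 3-bead model the dummy HB bead is bonded 1.95 A from its base along
# the base->(away from backbone) direction, then bent within the base-pair
# plane toward its partner (the 180-degree angle term is soft) until the
# HB-site separation reaches its target.

.bdna_geometry <- function(variant, twist = 36, rise = 3.4, params = dna_parameters()) {
  phi <- twist * pi / 180
  r0_bb <- params$bonds$r0[params$bonds$class == "bb_bb"]
  r0_bs <- params$bonds$r0[params$bonds$class == "bb_base"]
  chord2 <- r0_bb^2 - rise^2
  if (chord2 <= 0) stop("rise exceeds the backbone bond length; no helix exists")
  R <- sqrt(chord2 / (4 * sin(phi / 2)^2))

  r0_dummy <- params$bonds$r0[params$bonds$class == "base_hb"]

  if (variant == "two_bead") {
    # complementary bases carry the 12-10 HB potential directly: place them
    # at the A-T equilibrium separation (bases end up nearly diametral, which
    # also parks the stacking distance at its own minimum), keeping diagonal
    # cross-strand base contacts outside the WCA core
    sep_target <- 6.05
    diag_min <- 5.7
    obj <- function(x) {
      r_s <- x[1]; phi1 <- x[2]; delta <- x[3]
      sep <- 2 * r_s * sin(phi1)
      bond <- sqrt(R^2 + r_s^2 - 2 * R * r_s * cos(delta - phi1))
      dm <- sqrt((2 * r_s * sin(phi1 - phi / 2))^2 + rise^2)
      dp <- sqrt((2 * r_s * sin(phi1 + phi / 2))^2 + rise^2)
      100 * (bond - r0_bs)^2 + (sep - sep_target)^2 +
        100 * max(0, diag_min - dm)^2 + 100 * max(0, diag_min - dp)^2 +
        10 * max(0, 0.2 - delta)^2 + 10 * max(0, delta - pi)^2
    }
  } else {
    # hydrogen bonding lives on the dummy beads, which stay collinear with
    # the backbone-base axis (zero angle strain); partner bases carry no
    # direct potential, so the target is the dummy-dummy separation, with
    # diagonal (non-partner) base and dummy contacts kept out of their
    # repulsive cores
    hb_sep_target <- 1.3 * params$hb3$sigma[1]
    obj <- function(x) {
      r_s <- x[1]; phi1 <- x[2]; delta <- x[3]
      bb1 <- R * c(cos(delta), sin(delta))
      ba1 <- r_s * c(cos(phi1), sin(phi1))
      u1 <- ba1 - bb1; u1 <- u1 / sqrt(sum(u1^2))
      hb1 <- ba1 + r0_dummy * u1
      hbsep <- 2 * hb1[2]  # partner is the y-mirror image
      bond <- sqrt(R^2 + r_s^2 - 2 * R * r_s * cos(delta - phi1))
      dm <- sqrt((2 * r_s * sin(phi1 - phi / 2))^2 + rise^2)
      dp <- sqrt((2 * r_s * sin(phi1 + phi / 2))^2 + rise^2)
      # dummy bead of bp k (strand 1) vs dummies of bp k+/-1 (strand 2)
      rot <- function(p, a) c(cos(a) * p[1] - sin(a) * p[2],
                              sin(a) * p[1] + cos(a) * p[2])
      hb2m <- c(hb1[1], -hb1[2])
      hdm <- sqrt(sum((rot(hb2m, -phi) - hb1)^2) + rise^2)
      hdp <- sqrt(sum((rot(hb2m, phi) - hb1)^2) + rise^2)
      100 * (bond - r0_bs)^2 + 10 * (hbsep - hb_sep_target)^2 +
        5 * max(0, 5.5 - dm)^2 + 5 * max(0, 5.5 - dp)^2 +
        50 * max(0, 1.9 - hdm)^2 + 50 * max(0, 1.9 - hdp)^2 +
        10 * max(0, 0.2 - delta)^2 + 10 * max(0, delta - pi)^2
    }
  }
  best <- NULL
  for (phi1_0 in c(40, 55, 65, 75, 90) * pi / 180) {
    for (rs0 in c(2.5, 3, 4, 5)) {
      fit <- stats::optim(c(rs0, phi1_0, phi1_0 + 1), obj, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  }
  list(R = R, r_s = best$par[1], phi1 = best$par[2], delta = best$par[3],
       twist = phi, rise = rise, residual = best$value)
}

#' Ideal B-form coordinates for a DNA duplex topology
#'
#' Generates canonical B-DNA starting coordinates (36 degree twist and 3.4 A
#' rise per base pair by default). Radial placements are solved so all bond
#' lengths match their equilibrium values within 0.2 A and complementary
#' hydrogen-bonding sites fall inside their engagement band
#' (between sigma_HB and 1.5 sigma_HB); the resulting configuration is
#' classified hybridized by [classify_hybridized()].
#'
#' @param topology A duplex `cg_topology` (2- or 3-bead).
#' @param twist Helical twist per base pair in degrees (default 36).
#' @param rise Axial rise per base pair in A (default 3.4).
#' @param box Orthorhombic box edge lengths in A (length 1 or 3); default is a
#'   cube comfortably larger than the duplex plus all interaction cutoffs.
#' @param params DNA parameter set (bond lengths used by the geometry solver).
#' @return Object of class `cg_coordinates`: list with `positions` (n x 3
#'   matrix, A) and `box` (length-3 vector, A).
#' @export
#' @examples
#' top <- build_dna_topology("ATGC", "two_bead", duplex = TRUE)
#' crd <- build_bdna_coordinates(top)
build_bdna_coordinates <- function(topology, twist = 36, rise = 3.4,
                                   box = NULL, params = dna_parameters()) {
  if (!inherits(topology, "cg_topology")) stop("need a cg_topology")
  if (!isTRUE(topology$duplex) || length(unique(topology$beads$chain)) != 2) {
    stop("B-DNA coordinates require a duplex topology")
  }
  variant <- topology$variant
  geo <- .bdna_geometry(variant, twist, rise, params)
  beads <- topology$beads
  n <- max(beads$residue[beads$chain == 1])
  pos <- matrix(NA_real_, nrow(beads), 3)

  r0_hb <- params$bonds$r0[params$bonds$class == "base_hb"]
  # bend dummies toward their partner only if the collinear placement leaves
  # them outside this separation (inside [sigma, 1.5 sigma] either way)
  hb_target <- 1.35 * params$hb3$sigma[1]

  cyl <- function(r, ang, z) c(r * cos(ang), r * sin(ang), z)
  for (k in 0:(n - 1)) {
    th <- k * geo$twist; z <- k * geo$rise
    res1 <- k + 1            # strand 1 residue at this base pair
    res2 <- n - k            # strand 2 residue (antiparallel)
    bb1 <- cyl(geo$R, th + geo$delta, z)
    bb2 <- cyl(geo$R, th - geo$delta, z)
    ba1 <- cyl(geo$r_s, th + geo$phi1, z)
    ba2 <- cyl(geo$r_s, th - geo$phi1, z)
    pos[.bead_at(beads, 1, res1, "dna_backbone"), ] <- bb1
    pos[.bead_at(beads, 2, res2, "dna_backbone"), ] <- bb2
    pos[.bead_at(beads, 1, res1, "dna_base"), ] <- ba1
    pos[.bead_at(beads, 2, res2, "dna_base"), ] <- ba2
    if (variant == "three_bead") {
      u1 <- (ba1 - bb1) / sqrt(sum((ba1 - bb1)^2))
      u2 <- (ba2 - bb2) / sqrt(sum((ba2 - bb2)^2))
      e1 <- (ba2 - ba1) / sqrt(sum((ba2 - ba1)^2))
      hbsep <- function(t) {
        w1 <- (1 - t) * u1 + t * e1; w1 <- w1 / sqrt(sum(w1^2))
        w2 <- (1 - t) * u2 - t * e1; w2 <- w2 / sqrt(sum(w2^2))
        h1 <- ba1 + r0_hb * w1; h2 <- ba2 + r0_hb * w2
        sqrt(sum((h1 - h2)^2))
      }
      t <- if (hbsep(0) <= hb_target) 0 else
        stats::uniroot(function(t) hbsep(t) - hb_target, c(0, 1), tol = 1e-10)$root
      w1 <- (1 - t) * u1 + t * e1; w1 <- w1 / sqrt(sum(w1^2))
      w2 <- (1 - t) * u2 - t * e1; w2 <- w2 / sqrt(sum(w2^2))
      pos[.bead_at(beads, 1, res1, "dna_hb"), ] <- ba1 + r0_hb * w1
      pos[.bead_at(beads, 2, res2, "dna_hb"), ] <- ba2 + r0_hb * w2
    }
  }
  if (is.null(box)) {
    span <- max(apply(pos, 2, function(x) diff(range(x))))
    box <- rep(max(150, ceiling(span + 100)), 3)
  }
  if (length(box) == 1) box <- rep(box, 3)
  structure(list(positions = pos, box = as.numeric(box)), class = "cg_coordinates")
}

#' Straight-chain starting coordinates for a protein topology
#'
#' Places the one-bead-per-residue chain on a line along x with the bonded
#' spacing (3.8 A); a generic, overlap-free starting point for relaxation.
#'
#' @param topology A protein `cg_topology`.
#' @param origin 3-vector, position of the first bead.
#' @param box Box edges (default cube of 2x chain length + 100 A).
#' @return A `cg_coordinates`.
#' @export
build_extended_protein_coordinates <- function(topology, origin = c(0, 0, 0),
                                               box = NULL) {
  n <- nrow(topology$beads)
  pos <- cbind(origin[1] + 3.8 * (seq_len(n) - 1), origin[2], origin[3])
  if (is.null(box)) box <- rep(max(150, ceiling(3.8 * n * 2 + 100)), 3)
  if (length(box) == 1) box <- rep(box, 3)
  structure(list(positions = pos, box = as.numeric(box)), class = "cg_coordinates")
}

#' Merge coordinate sets (for combined topologies)
#'
#' @param ... `cg_coordinates` objects, in the same order as the topologies
#'   given to [combine_topologies()].
#' @param box Box for the merged system (default: largest input box).
#' @return A `cg_coordinates`.
#' @export
combine_coordinates <- function(..., box = NULL) {
  sets <- list(...)
  pos <- do.call(rbind, lapply(sets, function(s) s$positions))
  if (is.null(box)) {
    box <- sets[[which.max(vapply(sets, function(s) max(s$box), numeric(1)))]]$box
  }
  if (length(box) == 1) box <- rep(box, 3)
  structure(list(positions = pos, box = as.numeric(box)), class = "cg_coordinates")
}

#' Rigidly translate coordinates
#' @param coords A `cg_coordinates`.
#' @param shift 3-vector in A.
#' @return Shifted `cg_coordinates`.
#' @export
translate_coordinates <- function(coords, shift) {
  coords$positions <- sweep(coords$positions, 2, shift, "+")
  coords
}
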