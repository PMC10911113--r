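#' Harmonic bond potential
#'
#' `U(r) = K (r - r0)^2` (no 1/2 prefactor, matching the convention under
#' which the model's printed force constants were calibrated).
#'
#' @param r Distance(s) in A (> 0).
#' @param class Bond class: `"bb_bb"`, `"bb_base"`, `"base_hb"` or
#'   `"protein"`.
#' @param params DNA parameter set.
#' @return Energy in kcal/mol.
#' @export
#' @examples
#' u_harmonic_bond(6.5, "bb_bb")  # 50 kcal/mol
u_harmonic_bond <- function(r, class = "bb_bb", params = dna_parameters()) {
  stopifnot(all(r > 0))
  row <- params$bonds[params$bonds$class == class, ]
  if (nrow(row) != 1) stop("unknown bond class: ", class)
  row$K * (r - row$r0)^2
}

#' Cosine-squared angle potential
#'
#' `U(theta) = K (cos theta - cos theta0)^2`.
#'
#' @param theta Angle(s) in degrees, in `[0, 180]`.
#' @param class Angle class: `"backbone"` (K = 40) or `"hb"` (K = 80); both
#'   have theta0 = 180 degrees.
#' @param params DNA parameter set.
#' @return Energy in kcal/mol.
#' @export
#' @examples
#' u_cosine_sq_angle(90, "backbone")  # 40 kcal/mol
u_cosine_sq_angle <- function(theta, class = "backbone", params = dna_parameters()) {
  stopifnot(all(theta >= 0), all(theta <= 180))
  row <- params$angles[params$angles$class == class, ]
  if (nrow(row) != 1) stop("unknown angle class: ", class)
  row$K * (cos(theta * pi / 180) - cos(row$theta0 * pi / 180))^2
}

#' 12-10 Lennard-Jones potential (stacking and hydrogen bonding)
#'
#' `U(r) = delta * (5 (sigma/r)^12 - 6 (sigma/r)^10)` for `r < cutoff`, else
#' 0. The minimum is exactly `-delta` at `r = sigma`.
#'
#' @param r Distance(s) in A (> 0).
#' @param sigma Equilibrium distance (A).
#' @param delta Well depth (kcal/mol).
#' @param cutoff Truncation distance (A).
#' @return Energy in kcal/mol.
#' @export
#' @examples
#' u_lj1210(3.6, 3.6, 9.7, 6.2)  # -9.7
u_lj1210 <- function(r, sigma, delta, cutoff = Inf) {
  stopifnot(all(r > 0), sigma > 0)
  s <- sigma / r
  ifelse(r < cutoff, delta * (5 * s^12 - 6 * s^10), 0)
}

#' Weeks-Chandler-Andersen excluded-volume potential
#'
#' Purely repulsive LJ truncated and shifted at its minimum:
#' `U(r) = 4 eps ((sigma/r)^12 - (sigma/r)^6) + eps` for
#' `r < 2^(1/6) sigma`, else 0.
#'
#' @param r Distance(s) in A (> 0).
#' @param eps Strength (kcal/mol, default 4).
#' @param sigma Diameter (A, default 5.5).
#' @return Energy in kcal/mol (nonnegative).
#' @export
#' @examples
#' u_wca(5.5)  # 4 kcal/mol
u_wca <- function(r, eps = 4, sigma = 5.5) {
  stopifnot(all(r > 0))
  s <- sigma / r
  ifelse(r < 2^(1 / 6) * sigma, 4 * eps * (s^12 - s^6) + eps, 0)
}

#' Debye-Hueckel screened Coulomb potential
#'
#' `U(r) = k_e q_i q_j exp(-r/kappa) / (eps_r r)` for `r < 3.5 kappa`, else 0,
#' with `k_e = 332.06` kcal A / (mol e^2).
#'
#' @param qi,qj Charges in e.
#' @param r Distance(s) in A (> 0).
#' @param ctx Electrostatics context (see [electrostatics_context()]).
#' @return Energy in kcal/mol.
#' @export
#' @examples
#' u_debye_huckel(-1, -1, 10, electrostatics_context(100))  # ~0.153
u_debye_huckel <- function(qi, qj, r, ctx = electrostatics_context()) {
  stopifnot(all(r > 0))
  ifelse(r < ctx$cutoff,
         cg_constants$coulomb * qi * qj * exp(-r / ctx$kappa) / (ctx$eps_r * r),
         0)
}

#' HPS (Ashbaugh-Hatch) pair potential
#'
#' Modified LJ with independently scaled attraction: with arithmetic-mixed
#' `sigma` and `lambda` and `U_LJ = 4 eps ((sigma/r)^12 - (sigma/r)^6)`,
#' returns `U_LJ + (1 - lambda) eps` for `r <= 2^(1/6) sigma` and
#' `lambda U_LJ` beyond. Pairs involving a dummy hydrogen-bonding bead and a
#' protein bead have `eps = 0` and return 0 at all distances.
#'
#' @param species_i,species_j Species labels: one-letter amino-acid codes,
#'   `"BB"` (DNA backbone), `"dA"`/`"dT"`/`"dC"`/`"dG"` (DNA bases), or
#'   `"hb_a"` ... (dummy hydrogen-bonding beads).
#' @param r Distance(s) in A.
#' @param params HPS parameter set.
#' @return Energy in kcal/mol.
#' @export
#' @examples
#' u_hps_pair("K", "BB", 6)
u_hps_pair <- function(species_i, species_j, r, params = hps_parameters()) {
  stopifnot(all(r > 0))
  tab <- params$species
  ri <- tab[tab$species == species_i, ]
  rj <- tab[tab$species == species_j, ]
  if (nrow(ri) != 1) stop("no HPS entry for species: ", species_i)
  if (nrow(rj) != 1) stop("no HPS entry for species: ", species_j)
  if ((ri$kind == "dna_hb" && rj$kind == "protein") ||
      (rj$kind == "dna_hb" && ri$kind == "protein")) {
    return(rep(0, length(r)))
  }
  sigma <- (ri$sigma + rj$sigma) / 2
  lambda <- (ri$lambda + rj$lambda) / 2
  s <- sigma / r
  ulj <- 4 * params$eps * (s^12 - s^6)
  ifelse(r <= 2^(1 / 6) * sigma, ulj + (1 - lambda) * params$eps, lambda * ulj)
}

# -- Interaction system --------------------------------------------------------

.pair_param_lookup <- function(pairs, table, cutoff) {
  m <- match(pairs$pair, table$pair)
  if (anyNA(m)) stop("missing 12-10 parameters for pair(s): ",
                     paste(unique(pairs$pair[is.na(m)]), collapse = ", "))
  list(i = pairs$i - 1L, j = pairs$j - 1L,
       sigma = table$sigma[m], delta = table$delta[m],
       cutoff = rep(cutoff, nrow(pairs)))
}

.empty_pairlist <- function() list(i = integer(), j = integer(),
                                   sigma = numeric(), delta = numeric(),
                                   cutoff = numeric())

#' Compile a topology into an interaction system
#'
#' Resolves every bonded term and nonbonded pair of a topology against the
#' parameter sets, producing the flat interaction lists consumed by the energy
#' kernel and the integrator. Users normally call [total_energy_forces()] or
#' [run_langevin()], which do this internally.
#'
#' @param topology A `cg_topology`.
#' @param dna_params DNA parameter set.
#' @param hps_params HPS parameter set (used when protein beads are present,
#'   or for any protein-DNA cross terms).
#' @param elec Electrostatics context.
#' @return A list of interaction tables (class `cg_system`).
#' @export
interaction_system <- function(topology,
                               dna_params = dna_parameters(),
                               hps_params = hps_parameters(),
                               elec = electrostatics_context()) {
  beads <- topology$beads
  n <- nrow(beads)
  bond_par <- dna_params$bonds
  bm <- match(topology$bonds$class, bond_par$class)
  bonds <- list(i = topology$bonds$i - 1L, j = topology$bonds$j - 1L,
                K = bond_par$K[bm], r0 = bond_par$r0[bm])
  ang_par <- dna_params$angles
  am <- match(topology$angles$class, ang_par$class)
  angles <- list(i = topology$angles$i - 1L, j = topology$angles$j - 1L,
                 k = topology$angles$k - 1L, K = ang_par$K[am],
                 cos0 = cos(ang_par$theta0[am] * pi / 180))

  stack <- if (nrow(topology$pairs$stacking)) {
    .pair_param_lookup(topology$pairs$stacking, dna_params$stacking, dna_params$r_stack)
  } else .empty_pairlist()

  hb <- if (nrow(topology$pairs$hb)) {
    if (topology$variant == "three_bead") {
      .pair_param_lookup(topology$pairs$hb, dna_params$hb3, dna_params$r_hb3)
    } else {
      .pair_param_lookup(topology$pairs$hb, dna_params$hb2, dna_params$r_hb2)
    }
  } else .empty_pairlist()

  # WCA: the excluded-volume class; optionally every other nonbonded DNA pair
  # that involves a backbone or base bead (wca_all_pairs switch)
  wi <- topology$pairs$excluded$i; wj <- topology$pairs$excluded$j
  if (isTRUE(dna_params$wca_all_pairs)) {
    dna_idx <- which(beads$kind %in% c("dna_backbone", "dna_base"))
    if (length(dna_idx) >= 2) {
      cmb <- utils::combn(dna_idx, 2)
      key <- paste(cmb[1, ], cmb[2, ])
      classified <- c(paste(topology$pairs$stacking$i, topology$pairs$stacking$j),
                      paste(topology$pairs$hb$i, topology$pairs$hb$j),
                      paste(topology$pairs$excluded$i, topology$pairs$excluded$j),
                      paste(pmin(topology$bonds$i, topology$bonds$j),
                            pmax(topology$bonds$i, topology$bonds$j)))
      extra <- !key %in% classified
      wi <- c(wi, cmb[1, extra]); wj <- c(wj, cmb[2, extra])
    }
  }
  wca <- list(i = as.integer(wi) - 1L, j = as.integer(wj) - 1L,
              sigma = rep(dna_params$sigma_ex, length(wi)),
              eps = dna_params$eps_ex)

  # Debye-Hueckel between all charged bead pairs except directly bonded ones
  charged <- which(beads$charge != 0)
  di <- integer(); dj <- integer()
  if (length(charged) >= 2) {
    cmb <- utils::combn(charged, 2)
    bonded_key <- paste(pmin(topology$bonds$i, topology$bonds$j),
                        pmax(topology$bonds$i, topology$bonds$j))
    keep <- !paste(cmb[1, ], cmb[2, ]) %in% bonded_key
    di <- cmb[1, keep]; dj <- cmb[2, keep]
  }
  dh <- list(i = as.integer(di) - 1L, j = as.integer(dj) - 1L,
             prefactor = cg_constants$coulomb * beads$charge[di] * beads$charge[dj] / elec$eps_r,
             kappa = elec$kappa, cutoff = elec$cutoff)

  # HPS: protein-protein and protein-DNA (backbone/base) pairs, excluding
  # direct bonds; dummy HB beads do not interact with protein (eps = 0 -> omit)
  prot <- which(beads$kind == "protein")
  hi <- integer(); hj <- integer(); hsig <- numeric(); hlam <- numeric()
  if (length(prot)) {
    tab <- hps_params$species
    hps_key <- ifelse(beads$kind == "dna_base", paste0("d", beads$species),
                      beads$species)
    sp_m <- match(hps_key, tab$species)
    partner <- which(beads$kind %in% c("protein", "dna_backbone", "dna_base"))
    pi_ <- rep(prot, each = length(partner))
    pj_ <- rep(partner, times = length(prot))
    ii <- pmin(pi_, pj_); jj <- pmax(pi_, pj_)
    keyed <- !duplicated(paste(ii, jj)) & ii != jj
    ii <- ii[keyed]; jj <- jj[keyed]
    bonded_key <- paste(pmin(topology$bonds$i, topology$bonds$j),
                        pmax(topology$bonds$i, topology$bonds$j))
    keep <- !paste(ii, jj) %in% bonded_key
    ii <- ii[keep]; jj <- jj[keep]
    hi <- ii; hj <- jj
    hsig <- (tab$sigma[sp_m[ii]] + tab$sigma[sp_m[jj]]) / 2
    hlam <- (tab$lambda[sp_m[ii]] + tab$lambda[sp_m[jj]]) / 2
  }
  hps <- list(i = as.integer(hi) - 1L, j = as.integer(hj) - 1L,
              sigma = hsig, lambda = hlam, eps = hps_params$eps, cut_factor = 3.0)

  sys <- list(n = n, bonds = bonds, angles = angles, stacking = stack, hb = hb,
              wca = wca, dh = dh, hps = hps, masses = beads$mass)
  class(sys) <- "cg_system"
  sys
}

#' Total potential energy and forces
#'
#' Evaluates every term of the force field for a configuration and returns the
#' per-term decomposition together with the analytic forces (the exact
#' negative gradient of the returned total).
#'
#' @param topology A `cg_topology`.
#' @param coords A `cg_coordinates` (or bare n x 3 matrix; then `box` must be
#'   given).
#' @param dna_params,hps_params,elec Parameter sets.
#' @param box Orthorhombic box edges (A); taken from `coords` if absent.
#' @param pbc Apply the periodic minimum-image convention? Default `TRUE`.
#' @param system Optional precompiled `cg_system` (skips recompilation).
#' @return An energy report: list with `terms` (named vector: bond, angle,
#'   stacking, hb, excluded, electrostatics, hps), `total` (their sum) and
#'   `forces` (n x 3 matrix, kcal/(mol A)).
#' @export
total_energy_forces <- function(topology, coords,
                                dna_params = dna_parameters(),
                                hps_params = hps_parameters(),
                                elec = electrostatics_context(),
                                box = NULL, pbc = TRUE, system = NULL) {
  pos <- if (inherits(coords, "cg_coordinates")) coords$positions else coords
  if (is.null(box)) {
    if (inherits(coords, "cg_coordinates")) box <- coords$box
    else stop("box required when coords is a bare matrix")
  }
  if (length(box) == 1) box <- rep(box, 3)
  if (is.null(system)) {
    system <- interaction_system(topology, dna_params, hps_params, elec)
  }
  out <- .cg_energy_forces(pos, unclass(system), as.numeric(box), isTRUE(pbc))
  structure(list(terms = out$terms, total = out$total, forces = out$forces),
            class = "cg_energy_report")
}
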