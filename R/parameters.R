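#' DNA force-field parameter set
#'
#' Returns the complete parameter set of the coarse-grained DNA model: bonded
#' constants, the 12-10 stacking and hydrogen-bonding tables, the
#' Weeks-Chandler-Andersen excluded-volume settings, and the global scaling
#' factors for stacking and hydrogen-bonding strengths.
#'
#' The packaged tables already include the calibrated scaling factors
#' `Delta_stack = 2.1` and `Delta_HB = 0.95`; passing different values of
#' `delta_stack` / `delta_hb` rescales the energies *relative* to those
#' defaults (so the defaults never apply the calibration twice).
#'
#' @param delta_stack Global stacking strength scale (default 2.1, the
#'   calibrated value baked into the stacking table).
#' @param delta_hb Global hydrogen-bonding strength scale (default 0.95).
#' @param wca_all_pairs Logical; if `TRUE`, apply WCA excluded volume to every
#'   nonbonded DNA pair (backbone included) rather than only to the base-pair
#'   cases of the model definition. Default `FALSE` (the literal rule).
#' @param overrides Optional named list of constants to override (any field of
#'   the returned object), e.g. `list(eps_ex = 2)`.
#'
#' @return An object of class `cg_dna_parameters`: a list with fields
#'   `bonds` (data frame: class, K, r0), `angles` (data frame: class, K,
#'   theta0), `stacking` (data frame: pair, sigma, delta), `r_stack`,
#'   `hb2` / `hb3` (2-bead and 3-bead hydrogen-bonding tables), `r_hb2`,
#'   `r_hb3`, `eps_ex`, `sigma_ex`, `delta_stack`, `delta_hb`,
#'   `wca_all_pairs`.
#' @export
#' @examples
#' p <- dna_parameters()
#' subset(p$stacking, pair == "A-A")$delta  # 9.7 kcal/mol
dna_parameters <- function(delta_stack = 2.1, delta_hb = 0.95,
                           wca_all_pairs = FALSE, overrides = NULL) {
  stack <- data.frame(
    pair  = names(STACK_DELTA),
    sigma = 3.6,
    delta = unname(STACK_DELTA) * (delta_stack / 2.1),
    stringsAsFactors = FALSE
  )
  hb2 <- data.frame(
    pair  = c("A-T", "C-G"),
    sigma = c(6.0, 5.5),
    delta = c(2.7, 3.3) * (delta_hb / 0.95),
    stringsAsFactors = FALSE
  )
  hb3 <- data.frame(
    pair  = c("a-t", "c-g"),
    sigma = c(1.65, 1.65),
    delta = c(8.5, 10.4) * (delta_hb / 0.95),
    stringsAsFactors = FALSE
  )
  p <- list(
    bonds = data.frame(
      class = c("bb_bb", "bb_base", "base_hb", "protein"),
      K     = c(50, 50, 50, 10),
      r0    = c(5.5, 5.75, 1.95, 3.8),
      stringsAsFactors = FALSE
    ),
    angles = data.frame(
      class  = c("backbone", "hb"),
      K      = c(40, 80),
      theta0 = c(180, 180),
      stringsAsFactors = FALSE
    ),
    stacking    = stack,
    r_stack     = 6.2,
    hb2         = hb2,
    r_hb2       = 9.5,
    hb3         = hb3,
    r_hb3       = 3.3,   # = 2 * sigma_HB of the dummy-bead pairs
    eps_ex      = 4.0,
    sigma_ex    = 5.5,
    delta_stack = delta_stack,
    delta_hb    = delta_hb,
    wca_all_pairs = isTRUE(wca_all_pairs)
  )
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides), !is.null(names(overrides)))
    for (nm in names(overrides)) {
      if (!nm %in% names(p)) stop("unknown DNA parameter override: ", nm)
      p[[nm]] <- overrides[[nm]]
    }
  }
  class(p) <- "cg_dna_parameters"
  p
}

#' HPS parameter set for protein beads and protein-DNA cross-interactions
#'
#' Per-species hydropathy (lambda), vdW diameter (sigma, A) and charge for the
#' one-bead-per-residue protein model and for DNA beads in the hydropathy-scale
#' (HPS) framework. Mixing is arithmetic for both lambda and sigma, and the
#' global interaction strength is `eps = 0.2` kcal/mol. Dummy
#' hydrogen-bonding beads of the 3-bead DNA model do not interact with protein
#' beads (`eps = 0`).
#'
#' @param scale Hydropathy scale, `"urry"` (default) or `"kr"`.
#' @param lambda_scale Multiplier applied to every lambda (e.g. 0 makes all
#'   short-range HPS interactions purely repulsive).
#' @param eps Interaction strength in kcal/mol (default 0.2).
#' @return An object of class `cg_hps_parameters` with fields `species`
#'   (data frame: species, lambda, sigma, charge, mass), `eps`, `scale`.
#'   Species keys: one-letter amino-acid codes, `"BB"` for the DNA backbone,
#'   `"dA"`/`"dT"`/`"dC"`/`"dG"` for DNA bases (distinct from the Ala/Thr/...
#'   codes) and `"hb_a"` ... for dummy hydrogen-bonding beads.
#' @export
#' @examples
#' hps_parameters()$eps  # 0.2
hps_parameters <- function(scale = c("urry", "kr"), lambda_scale = 1, eps = 0.2) {
  scale <- match.arg(scale)
  lam <- if (scale == "urry") AA_LAMBDA_URRY else AA_LAMBDA_KR
  aa <- data.frame(
    species = AA_CODES, kind = "protein",
    lambda = unname(lam[AA_CODES]) * lambda_scale,
    sigma  = unname(AA_SIGMA[AA_CODES]),
    charge = unname(AA_CHARGE[AA_CODES]),
    mass   = unname(AA_MASS[AA_CODES]),
    stringsAsFactors = FALSE
  )
  # DNA beads participate in protein-DNA HPS interactions; their vdW diameter
  # is taken as the model's excluded-volume diameter (5.5 A).
  dna <- data.frame(
    species = c("BB", paste0("d", DNA_BASES)),
    kind    = c("dna_backbone", rep("dna_base", 4)),
    lambda  = unname(DNA_HPS_LAMBDA[c("BB", DNA_BASES)]) * lambda_scale,
    sigma   = 5.5,
    charge  = c(-1, 0, 0, 0, 0),
    mass    = unname(DNA_MASSES[c("BB", DNA_BASES)]),
    stringsAsFactors = FALSE
  )
  # dummy HB beads: no HPS interaction with protein (eps 0 handled at system
  # build); lambda/sigma retained only for completeness
  hb <- data.frame(
    species = paste0("hb_", c("a", "t", "c", "g")),
    kind    = "dna_hb",
    lambda  = 0, sigma = 1.65, charge = 0,
    mass    = 0.5 * unname(DNA_MASSES[DNA_BASES]),
    stringsAsFactors = FALSE
  )
  p <- list(species = rbind(aa, dna, hb), eps = eps, scale = scale)
  class(p) <- "cg_hps_parameters"
  p
}

#' Electrostatics context (Debye-Hueckel screening)
#'
#' Screened-Coulomb settings: relative permittivity, Debye length and cutoff.
#' The Debye length can be given explicitly or derived from the salt
#' concentration; the two calibrated conditions are 10 A at 100 mM and 8.8 A
#' at 120 mM monovalent salt.
#'
#' @param salt_mM Monovalent salt concentration in mM (100 or 120 map to the
#'   calibrated Debye lengths; other values use kappa = 10 * sqrt(100/salt)).
#' @param kappa Debye screening length in A (overrides `salt_mM`).
#' @param eps_r Relative dielectric constant (default 80).
#' @return Object of class `cg_electrostatics` with fields `eps_r`, `kappa`,
#'   `cutoff` (= 3.5 kappa) and `salt_mM`.
#' @export
#' @examples
#' electrostatics_context(salt_mM = 120)$kappa  # 8.8
electrostatics_context <- function(salt_mM = 100, kappa = NULL, eps_r = 80) {
  if (is.null(kappa)) {
    kappa <- if (isTRUE(all.equal(salt_mM, 100))) 10 else
             if (isTRUE(all.equal(salt_mM, 120))) 8.8 else
             10 * sqrt(100 / salt_mM)
  } else {
    salt_mM <- NA_real_
  }
  stopifnot(kappa > 0, eps_r > 0)
  ctx <- list(eps_r = eps_r, kappa = kappa, cutoff = 3.5 * kappa, salt_mM = salt_mM)
  class(ctx) <- "cg_electrostatics"
  ctx
}
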