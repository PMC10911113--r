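# Unit system used throughout the package:
#   length A, energy kcal/mol, mass amu, charge e, time fs (ps accepted where noted),
#   temperature K.

#' Physical constants used by the toolkit
#'
#' Boltzmann constant in kcal/(mol K), Coulomb constant in kcal A/(mol e^2),
#' Avogadro's number, and the conversion from kcal/(mol A amu) to A/fs^2
#' used by the integrator.
#'
#' @format A named list.
#' @export
cg_constants <- list(
  kB       = 0.0019872041,   # kcal/(mol K)
  coulomb  = 332.06,         # kcal A/(mol e^2); k_e / eps_0 factor folded in
  avogadro = 6.02214076e23,  # 1/mol
  # (kcal/mol/A) / amu -> A/fs^2
  acc_conv = 4.184e-4,
  A3_to_L  = 1e-27
)

# -- DNA bead bookkeeping ------------------------------------------------------

DNA_BASES <- c("A", "T", "C", "G")

DNA_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

# masses in amu; backbone is the sugar-phosphate group
DNA_MASSES <- c(BB = 178.08, A = 134.1, T = 125.1, C = 110.1, G = 150.1)

# hydropathy of DNA beads in the HPS framework (dimensionless)
DNA_HPS_LAMBDA <- c(BB = 0.38, A = 0.40, T = 0.54, C = 0.59, G = 0.35)

# stacking strengths delta_stack (kcal/mol) for the 10 unordered base pairs,
# already scaled by the calibrated Delta_stack = 2.1
STACK_DELTA <- c(
  "A-A" = 9.7, "A-T" = 8.6, "A-C" = 7.8, "A-G" = 10.3,
  "T-T" = 7.7, "T-C" = 6.9, "T-G" = 9.2,
  "C-C" = 6.2, "C-G" = 8.3, "G-G" = 11.0
)

# -- Amino-acid tables (one-letter codes) --------------------------------------
# vdW diameters (A) and hydropathies for the two selectable HPS scales; residue
# masses in amu; formal charges in e.

AA_CODES <- c("A","R","N","D","C","Q","E","G","H","I","K","L","M","F","P","S","T","W","Y","V")

AA_MASS <- c(
  A = 71.08,  R = 156.19, N = 114.10, D = 115.09, C = 103.14,
  Q = 128.13, E = 129.12, G = 57.05,  H = 137.14, I = 113.16,
  K = 128.17, L = 113.16, M = 131.19, F = 147.18, P = 97.12,
  S = 87.08,  T = 101.10, W = 186.21, Y = 163.18, V = 99.07
)

AA_SIGMA <- c(
  A = 5.04, R = 6.56, N = 5.68, D = 5.58, C = 5.48,
  Q = 6.02, E = 5.92, G = 4.50, H = 6.08, I = 6.18,
  K = 6.36, L = 6.18, M = 6.18, F = 6.36, P = 5.56,
  S = 5.18, T = 5.62, W = 6.78, Y = 6.46, V = 5.86
)

AA_CHARGE <- c(
  A = 0, R = 1, N = 0, D = -1, C = 0,
  Q = 0, E = -1, G = 0, H = 0, I = 0,
  K = 1, L = 0, M = 0, F = 0, P = 0,
  S = 0, T = 0, W = 0, Y = 0, V = 0
)

# Urry-derived hydropathy scale (HPS-Urry)
AA_LAMBDA_URRY <- c(
  A = 0.602942, R = 0.558824, N = 0.588236, D = 0.294119, C = 0.647060,
  Q = 0.558824, E = 0.000000, G = 0.573530, H = 0.764707, I = 0.705883,
  K = 0.382354, L = 0.720589, M = 0.676471, F = 0.823530, P = 0.758824,
  S = 0.588236, T = 0.588236, W = 1.000000, Y = 0.897059, V = 0.664707
)

# Kapcha-Rossky-derived hydropathy scale (HPS-KR)
AA_LAMBDA_KR <- c(
  A = 0.730, R = 0.000, N = 0.432, D = 0.378, C = 0.595,
  Q = 0.514, E = 0.459, G = 0.649, H = 0.514, I = 0.973,
  K = 0.514, L = 0.973, M = 0.838, F = 1.000, P = 1.000,
  S = 0.595, T = 0.676, W = 0.946, Y = 0.865, V = 0.892
)
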