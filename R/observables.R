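# Helpers shared by the structural observables -------------------------------

.hb_site_kind <- function(variant) if (variant == "three_bead") "dna_hb" else "dna_base"

.site_sigma_table <- function(topology, dna_params) {
  if (topology$variant == "three_bead") {
    setNames(dna_params$hb3$sigma, dna_params$hb3$pair)
  } else {
    setNames(dna_params$hb2$sigma, dna_params$hb2$pair)
  }
}

#' Classify the hybridization state of a duplex configuration
#'
#' A hydrogen-bonding site is engaged if any complementary site on the other
#' strand lies within `1.5 sigma_HB` of it (sigma per pair type: base beads
#' for the 2-bead model, dummy HB beads for the 3-bead model). A strand is
#' hybridized if at least half of its sites are engaged; the duplex is
#' reported hybridized when both strands are.
#'
#' @param coords A `cg_coordinates` or bare n x 3 position matrix.
#' @param topology A duplex `cg_topology`.
#' @param dna_params DNA parameter set (for sigma_HB).
#' @param box Optional box for minimum-image distances (taken from `coords`
#'   when it is a `cg_coordinates`; `NULL` disables imaging).
#' @param factor Engagement distance in units of sigma_HB (default 1.5).
#' @return List with `engaged` (per-strand counts), `n_sites`,
#'   `strand_hybridized` (logical, per strand) and `hybridized` (both).
#' @export
classify_hybridized <- function(coords, topology, dna_params = dna_parameters(),
                                box = NULL, factor = 1.5) {
  if (!isTRUE(topology$duplex)) stop("hybridization requires a duplex topology")
  pos <- if (inherits(coords, "cg_coordinates")) coords$positions else coords
  if (is.null(box) && inherits(coords, "cg_coordinates")) box <- coords$box
  beads <- topology$beads
  kind <- .hb_site_kind(topology$variant)
  s1 <- beads[beads$chain == 1 & beads$kind == kind, ]
  s2 <- beads[beads$chain == 2 & beads$kind == kind, ]
  base_of <- function(sp) toupper(sub("hb_", "", sp))
  b1 <- base_of(s1$species); b2 <- base_of(s2$species)
  sig <- .site_sigma_table(topology, dna_params)
  pair_label <- function(a, b) {
    swap <- match(a, DNA_BASES) > match(b, DNA_BASES)
    lab <- paste(ifelse(swap, b, a), ifelse(swap, a, b), sep = "-")
    if (topology$variant == "three_bead") tolower(lab) else lab
  }
  d2 <- matrix(0, nrow(s1), nrow(s2))
  for (c in 1:3) {
    dc <- outer(pos[s1$index, c], pos[s2$index, c], "-")
    if (!is.null(box)) dc <- dc - box[c] * round(dc / box[c])
    d2 <- d2 + dc^2
  }
  comp <- outer(b1, b2, function(a, b) unname(DNA_COMPLEMENT[a]) == b)
  lab <- outer(b1, b2, pair_label)
  thr2 <- matrix((factor * unname(sig[lab]))^2, nrow(s1), nrow(s2))
  hit <- comp & d2 < thr2
  engaged <- c(sum(rowSums(hit) > 0), sum(colSums(hit) > 0))
  n_sites <- c(nrow(s1), nrow(s2))
  strand_hyb <- engaged >= ceiling(n_sites / 2)
  list(engaged = engaged, n_sites = n_sites,
       strand_hybridized = strand_hyb, hybridized = all(strand_hyb))
}

# block-averaged standard error (>= 3 blocks)
.block_se <- function(x, n_blocks = 5) {
  n_blocks <- max(3, min(n_blocks, length(x)))
  if (length(x) < 3) return(NA_real_)
  blk <- split(x, cut(seq_along(x), n_blocks, labels = FALSE))
  mu <- vapply(blk, mean, numeric(1))
  stats::sd(mu) / sqrt(length(mu))
}

.interp_crossing <- function(temps, frac, level = 0.5) {
  idx <- which(frac[-1] >= level & frac[-length(frac)] < level)
  if (!length(idx)) {
    if (all(frac >= level)) return(temps[1])
    if (all(frac < level)) return(NA_real_)
    idx <- which(diff(sign(frac - level)) != 0)
    if (!length(idx)) return(NA_real_)
  }
  i <- idx[1]
  t0 <- temps[i]; t1 <- temps[i + 1]; f0 <- frac[i]; f1 <- frac[i + 1]
  if (f1 == f0) (t0 + t1) / 2 else t0 + (level - f0) * (t1 - t0) / (f1 - f0)
}

#' Melting curve and heat-capacity analysis of per-temperature ensembles
#'
#' Computes the melted fraction per temperature with a fraction-based melting
#' temperature (monotone linear interpolation at 0.5), and the heat capacity
#' `Cv(T) = (<E^2> - <E>^2) / (kB T^2)` with a calorimetric Tm at the maximum
#' of a Gaussian-smoothed Cv curve. Uncertainties come from block averaging.
#'
#' @param temperatures Temperatures (K), length >= 2.
#' @param melted List (one element per temperature) of logical per-sample
#'   melted flags.
#' @param energies List of per-sample potential energies (kcal/mol).
#' @param n_blocks Blocks for uncertainty estimates (>= 3).
#' @return List with `curve` (data frame: temperature, fraction_melted, se),
#'   `heat_capacity` (data frame: temperature, cv, cv_smooth), `tm_fraction`,
#'   `tm_fraction_se`, `tm_cv`, `tm_cv_se`.
#' @export
melting_analysis <- function(temperatures, melted, energies, n_blocks = 5) {
  m <- length(temperatures)
  if (m < 2) stop("need at least 2 temperatures")
  stopifnot(length(melted) == m, length(energies) == m)
  kB <- cg_constants$kB
  frac <- vapply(melted, function(x) mean(as.numeric(x)), numeric(1))
  se <- vapply(melted, function(x) .block_se(as.numeric(x), n_blocks), numeric(1))
  cv <- vapply(seq_len(m), function(i) {
    e <- energies[[i]]
    if (length(e) < 2) return(0)
    mean((e - mean(e))^2) / (kB * temperatures[i]^2)
  }, numeric(1))
  # Gaussian kernel smoothing with bandwidth = ladder spacing
  bw <- if (m > 1) mean(diff(temperatures)) else 1
  smooth_at <- function(t0) {
    w <- exp(-0.5 * ((temperatures - t0) / bw)^2)
    sum(w * cv) / sum(w)
  }
  cv_smooth <- vapply(temperatures, smooth_at, numeric(1))
  tgrid <- seq(min(temperatures), max(temperatures), length.out = 512)
  tm_cv <- tgrid[which.max(vapply(tgrid, smooth_at, numeric(1)))]
  tm_frac <- .interp_crossing(temperatures, frac)

  # block jackknife for Tm uncertainties
  nb <- max(3, n_blocks)
  blocks_ok <- all(vapply(melted, length, integer(1)) >= nb)
  tm_f_b <- tm_c_b <- rep(NA_real_, nb)
  if (blocks_ok) {
    for (b in seq_len(nb)) {
      fb <- vapply(seq_len(m), function(i) {
        x <- as.numeric(melted[[i]])
        mean(x[cut(seq_along(x), nb, labels = FALSE) == b])
      }, numeric(1))
      tm_f_b[b] <- .interp_crossing(temperatures, fb)
      cvb <- vapply(seq_len(m), function(i) {
        e <- energies[[i]]
        e <- e[cut(seq_along(e), nb, labels = FALSE) == b]
        if (length(e) < 2) return(0)
        mean((e - mean(e))^2) / (kB * temperatures[i]^2)
      }, numeric(1))
      sm <- function(t0) { w <- exp(-0.5 * ((temperatures - t0) / bw)^2); sum(w * cvb) / sum(w) }
      tm_c_b[b] <- tgrid[which.max(vapply(tgrid, sm, numeric(1)))]
    }
  }
  list(
    curve = data.frame(temperature = temperatures, fraction_melted = frac, se = se),
    heat_capacity = data.frame(temperature = temperatures, cv = cv,
                               cv_smooth = cv_smooth),
    tm_fraction = tm_frac,
    tm_fraction_se = if (all(is.na(tm_f_b))) NA_real_ else
      stats::sd(tm_f_b, na.rm = TRUE) / sqrt(sum(!is.na(tm_f_b))),
    tm_cv = tm_cv,
    tm_cv_se = if (all(is.na(tm_c_b))) NA_real_ else
      stats::sd(tm_c_b, na.rm = TRUE) / sqrt(sum(!is.na(tm_c_b)))
  )
}

#' Melting observables from a replica-exchange run
#'
#' Applies [classify_hybridized()] to every stored frame of a [run_remd()]
#' result and feeds the per-temperature melted flags and potential energies to
#' [melting_analysis()]. A configuration counts as melted when either strand
#' has fewer than half of its sites engaged.
#'
#' @param remd A `cg_remd` object.
#' @param topology The duplex topology that was simulated.
#' @param box Box edges used in the run (for minimum-image distances).
#' @param dna_params DNA parameter set.
#' @param ... Passed to [melting_analysis()].
#' @return See [melting_analysis()].
#' @export
remd_melting <- function(remd, topology, box = NULL,
                         dna_params = dna_parameters(), ...) {
  melted <- lapply(remd$samples, function(sm) {
    k <- dim(sm$frames)[3]
    vapply(seq_len(k), function(t) {
      !classify_hybridized(sm$frames[, , t], topology, dna_params, box = box)$hybridized
    }, logical(1))
  })
  energies <- lapply(remd$samples, function(sm) sm$energies)
  melting_analysis(remd$temperatures, melted, energies, ...)
}

# -- Helical structure ---------------------------------------------------------

.frame_list <- function(frames) {
  if (is.array(frames) && length(dim(frames)) == 3) {
    lapply(seq_len(dim(frames)[3]), function(t) frames[, , t])
  } else if (is.matrix(frames)) {
    list(frames)
  } else if (inherits(frames, "cg_trajectory")) {
    .frame_list(frames$frames)
  } else if (inherits(frames, "cg_coordinates")) {
    list(frames$positions)
  } else stop("unsupported frames object")
}

# canonical base-pair intactness for structural statistics: the canonical
# Watson-Crick partner site sits inside the bound well (factor x sigma_HB,
# tighter than the melting engagement criterion)
.intact_bps <- function(pos, topology, dna_params, factor = 1.35) {
  beads <- topology$beads
  n <- max(beads$residue[beads$chain == 1])
  kind <- .hb_site_kind(topology$variant)
  s1 <- .bead_at(beads, 1, 1:n, kind)
  s2 <- .bead_at(beads, 2, n:1, kind)  # canonical partner of residue i
  b1 <- toupper(sub("hb_", "", beads$species[s1]))
  sig <- .site_sigma_table(topology, dna_params)
  lab <- ifelse(b1 %in% c("A", "T"), "A-T", "C-G")
  if (topology$variant == "three_bead") lab <- tolower(lab)
  d <- sqrt(rowSums((pos[s1, , drop = FALSE] - pos[s2, , drop = FALSE])^2))
  d < factor * unname(sig[lab])
}

# tetrad-centroid helical axis machinery; returns per-frame quantities
.helical_frame <- function(pos, beads, n, pairing, exclude = 3) {
  bb1 <- .bead_at(beads, 1, 1:n, "dna_backbone")
  bb2 <- .bead_at(beads, 2, 1:n, "dna_backbone")
  ba1 <- .bead_at(beads, 1, 1:n, "dna_base")
  ba2 <- .bead_at(beads, 2, 1:n, "dna_base")
  p <- pairing$res2  # partner residue on strand 2 for strand-1 residue i
  # base-pair centres
  centre <- (pos[ba1, , drop = FALSE] + pos[ba2[p], , drop = FALSE]) / 2
  # tetrad anchors for residues i = (exclude+1) .. (n - exclude - 3)
  is_ <- (exclude + 1):(n - exclude - 3)
  anchors <- t(vapply(is_, function(i) {
    idx <- c(bb1[i], ba1[i], bb1[i + 3], ba1[i + 3],
             bb2[p[i]], ba2[p[i]], bb2[p[i + 3]], ba2[p[i + 3]])
    colMeans(pos[idx, , drop = FALSE])
  }, numeric(3)))
  M <- nrow(anchors)
  lag <- min(M - 1, 10)
  u_at <- function(ai) {  # local axis direction for anchor index ai
    lo <- max(1, min(ai - floor(lag / 2), M - lag))
    hi <- lo + lag
    u <- anchors[hi, ] - anchors[lo, ]
    u / sqrt(sum(u^2))
  }
  us <- t(vapply(seq_len(M), u_at, numeric(3)))
  # map base-pair index j to nearest anchor row
  anchor_for <- function(j) {
    ai <- round(j - 1.5) - exclude  # anchor row whose tetrad centre is nearest
    min(max(ai, 1), M)
  }
  list(pos = pos, centre = centre, anchors = anchors, us = us,
       anchor_for = anchor_for, bb1 = bb1, bb2 = bb2, ba1 = ba1, ba2 = ba2, p = p)
}

#' Helical structural parameters of a duplex trajectory
#'
#' Approximates the helical axis from centroids of nucleotide tetrads
#' (residues i and i+3 on each strand, at least `exclude_terminal` bases from
#' the termini) and derives: base rise (mean axial spacing of consecutive
#' base-pair projections), base pairs per helical turn (360 degrees over the
#' mean twist increment about the axis), and the duplex width. Width is
#' reported as twice the mean radial distance of backbone beads from the
#' axis plus twice `width_padding`; the default padding, half the
#' excluded-volume diameter sigma_ex (i.e. one bead radius), measures the
#' duplex surface-to-surface across the steric envelope of the backbone
#' beads. Setting `width_padding = 0` gives bare bead-centre distances.
#'
#' Frames whose duplex is not hybridized are excluded (and counted), and
#' within hybridized frames only intact steps enter the statistics: a
#' base-pair step contributes only if the canonical Watson-Crick partner
#' sites of both its base pairs are within their engagement distance
#' (transiently open or slipped base pairs carry no defined local helical
#' geometry).
#'
#' @param frames A `cg_trajectory`, an n x 3 x T array, or a single n x 3
#'   matrix / `cg_coordinates`.
#' @param topology The duplex topology (>= 14 bp).
#' @param exclude_terminal Bases excluded at each end (default 3).
#' @param width_padding Radial padding added to the bead-centre radius
#'   (default `dna_params$sigma_ex / 2`).
#' @param dna_params DNA parameter set.
#' @param intact_factor Intactness threshold for structural statistics in
#'   units of sigma_HB (default 1.35): tighter than the 1.5 sigma_HB melting
#'   engagement criterion because local helical geometry is only defined for
#'   canonical pairs sitting in their bound well; transiently open or slipped
#'   pairs are excluded.
#' @return List with `rise`, `width`, `bp_per_turn` (each `c(mean, sd)`
#'   pooled over steps and frames), `n_frames_used`, `n_frames_melted`.
#' @export
helical_parameters <- function(frames, topology, exclude_terminal = 3,
                               width_padding = NULL,
                               dna_params = dna_parameters(),
                               intact_factor = 1.35) {
  if (!isTRUE(topology$duplex)) stop("need a duplex topology")
  beads <- topology$beads
  n <- max(beads$residue[beads$chain == 1])
  if (n < 14) stop("helical analysis needs at least 14 base pairs")
  if (is.null(width_padding)) width_padding <- dna_params$sigma_ex / 2
  pairing <- duplex_pairing(topology)
  fl <- .frame_list(frames)
  rises <- c(); twists <- c(); radii <- c()
  melted <- 0L
  for (pos in fl) {
    if (!classify_hybridized(pos, topology, dna_params)$hybridized) {
      melted <- melted + 1L
      next
    }
    intact <- .intact_bps(pos, topology, dna_params, intact_factor)
    hf <- .helical_frame(pos, beads, n, pairing, exclude_terminal)
    js <- (exclude_terminal + 1):(n - exclude_terminal - 1)
    js <- js[intact[js] & intact[js + 1]]
    for (j in js) {
      u <- hf$us[hf$anchor_for(j + 0.5), ]
      rises <- c(rises, abs(sum((hf$centre[j + 1, ] - hf$centre[j, ]) * u)))
      # cross-base-pair vectors, perpendicular components
      v1 <- pos[hf$ba1[j], ] - pos[hf$ba2[hf$p[j]], ]
      v2 <- pos[hf$ba1[j + 1], ] - pos[hf$ba2[hf$p[j + 1]], ]
      v1p <- v1 - sum(v1 * u) * u
      v2p <- v2 - sum(v2 * u) * u
      cr <- c(v1p[2] * v2p[3] - v1p[3] * v2p[2],
              v1p[3] * v2p[1] - v1p[1] * v2p[3],
              v1p[1] * v2p[2] - v1p[2] * v2p[1])
      twists <- c(twists, atan2(sum(cr * u), sum(v1p * v2p)) * 180 / pi)
    }
    jr <- (exclude_terminal + 1):(n - exclude_terminal)
    jr <- jr[intact[jr]]
    for (j in jr) {
      ai <- hf$anchor_for(j)
      u <- hf$us[ai, ]; a0 <- hf$anchors[ai, ]
      for (x in list(hf$pos[hf$bb1[j], ], hf$pos[hf$bb2[hf$p[j]], ])) {
        d <- x - a0
        radii <- c(radii, sqrt(sum((d - sum(d * u) * u)^2)))
      }
    }
  }
  if (!length(rises)) stop("no hybridized frames to analyse")
  mean_twist <- mean(abs(twists))
  bpt <- 360 / abs(twists)
  list(
    rise = c(mean = mean(rises), sd = stats::sd(rises)),
    width = c(mean = 2 * (mean(radii) + width_padding),
              sd = 2 * stats::sd(radii)),
    bp_per_turn = c(mean = 360 / mean_twist, sd = stats::sd(bpt)),
    n_frames_used = length(fl) - melted,
    n_frames_melted = melted
  )
}

#' Major and minor groove widths at a base-pair step
#'
#' Measures cross-strand backbone-backbone separations at the designated step
#' (1-based; step `s` lies between base pairs `s` and `s+1`). The
#' strand-2 partner offsets defining the two grooves are frozen on the ideal
#' B-form fixture built from the same topology: scanning offsets within one
#' helical turn, the minor groove is the maximal separation and the major
#' groove the minimal one (the bead-centre convention in which experimental
#' B-DNA gives minor ~17 A > major ~12 A). Distances are bead-centre values;
#' no bead radius is subtracted.
#'
#' @param frames Trajectory frames (as in [helical_parameters()]).
#' @param topology Duplex topology (>= 3 helical turns recommended).
#' @param step_index 1-based base-pair step (must be >= 3 base pairs away from
#'   both termini).
#' @param offsets Optional list with `minor` and `major` integer offsets
#'   (skips the ideal-fixture calibration).
#' @param dna_params DNA parameter set.
#' @param intact_factor Intactness threshold for the step's base pairs, in
#'   units of sigma_HB (see [helical_parameters()]).
#' @return List with `minor` and `major` (`c(mean, sd)` over frames) and the
#'   `offsets` used.
#' @export
groove_widths <- function(frames, topology, step_index, offsets = NULL,
                          dna_params = dna_parameters(), intact_factor = 1.35) {
  if (!isTRUE(topology$duplex)) stop("need a duplex topology")
  beads <- topology$beads
  n <- max(beads$residue[beads$chain == 1])
  if (step_index < 3 || step_index + 1 > n - 2) {
    stop("step too close to the duplex termini")
  }
  pairing <- duplex_pairing(topology)
  p <- pairing$res2
  bb1 <- .bead_at(beads, 1, 1:n, "dna_backbone")
  bb2 <- .bead_at(beads, 2, 1:n, "dna_backbone")
  step_sep <- function(pos, k) {
    r2a <- p[step_index] + k; r2b <- p[step_index + 1] + k
    if (r2a > n || r2b < 1 || r2a < 1 || r2b > n) return(NA_real_)
    m1 <- (pos[bb1[step_index], ] + pos[bb1[step_index + 1], ]) / 2
    m2 <- (pos[bb2[r2a], ] + pos[bb2[r2b], ]) / 2
    sqrt(sum((m1 - m2)^2))
  }
  if (is.null(offsets)) {
    ideal <- build_bdna_coordinates(topology, params = dna_params)$positions
    ks <- -5:5
    d <- vapply(ks, function(k) step_sep(ideal, k), numeric(1))
    ok <- !is.na(d)
    offsets <- list(minor = ks[ok][which.max(d[ok])],
                    major = ks[ok][which.min(d[ok])])
  }
  fl <- .frame_list(frames)
  # only frames where the step's neighbourhood (+/- 2 bp) is canonically
  # intact define a groove geometry at that step
  nbhd <- max(1, step_index - 2):min(n, step_index + 3)
  ok <- vapply(fl, function(pos) {
    all(.intact_bps(pos, topology, dna_params, intact_factor)[nbhd])
  }, logical(1))
  if (!any(ok)) stop("no frames with an intact base-pair step to analyse")
  dm <- vapply(fl[ok], function(pos) step_sep(pos, offsets$minor), numeric(1))
  dM <- vapply(fl[ok], function(pos) step_sep(pos, offsets$major), numeric(1))
  list(minor = c(mean = mean(dm), sd = stats::sd(dm)),
       major = c(mean = mean(dM), sd = stats::sd(dM)),
       offsets = offsets, n_frames_used = sum(ok),
       n_frames_excluded = sum(!ok))
}

#' Intermolecular contact-probability map
#'
#' Probability, over frames, that any bead pair between group `a` of `groups_A`
#' and group `b` of `groups_B` lies within the contact cutoff. The default
#' cutoff rule is `1.5 x` the arithmetic-mean vdW diameter of the pair (per
#' species, from the HPS table; DNA beads 5.5 A); a numeric `cutoff` applies
#' one distance to all pairs.
#'
#' @param frames Trajectory frames.
#' @param topology The system topology.
#' @param groups_A,groups_B Lists of 1-based bead index vectors (named lists
#'   give labelled axes).
#' @param cutoff Optional fixed cutoff in A.
#' @param cutoff_factor Multiplier on the mean pair diameter (default 1.5).
#' @param hps_params HPS parameter set (species diameters).
#' @return Matrix of contact probabilities in `[0, 1]` (rows = groups_A).
#' @export
contact_map <- function(frames, topology, groups_A, groups_B, cutoff = NULL,
                        cutoff_factor = 1.5, hps_params = hps_parameters()) {
  stopifnot(length(groups_A) >= 1, length(groups_B) >= 1)
  if (any(vapply(groups_A, length, integer(1)) == 0) ||
      any(vapply(groups_B, length, integer(1)) == 0)) stop("empty contact group")
  fl <- .frame_list(frames)
  tab <- hps_params$species
  key <- ifelse(topology$beads$kind == "dna_base",
                paste0("d", topology$beads$species), topology$beads$species)
  sig <- tab$sigma[match(key, tab$species)]
  sig[is.na(sig)] <- 5.5
  out <- matrix(0, length(groups_A), length(groups_B),
                dimnames = list(names(groups_A), names(groups_B)))
  for (a in seq_along(groups_A)) {
    ia <- groups_A[[a]]
    for (b in seq_along(groups_B)) {
      ib <- groups_B[[b]]
      cut_ab <- if (is.null(cutoff)) {
        cutoff_factor * outer(sig[ia], sig[ib], "+") / 2
      } else matrix(cutoff, length(ia), length(ib))
      hits <- vapply(fl, function(pos) {
        d2 <- outer(pos[ia, 1], pos[ib, 1], "-")^2 +
              outer(pos[ia, 2], pos[ib, 2], "-")^2 +
              outer(pos[ia, 3], pos[ib, 3], "-")^2
        any(d2 < cut_ab^2)
      }, logical(1))
      out[a, b] <- mean(hits)
    }
  }
  out
}
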