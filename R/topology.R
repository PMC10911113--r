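#' @useDynLib cgdna, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim sd var setNames approx runif rnorm
#' @importFrom utils head tail read.table write.table
NULL

.bases_of <- function(beads) beads[beads$kind == "dna_base", , drop = FALSE]

# Complementarity test for base letters (upper case) or hb species (hb_a ...)
.complementary <- function(x, y) {
  unname(DNA_COMPLEMENT[x]) == y
}

# Build the bead table for one DNA strand
.dna_strand_beads <- function(seq, variant, chain) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  per <- if (variant == "three_bead") 3L else 2L
  res <- rep(seq_len(n), each = per)
  if (variant == "three_bead") {
    species <- as.vector(rbind("BB", ch, paste0("hb_", tolower(ch))))
    kind <- rep(c("dna_backbone", "dna_base", "dna_hb"), n)
    mass <- as.vector(rbind(DNA_MASSES["BB"], DNA_MASSES[ch], 0.5 * DNA_MASSES[ch]))
  } else {
    species <- as.vector(rbind("BB", ch))
    kind <- rep(c("dna_backbone", "dna_base"), n)
    mass <- as.vector(rbind(DNA_MASSES["BB"], DNA_MASSES[ch]))
  }
  data.frame(
    chain = chain, residue = res, species = species, kind = kind,
    mass = unname(mass),
    charge = ifelse(kind == "dna_backbone", -1, 0),
    stringsAsFactors = FALSE
  )
}

# Nonbonded pair classification over all DNA beads of a bead table.
# Returns list(stacking=, hb=, excluded=) of data frames with bead indices i<j.
.classify_dna_pairs <- function(beads, variant) {
  bs <- which(beads$kind == "dna_base")
  stacking <- hb <- excluded <- data.frame(i = integer(), j = integer(),
                                           pair = character(), stringsAsFactors = FALSE)
  if (length(bs) >= 2) {
    cmb <- utils::combn(bs, 2)
    bi <- cmb[1, ]; bj <- cmb[2, ]
    same_chain <- beads$chain[bi] == beads$chain[bj]
    dres <- abs(beads$residue[bi] - beads$residue[bj])
    a <- beads$species[bi]; b <- beads$species[bj]
    swap <- match(a, DNA_BASES) > match(b, DNA_BASES)
    pair_lab <- paste(ifelse(swap, b, a), ifelse(swap, a, b), sep = "-")
    is_stack <- same_chain & dres == 1
    comp <- .complementary(a, b)
    # Complementary (non-near-neighbour) base pairs contribute to the
    # hydrogen-bonding term: directly in the 2-bead model, via their dummy HB
    # beads in the 3-bead model. Either way they are not excluded-volume
    # pairs; in the 3-bead model the base beads themselves carry no potential
    # for these pairs.
    is_hb <- comp & !(same_chain & dres <= 2) & !is_stack
    is_ex <- !is_stack & !is_hb
    stacking <- data.frame(i = bi[is_stack], j = bj[is_stack],
                           pair = pair_lab[is_stack], stringsAsFactors = FALSE)
    if (variant == "two_bead") {
      hb <- data.frame(i = bi[is_hb], j = bj[is_hb],
                       pair = pair_lab[is_hb], stringsAsFactors = FALSE)
    }
    excluded <- data.frame(i = bi[is_ex], j = bj[is_ex],
                           pair = pair_lab[is_ex], stringsAsFactors = FALSE)
  }
  if (variant == "three_bead") {
    hs <- which(beads$kind == "dna_hb")
    if (length(hs) >= 2) {
      cmb <- utils::combn(hs, 2)
      hi <- cmb[1, ]; hj <- cmb[2, ]
      same_chain <- beads$chain[hi] == beads$chain[hj]
      dres <- abs(beads$residue[hi] - beads$residue[hj])
      a <- toupper(sub("hb_", "", beads$species[hi]))
      b <- toupper(sub("hb_", "", beads$species[hj]))
      comp <- .complementary(a, b)
      keep <- comp & !(same_chain & dres <= 2)
      swap <- match(a, DNA_BASES) > match(b, DNA_BASES)
      lab <- tolower(paste(ifelse(swap, b, a), ifelse(swap, a, b), sep = "-"))
      hb <- data.frame(i = hi[keep], j = hj[keep], pair = lab[keep],
                       stringsAsFactors = FALSE)
    }
  }
  list(stacking = stacking, hb = hb, excluded = excluded)
}

#' Build a coarse-grained DNA topology
#'
#' Maps a nucleotide sequence onto the 2-bead (backbone + base) or 3-bead
#' (backbone + base + hydrogen-bonding dummy) representation, generating
#' beads, harmonic bonds, cosine-squared angles and the full nonbonded pair
#' classification (stacking / hydrogen bonding / excluded volume; the classes
#' are mutually exclusive and bonded pairs carry no nonbonded class).
#'
#' For a duplex the complementary strand is generated internally (reverse
#' complement, 5' to 3') and residue `i` of strand 1 pairs with residue
#' `n + 1 - i` of strand 2.
#'
#' @param seq DNA sequence string (strand 1, 5' to 3').
#' @param variant `"two_bead"` or `"three_bead"`.
#' @param duplex Logical; build the double-stranded topology?
#' @return Object of class `cg_topology` with fields `beads`, `bonds`,
#'   `angles`, `pairs` (list `stacking`, `hb`, `excluded`), `variant`,
#'   `duplex`, `sequences`.
#' @export
#' @examples
#' top <- build_dna_topology("GCGTCATACAGTGC", "two_bead")
#' nrow(top$beads)  # 28
build_dna_topology <- function(seq, variant = c("two_bead", "three_bead"),
                               duplex = FALSE) {
  variant <- match.arg(variant)
  s1 <- validate_dna_sequence(seq)
  seqs <- list(s1)
  if (duplex) seqs <- c(seqs, dna_complement(s1))
  beads <- do.call(rbind, lapply(seq_along(seqs), function(k)
    .dna_strand_beads(seqs[[k]], variant, chain = k)))
  beads$index <- seq_len(nrow(beads))
  beads <- beads[, c("index", "chain", "residue", "species", "kind", "mass", "charge")]

  bonds <- NULL; angles <- NULL
  for (chain in seq_along(seqs)) {
    n <- nchar(seqs[[chain]])
    bb <- beads$index[beads$chain == chain & beads$kind == "dna_backbone"]
    ba <- beads$index[beads$chain == chain & beads$kind == "dna_base"]
    if (n > 1) {
      bonds <- rbind(bonds, data.frame(i = bb[-n], j = bb[-1], class = "bb_bb",
                                       stringsAsFactors = FALSE))
    }
    bonds <- rbind(bonds, data.frame(i = bb, j = ba, class = "bb_base",
                                     stringsAsFactors = FALSE))
    if (n > 2) {
      angles <- rbind(angles, data.frame(i = bb[1:(n - 2)], j = bb[2:(n - 1)],
                                         k = bb[3:n], class = "backbone",
                                         stringsAsFactors = FALSE))
    }
    if (variant == "three_bead") {
      hb <- beads$index[beads$chain == chain & beads$kind == "dna_hb"]
      bonds <- rbind(bonds, data.frame(i = ba, j = hb, class = "base_hb",
                                       stringsAsFactors = FALSE))
      angles <- rbind(angles, data.frame(i = hb, j = ba, k = bb, class = "hb",
                                         stringsAsFactors = FALSE))
    }
  }
  if (is.null(bonds)) bonds <- data.frame(i = integer(), j = integer(),
                                          class = character(), stringsAsFactors = FALSE)
  if (is.null(angles)) angles <- data.frame(i = integer(), j = integer(), k = integer(),
                                            class = character(), stringsAsFactors = FALSE)
  top <- list(
    beads = beads, bonds = bonds, angles = angles,
    pairs = .classify_dna_pairs(beads, variant),
    variant = variant, duplex = duplex, sequences = seqs
  )
  class(top) <- "cg_topology"
  top
}

#' Build a one-bead-per-residue protein topology
#'
#' One bead per amino acid at the C-alpha position, consecutive residues
#' connected by harmonic bonds (r0 = 3.8 A, K = 10 kcal/(mol A^2)); Arg/Lys
#' carry +1, Asp/Glu -1, all other residues are neutral. No angle terms.
#'
#' @param aa_seq One-letter amino-acid sequence string.
#' @return A `cg_topology` with `variant = "protein"`.
#' @export
#' @examples
#' net_charge(build_protein_topology("KKDE"))  # 0
build_protein_topology <- function(aa_seq) {
  s <- validate_protein_sequence(aa_seq)
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  beads <- data.frame(
    index = seq_len(n), chain = 1L, residue = seq_len(n),
    species = ch, kind = "protein",
    mass = unname(AA_MASS[ch]), charge = unname(AA_CHARGE[ch]),
    stringsAsFactors = FALSE
  )
  bonds <- if (n > 1) {
    data.frame(i = 1:(n - 1), j = 2:n, class = "protein", stringsAsFactors = FALSE)
  } else {
    data.frame(i = integer(), j = integer(), class = character(), stringsAsFactors = FALSE)
  }
  top <- list(
    beads = beads, bonds = bonds,
    angles = data.frame(i = integer(), j = integer(), k = integer(),
                        class = character(), stringsAsFactors = FALSE),
    pairs = list(stacking = data.frame(), hb = data.frame(), excluded = data.frame()),
    variant = "protein", duplex = FALSE, sequences = list(s)
  )
  class(top) <- "cg_topology"
  top
}

#' Combine topologies into one multi-molecule system
#'
#' Concatenates bead tables (chains renumbered, indices shifted) and
#' recomputes the DNA nonbonded pair classification over the merged system,
#' so interstrand stacking/HB/excluded rules apply across molecules exactly
#' as within one. DNA molecules must share the same model variant.
#'
#' @param ... `cg_topology` objects.
#' @return A merged `cg_topology`.
#' @export
combine_topologies <- function(...) {
  tops <- list(...)
  stopifnot(length(tops) >= 1)
  dna_var <- unique(vapply(tops, function(t) t$variant, character(1)))
  dna_var <- setdiff(dna_var, "protein")
  if (length(dna_var) > 1) stop("cannot mix 2-bead and 3-bead DNA in one system")
  off_bead <- 0L; off_chain <- 0L
  beads <- NULL; bonds <- NULL; angles <- NULL; seqs <- list()
  for (t in tops) {
    b <- t$beads
    b$index <- b$index + off_bead
    b$chain <- b$chain + off_chain
    beads <- rbind(beads, b)
    bo <- t$bonds; bo$i <- bo$i + off_bead; bo$j <- bo$j + off_bead
    bonds <- rbind(bonds, bo)
    an <- t$angles
    if (nrow(an)) { an$i <- an$i + off_bead; an$j <- an$j + off_bead; an$k <- an$k + off_bead }
    angles <- rbind(angles, an)
    seqs <- c(seqs, t$sequences)
    off_bead <- off_bead + nrow(t$beads)
    off_chain <- off_chain + max(t$beads$chain)
  }
  variant <- if (length(dna_var)) dna_var else "protein"
  top <- list(
    beads = beads, bonds = bonds, angles = angles,
    pairs = .classify_dna_pairs(beads, variant),
    variant = variant,
    duplex = any(vapply(tops, function(t) isTRUE(t$duplex), logical(1))),
    sequences = seqs
  )
  class(top) <- "cg_topology"
  top
}

#' Net formal charge of a topology
#' @param topology A `cg_topology`.
#' @return Sum of bead charges (e).
#' @export
net_charge <- function(topology) sum(topology$beads$charge)

#' Exhaustive nonbonded pair classification
#'
#' Enumerates every unordered bead pair and reports its class:
#' `bonded` (directly bonded, no nonbonded interaction), `stacking`,
#' `hydrogen_bonding`, `excluded_volume`, or `plain` (electrostatics / HPS
#' only). The three structured DNA classes are mutually exclusive by
#' construction.
#'
#' @param topology A `cg_topology`.
#' @return Data frame with columns `i`, `j`, `class` covering all pairs.
#' @export
pair_classification <- function(topology) {
  n <- nrow(topology$beads)
  cmb <- utils::combn(n, 2)
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  cls <- rep("plain", ncol(cmb))
  k_all <- key(cmb[1, ], cmb[2, ])
  set_cls <- function(df, label) {
    if (nrow(df)) cls[match(key(df$i, df$j), k_all)] <<- label
  }
  set_cls(topology$pairs$stacking, "stacking")
  set_cls(topology$pairs$hb, "hydrogen_bonding")
  set_cls(topology$pairs$excluded, "excluded_volume")
  set_cls(topology$bonds, "bonded")
  data.frame(i = cmb[1, ], j = cmb[2, ], class = cls, stringsAsFactors = FALSE)
}

# Residue pairing of a duplex: strand `c1` residue i pairs strand `c2`
# residue n + 1 - i. Returns data.frame(res1, res2).
duplex_pairing <- function(topology, chains = c(1L, 2L)) {
  if (!isTRUE(topology$duplex)) stop("topology is not a duplex")
  n1 <- max(topology$beads$residue[topology$beads$chain == chains[1]])
  data.frame(res1 = seq_len(n1), res2 = n1:1)
}

# index of the bead of `kind` at (chain, residue); vectorised over residue
.bead_at <- function(beads, chain, residue, kind) {
  idx <- beads$index[beads$chain == chain & beads$kind == kind]
  res <- beads$residue[beads$chain == chain & beads$kind == kind]
  idx[match(residue, res)]
}
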