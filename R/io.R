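#' Write a topology to a tabular text file
#'
#' Three TAB-separated sections (`[beads]`, `[bonds]`, `[angles]`) preceded by
#' a header line recording the model variant and duplex flag. Bead indices are
#' 1-based in the file (0-based indexing is internal to the energy kernel;
#' human-facing artifacts are 1-based).
#'
#' @param topology A `cg_topology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cgdna topology\tvariant=%s\tduplex=%s",
                     topology$variant, topology$duplex), con)
  writeLines("[beads]", con)
  utils::write.table(topology$beads, con, sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines("[bonds]", con)
  utils::write.table(topology$bonds, con, sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines("[angles]", con)
  utils::write.table(topology$angles, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a topology written by [write_topology()]
#'
#' @param path File path.
#' @return A `cg_topology` (pair classification recomputed).
#' @export
read_topology <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\t")[[1]]
  variant <- sub("variant=", "", hdr[2])
  duplex <- as.logical(sub("duplex=", "", hdr[3]))
  sec <- function(name) {
    i0 <- which(lines == sprintf("[%s]", name)) + 1
    ends <- c(grep("^\\[", lines), length(lines) + 1)
    i1 <- min(ends[ends > i0]) - 1
    if (i1 < i0 + 1) return(NULL)
    utils::read.table(text = lines[i0:i1], header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
  beads <- sec("beads"); bonds <- sec("bonds"); angles <- sec("angles")
  if (is.null(bonds)) bonds <- data.frame(i = integer(), j = integer(),
                                          class = character(), stringsAsFactors = FALSE)
  if (is.null(angles)) angles <- data.frame(i = integer(), j = integer(), k = integer(),
                                            class = character(), stringsAsFactors = FALSE)
  top <- list(beads = beads, bonds = bonds, angles = angles,
              pairs = .classify_dna_pairs(beads, variant),
              variant = variant, duplex = duplex,
              sequences = split(beads$species[beads$kind %in% c("dna_base", "protein")],
                                beads$chain[beads$kind %in% c("dna_base", "protein")]))
  top$sequences <- lapply(top$sequences, paste, collapse = "")
  class(top) <- "cg_topology"
  top
}

#' Write coordinates (or a trajectory) as XYZ frames
#'
#' @param x A `cg_coordinates`, n x 3 matrix, or n x 3 x T frame array.
#' @param topology Topology supplying bead species names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, topology, path) {
  fl <- .frame_list(x)
  sp <- topology$beads$species
  con <- file(path, "w")
  on.exit(close(con))
  for (pos in fl) {
    writeLines(as.character(nrow(pos)), con)
    writeLines("cgdna frame", con)
    writeLines(sprintf("%s %.6f %.6f %.6f", sp, pos[, 1], pos[, 2], pos[, 3]), con)
  }
  invisible(path)
}

#' Read XYZ frames
#'
#' @param path XYZ file path.
#' @return n x 3 x T array of coordinates.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    n <- as.integer(trimws(lines[i]))
    rows <- lines[(i + 2):(i + 1 + n)]
    m <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), function(p)
      as.numeric(p[2:4])))
    frames <- c(frames, list(m))
    i <- i + 2 + n
  }
  arr <- array(NA_real_, dim = c(nrow(frames[[1]]), 3, length(frames)))
  for (t in seq_along(frames)) arr[, , t] <- frames[[t]]
  arr
}

#' Export a LAMMPS-style data file (atom_style full fields)
#'
#' Numeric species/bond/angle type ids are assigned in order of first
#' appearance and documented in comment lines, for cross-checking against
#' engine implementations of the same force field.
#'
#' @param topology A `cg_topology`.
#' @param coords A `cg_coordinates`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lammps_data <- function(topology, coords, path) {
  beads <- topology$beads
  sp_types <- unique(beads$species)
  b_types <- unique(topology$bonds$class)
  a_types <- unique(topology$angles$class)
  box <- coords$box
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("cgdna data file", con)
  writeLines("", con)
  writeLines(sprintf("%d atoms", nrow(beads)), con)
  writeLines(sprintf("%d bonds", nrow(topology$bonds)), con)
  writeLines(sprintf("%d angles", nrow(topology$angles)), con)
  writeLines(sprintf("%d atom types", length(sp_types)), con)
  writeLines(sprintf("%d bond types", max(1, length(b_types))), con)
  writeLines(sprintf("%d angle types", max(1, length(a_types))), con)
  writeLines("", con)
  writeLines(sprintf("%.4f %.4f xlo xhi", -box[1] / 2, box[1] / 2), con)
  writeLines(sprintf("%.4f %.4f ylo yhi", -box[2] / 2, box[2] / 2), con)
  writeLines(sprintf("%.4f %.4f zlo zhi", -box[3] / 2, box[3] / 2), con)
  writeLines("", con)
  writeLines(paste0("# atom types: ",
                    paste(sprintf("%d=%s", seq_along(sp_types), sp_types), collapse = " ")), con)
  writeLines("", con)
  writeLines("Masses", con)
  writeLines("", con)
  for (t in seq_along(sp_types)) {
    writeLines(sprintf("%d %.4f", t, beads$mass[match(sp_types[t], beads$species)]), con)
  }
  writeLines("", con)
  writeLines("Atoms # full", con)
  writeLines("", con)
  writeLines(sprintf("%d %d %d %.4f %.6f %.6f %.6f",
                     beads$index, beads$chain, match(beads$species, sp_types),
                     beads$charge, coords$positions[, 1], coords$positions[, 2],
                     coords$positions[, 3]), con)
  if (nrow(topology$bonds)) {
    writeLines("", con); writeLines("Bonds", con); writeLines("", con)
    writeLines(sprintf("%d %d %d %d", seq_len(nrow(topology$bonds)),
                       match(topology$bonds$class, b_types),
                       topology$bonds$i, topology$bonds$j), con)
  }
  if (nrow(topology$angles)) {
    writeLines("", con); writeLines("Angles", con); writeLines("", con)
    writeLines(sprintf("%d %d %d %d %d", seq_len(nrow(topology$angles)),
                       match(topology$angles$class, a_types),
                       topology$angles$i, topology$angles$j, topology$angles$k), con)
  }
  invisible(path)
}

#' Read and validate a run-configuration file (YAML)
#'
#' Required fields: `variant`, `sequence` (or `fasta`), `temperature` (scalar
#' or ladder), `n_steps`, `seed`. Optional: `duplex` (default `TRUE`),
#' `salt_mM` or `kappa`, `dt` (10), `tau` (10), `stride` (1000), `box`,
#' `swap_interval`, `umbrella` (list: `centers`, `k_u`, `groupA`, `groupB`),
#' `output` paths.
#'
#' @param path YAML file path.
#' @return Validated config list (class `cg_run_config`) with defaults
#'   filled in and an `elec` electrostatics context attached.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("variant", "temperature", "n_steps", "seed")
  missing <- setdiff(required, names(cfg))
  if (!("sequence" %in% names(cfg)) && !("fasta" %in% names(cfg))) {
    missing <- c(missing, "sequence (or fasta)")
  }
  if (length(missing)) {
    stop("run config is missing required field(s): ", paste(missing, collapse = ", "))
  }
  if (!cfg$variant %in% c("two_bead", "three_bead")) {
    stop("variant must be two_bead or three_bead")
  }
  defaults <- list(duplex = TRUE, dt = 10, tau = 10, stride = 1000,
                   salt_mM = 100, swap_interval = 100)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  cfg$elec <- if (!is.null(cfg$kappa)) electrostatics_context(kappa = cfg$kappa)
              else electrostatics_context(salt_mM = cfg$salt_mM)
  if (!is.null(cfg$fasta)) cfg$sequence <- unname(read_sequences(cfg$fasta, "dna")[1])
  class(cfg) <- "cg_run_config"
  cfg
}

#' Stable hash of a run configuration
#'
#' Canonicalises the configuration (sorted names, numbers at full precision,
#' class/derived fields dropped) to JSON and returns its MD5; semantically
#' identical configs hash identically.
#'
#' @param cfg A config list.
#' @return MD5 string.
#' @export
config_hash <- function(cfg) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- x[!vapply(x, is.null, logical(1))]
      x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  cfg <- unclass(cfg)
  cfg$elec <- NULL
  js <- jsonlite::toJSON(canon(cfg), auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

#' Save a trajectory as plain-text artifacts
#'
#' Writes `<prefix>.xyz` (frames), `<prefix>_energies.tsv` (per-frame energy
#' decomposition) and `<prefix>_meta.json` (seed, settings, config hash).
#'
#' @param traj A `cg_trajectory`.
#' @param topology The topology simulated.
#' @param prefix Output path prefix.
#' @param config Optional config list recorded (and hashed) in the metadata.
#' @return Named vector of file paths, invisibly.
#' @export
save_trajectory <- function(traj, topology, prefix, config = NULL) {
  paths <- c(xyz = paste0(prefix, ".xyz"),
             energies = paste0(prefix, "_energies.tsv"),
             meta = paste0(prefix, "_meta.json"))
  write_xyz(traj$frames, topology, paths["xyz"])
  utils::write.table(traj$energies, paths["energies"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  meta <- list(settings = unclass(traj$settings), box = traj$box,
               n_frames = dim(traj$frames)[3],
               variant = traj$topology_variant,
               config_hash = if (!is.null(config)) config_hash(config) else NULL)
  jsonlite::write_json(meta, paths["meta"], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}
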