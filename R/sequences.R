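#' Validate a DNA sequence
#'
#' @param seq Character scalar over the alphabet A, C, G, T (case-insensitive).
#' @return The validated upper-case sequence.
#' @export
validate_dna_sequence <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  s <- toupper(seq)
  if (nchar(s) == 0) stop("empty DNA sequence")
  ch <- strsplit(s, "")[[1]]
  bad <- which(!ch %in% DNA_BASES)
  if (length(bad)) {
    stop(sprintf("invalid DNA symbol '%s' at position %d", ch[bad[1]], bad[1]))
  }
  s
}

#' Validate a protein sequence (one-letter amino-acid codes)
#'
#' @param seq Character scalar of one-letter codes for the 20 standard amino
#'   acids.
#' @return The validated upper-case sequence.
#' @export
validate_protein_sequence <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  s <- toupper(seq)
  if (nchar(s) == 0) stop("empty protein sequence")
  ch <- strsplit(s, "")[[1]]
  bad <- which(!ch %in% AA_CODES)
  if (length(bad)) {
    stop(sprintf("unknown residue letter '%s' at position %d", ch[bad[1]], bad[1]))
  }
  s
}

#' Watson-Crick complement of a DNA sequence
#'
#' Returns the reverse complement (the complementary strand read 5' to 3').
#'
#' @param seq DNA sequence string.
#' @return The reverse-complement sequence, 5' to 3'.
#' @export
#' @examples
#' dna_complement("GCGTCATACAGTGC")  # "GCACTGTATGACGC"
dna_complement <- function(seq) {
  s <- validate_dna_sequence(seq)
  ch <- strsplit(s, "")[[1]]
  paste(rev(unname(DNA_COMPLEMENT[ch])), collapse = "")
}

#' Read sequences from a FASTA file or a literal string
#'
#' If `x` is the path to an existing file it is parsed as FASTA (via
#' \pkg{seqinr}); otherwise it is treated as a raw sequence literal. Sequences
#' are validated against the requested alphabet.
#'
#' @param x File path or sequence string.
#' @param type `"dna"` or `"protein"`.
#' @return Named character vector of validated sequences (names are FASTA
#'   record ids, or `"seq1"` for a literal).
#' @export
read_sequences <- function(x, type = c("dna", "protein")) {
  type <- match.arg(type)
  validate <- if (type == "dna") validate_dna_sequence else validate_protein_sequence
  if (length(x) == 1 && !grepl("[\n>]", x) && file.exists(x)) {
    recs <- seqinr::read.fasta(x, as.string = TRUE, forceDNAtolower = FALSE, seqonly = FALSE)
    if (length(recs) == 0) stop("FASTA file contains no records: ", x)
    out <- vapply(recs, function(r) validate(as.character(r)[1]), character(1))
    names(out) <- vapply(recs, function(r) attr(r, "name"), character(1))
    out
  } else {
    out <- vapply(unname(x), validate, character(1))
    names(out) <- paste0("seq", seq_along(out))
    out
  }
}
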