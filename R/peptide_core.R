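# Peptide data model, FASTA/TSV I/O and molecular-mass computation.
#
# Peptides are represented throughout the package as named character vectors
# of uppercase one-letter amino acid codes: names are record ids, elements are
# sequences.  Only the 20 standard residues are admitted; ambiguity codes
# (B, J, X, Z) and the rare U/O are rejected because the cleavage formulas
# downstream are defined only over the standard alphabet.

#' The 20 standard one-letter amino acid codes
#' @return Character vector of the 20 standard residues.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# Average residue masses (Da) of the 20 standard amino acids, frozen as
# packaged constants so tests are byte-stable.  Chain mass = sum of residue
# masses + one water.
.residue_masses <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
.water_mass <- 18.02

#' Average residue mass table
#'
#' Average (isotope-weighted) masses of the 20 standard amino acid residues
#' in daltons, plus the mass of one water molecule added per chain.
#'
#' @return A list with elements `residues` (named numeric vector of 20
#'   residue masses) and `water` (scalar, Da).
#' @export
residue_mass_table <- function() {
  list(residues = .residue_masses, water = .water_mass)
}

#' Construct a peptide set
#'
#' Validates and canonicalises sequences (uppercase, standard alphabet only)
#' and returns them as a named character vector, the peptide representation
#' used by every other function in the package.
#'
#' @param seqs Character vector of amino acid sequences (case-insensitive).
#' @param ids Optional character vector of ids; defaults to existing names or
#'   `pep1`, `pep2`, ...
#' @return Named character vector of validated uppercase sequences.
#' @export
peptides <- function(seqs, ids = NULL) {
  if (is.null(ids)) {
    ids <- if (!is.null(names(seqs))) names(seqs) else paste0("pep", seq_along(seqs))
  }
  stopifnot(length(ids) == length(seqs))
  seqs <- toupper(as.character(seqs))
  for (i in seq_along(seqs)) .validate_residues(seqs[[i]], ids[[i]])
  stats::setNames(seqs, ids)
}

.validate_residues <- function(seq, id) {
  if (!nzchar(seq)) {
    stop("empty sequence in record '", id, "'", call. = FALSE)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% aa_alphabet())
  if (length(bad) > 0) {
    stop("invalid residue '", chars[bad[1]], "' in record '", id,
         "' at position ", bad[1], call. = FALSE)
  }
  invisible(TRUE)
}

#' Read peptides from a FASTA file
#'
#' @param path Path to a FASTA file of protein sequences.
#' @return Named character vector of validated uppercase sequences, record
#'   order preserved.
#' @export
read_fasta_peptides <- function(path) {
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0) stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  peptides(as.character(set), ids)
}

#' Write peptides to a FASTA file
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param peps Named character vector of peptide sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_peptides <- function(peps, path) {
  set <- Biostrings::BStringSet(unname(peps))
  names(set) <- names(peps)
  Biostrings::writeXStringSet(set, path, format = "fasta", width = 60L)
  invisible(path)
}

#' Average molecular mass of a peptide chain
#'
#' Sum of the average residue masses plus one water.  The degenerate empty
#' chain is allowed here (and only here) and returns the water mass.
#'
#' @param seq A single amino acid sequence (character scalar; empty allowed).
#' @param table Mass table from [residue_mass_table()].
#' @return Mass in daltons, rounded to 2 decimals.
#' @export
average_mass <- function(seq, table = residue_mass_table()) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  if (!nzchar(seq)) return(round(table$water, 2))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (any(!chars %in% names(table$residues))) {
    stop("sequence contains residues outside the mass table", call. = FALSE)
  }
  round(sum(table$residues[chars]) + table$water, 2)
}

#' Per-peptide composition report
#'
#' One row per peptide: id, length, average mass, and the glutamine and
#' proline fractions that characterise gliadin-like sequences.
#'
#' @param peps Named character vector of peptide sequences.
#' @return A data.frame with columns `id`, `length`, `mass`, `frac_Q`,
#'   `frac_P`.
#' @export
peptide_report <- function(peps) {
  if (length(peps) == 0) {
    return(data.frame(id = character(), length = integer(), mass = numeric(),
                      frac_Q = numeric(), frac_P = numeric(),
                      stringsAsFactors = FALSE))
  }
  n <- nchar(peps)
  data.frame(
    id = names(peps),
    length = as.integer(n),
    mass = vapply(peps, average_mass, numeric(1), USE.NAMES = FALSE),
    frac_Q = vapply(peps, function(s) residue_fraction(s, "Q"), numeric(1),
                    USE.NAMES = FALSE),
    frac_P = vapply(peps, function(s) residue_fraction(s, "P"), numeric(1),
                    USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Fraction of a given residue in a sequence
#' @param seq Amino acid sequence (character scalar).
#' @param residue Single residue code.
#' @return Fraction in `[0, 1]`.
#' @export
residue_fraction <- function(seq, residue) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  sum(chars == residue) / length(chars)
}

#' Expand repeat notation in a peptide string
#'
#' Gliadin repeat units are often written in a compact `(MOTIF)n` notation,
#' e.g. `"LQLQPF(PQPQLPY)3PQPQPF"`; this expands every parenthesised motif
#' the stated number of times.  Both `(PQQ)2` and `(PQQ)_2_` forms are
#' accepted.
#'
#' @param x Character vector of (possibly compact) sequences.
#' @return Character vector of fully expanded sequences.
#' @export
expand_repeats <- function(x) {
  vapply(x, function(s) {
    repeat {
      m <- regmatches(s, regexpr("\\(([A-Za-z]+)\\)_?([0-9]+)_?", s))
      if (length(m) == 0) break
      motif <- sub("\\(([A-Za-z]+)\\)_?([0-9]+)_?", "\\1", m)
      k <- as.integer(sub("\\(([A-Za-z]+)\\)_?([0-9]+)_?", "\\2", m))
      s <- sub("\\(([A-Za-z]+)\\)_?([0-9]+)_?",
               paste(rep(motif, k), collapse = ""), s)
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

# residue multiset of a set of sequences, as a table over the alphabet
residue_counts <- function(seqs) {
  chars <- unlist(strsplit(paste(seqs, collapse = ""), "", fixed = TRUE))
  tab <- table(factor(chars, levels = aa_alphabet()))
  stats::setNames(as.integer(tab), names(tab))
}
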