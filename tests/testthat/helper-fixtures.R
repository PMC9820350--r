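# Shared fixtures built in code.

# the gamma-gliadin immunogenic 26-mer used as the worked digestion example
g26 <- "FLQPQQPFPQQPQQPYPQQPQQPFPQ"

# the five Q/P-rich peptides resistant to human digestive peptidases,
# in compact repeat notation where applicable
resistant_peptides <- c(
  qlq12 = "QLQPFPQPQLPY",
  pqp13 = "PQPQLPYPQPQLP",
  lgq19 = "LGQQQPFPPQQPYPQPQPF",
  a33 = "LQLQPF(PQPQLPY)3PQPQPF",
  o26 = "FLQPQQPF(PQQ)2PY(PQQ)2PFPQ"
)

# residue multiset as a sorted character vector, for conservation checks
residue_multiset <- function(seqs) {
  sort(unlist(strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)))
}

# independent residue-mass summation oracle: counts residues and sums
# table entries, avoiding the production code path
oracle_mass <- function(seq) {
  tab <- residue_mass_table()
  counts <- table(strsplit(seq, "", fixed = TRUE)[[1]])
  round(sum(tab$residues[names(counts)] * as.numeric(counts)) + tab$water, 2)
}

# brute-force site oracle for simple positional rules, used to cross-check
# applicable_sites() on random sequences
oracle_cc_sites <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 3) return(integer(0))
  which(chars[-n] == "Q" & chars[-1] != "P")
}
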