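# Diagnostic-residue classification of candidate peptidase sequences.
#
# Candidates are aligned pairwise against reference sequences carrying
# anchor annotations (catalytic triad, substrate-binding subsites,
# metal-binding sites, essential residues) and classified by family and
# activity status from the residues observed at the anchor columns.
# Serine-family actives must carry the intact Ser-Asp-His triad; a
# candidate whose catalytic Ser column holds a non-catalytic residue while
# the rest of the triad is intact is an inactive homolog (the DPP 10
# situation, catalytic Ser replaced by Gly).

#' Alignment parameters
#'
#' @param matrix Substitution matrix name (`"BLOSUM62"`, resolved from the
#'   matrices packaged with Biostrings).
#' @param gap_open,gap_extend Non-negative affine gap penalties.
#' @return An `alignment_params` object.
#' @export
alignment_params <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 1) {
  stopifnot(gap_open >= 0, gap_extend >= 0)
  structure(list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_params")
}

.subst_matrix <- function(params) {
  e <- new.env()
  utils::data(list = params$matrix, package = "Biostrings", envir = e)
  get(params$matrix, envir = e)
}

#' Global pairwise alignment of two peptides
#'
#' Optimal global (Needleman-Wunsch) alignment under affine gap scoring.
#'
#' @param a,b Amino acid sequences (character scalars).
#' @param params An [alignment_params()] object.
#' @param type Passed to [Biostrings::pairwiseAlignment()]; `"global"` by
#'   default, `"global-local"` leaves the ends of `b` unpenalised (used for
#'   anchor transfer onto candidates with terminal extensions).
#' @return A list with `aligned_a`, `aligned_b` (equal-length gapped
#'   strings) and `score`.
#' @export
global_align <- function(a, b, params = alignment_params(), type = "global") {
  stopifnot(nzchar(a), nzchar(b))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = type,
    substitutionMatrix = .subst_matrix(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  list(aligned_a = as.character(Biostrings::alignedPattern(aln)),
       aligned_b = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

#' Construct an anchor profile
#'
#' @param family MEROPS-style family label (`"S9A"`, `"S9B"`, `"S9X"`,
#'   `"S28"`, `"M24B"`, `"M17"`, `"M20"`).
#' @param reference_id Accession or label of the numbering reference.
#' @param reference_seq The reference amino acid sequence (character
#'   scalar).
#' @param anchors data.frame with columns `role` (one of `catalytic`, `S1`,
#'   `S2`, `metal`, `essential`), `name` (e.g. `"Ser630"`), `position`
#'   (residue index in reference numbering) and `expected` (admissible
#'   residues, e.g. `"W/L/F"`).
#' @param motifs Optional character vector of exact diagnostic subsequences
#'   (e.g. the S9A family motifs).
#' @return An `anchor_profile` object.
#' @export
anchor_profile <- function(family, reference_id, reference_seq, anchors,
                           motifs = character(0)) {
  stopifnot(family %in% c("S9A", "S9B", "S9X", "S28", "M24B", "M17", "M20"))
  stopifnot(all(c("role", "name", "position", "expected") %in% names(anchors)))
  if (any(anchors$position < 1 | anchors$position > nchar(reference_seq))) {
    stop("anchor position outside reference sequence", call. = FALSE)
  }
  if (family %in% c("S9A", "S9B", "S28")) {
    cat_exp <- anchors$expected[anchors$role == "catalytic"]
    if (length(cat_exp) != 3 ||
        !identical(substr(cat_exp, 1, 1), c("S", "D", "H"))) {
      stop("serine-family profiles need exactly three catalytic anchors in ",
           "Ser, Asp, His order", call. = FALSE)
    }
  }
  structure(list(family = family, reference_id = reference_id,
                 reference_seq = toupper(reference_seq),
                 anchors = anchors, motifs = motifs),
            class = "anchor_profile")
}

#' Observed residues at a profile's anchor columns
#'
#' The reference is aligned globally while the candidate's terminal
#' overhangs are unpenalised, so N/C-terminal extensions of the candidate
#' do not disturb anchor read-off.
#'
#' @param candidate Candidate amino acid sequence (character scalar).
#' @param profile An [anchor_profile()].
#' @param params An [alignment_params()].
#' @return Character vector of observed residues (or `"-"` for a gap), one
#'   per anchor row, named by anchor name.
#' @export
extract_anchor_residues <- function(candidate, profile,
                                    params = alignment_params()) {
  aln <- global_align(profile$reference_seq, candidate, params,
                      type = "global-local")
  ref_chars <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  cand_chars <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  # column index of each ungapped reference position
  ref_pos <- cumsum(ref_chars != "-")
  observed <- vapply(profile$anchors$position, function(p) {
    col <- which(ref_pos == p & ref_chars != "-")[1]
    if (is.na(col)) "-" else cand_chars[col]
  }, character(1))
  stats::setNames(observed, profile$anchors$name)
}

.expected_set <- function(expected) strsplit(expected, "/", fixed = TRUE)[[1]]

#' Classify a candidate peptidase sequence
#'
#' The candidate is aligned to every profile; the best-scoring profile sets
#' the family call, and activity is decided from the anchor columns:
#' `active` when every catalytic, metal and essential anchor carries an
#' admissible residue; `inactive_homolog` when the catalytic Ser column
#' deviates to a non-catalytic residue while the rest of the triad and
#' metal anchors are intact; `incomplete` otherwise (gaps spanning anchors,
#' or other diagnostic deviations).  S9B candidates are additionally
#' annotated exo-only versus endo-capable from the exopeptidase-determinant
#' column (Asp/Asn there locks exopeptidase-only action; the smaller Ala of
#' FAP permits endopeptidase activity); S9A candidates are annotated with
#' family motif presence.
#'
#' @param candidate Candidate sequence (character scalar) with optional
#'   name used as id.
#' @param profiles List of [anchor_profile()] objects.
#' @param params An [alignment_params()].
#' @param candidate_id Optional id (defaults to the name of `candidate`).
#' @return A `classification_report` list: `candidate_id`, `best_family`,
#'   `best_reference`, `score`, `observed` (named residue vector),
#'   `activity_call`, `notes`.
#' @export
classify <- function(candidate, profiles, params = alignment_params(),
                     candidate_id = NULL) {
  stopifnot(length(profiles) >= 1)
  if (is.null(candidate_id)) {
    candidate_id <- if (!is.null(names(candidate))) names(candidate)[1] else "candidate"
  }
  candidate <- toupper(unname(candidate[1]))

  scores <- vapply(profiles, function(pr) {
    global_align(pr$reference_seq, candidate, params,
                 type = "global-local")$score
  }, numeric(1))
  best <- which.max(scores)
  profile <- profiles[[best]]
  observed <- extract_anchor_residues(candidate, profile, params)

  anc <- profile$anchors
  gating <- anc$role %in% c("catalytic", "metal", "essential")
  match_ok <- vapply(seq_len(nrow(anc)), function(i) {
    observed[i] %in% .expected_set(anc$expected[i])
  }, logical(1))
  gaps <- observed == "-"

  notes <- character(0)
  if (all(match_ok[gating]) && !any(gaps[gating])) {
    activity <- "active"
  } else {
    cat_rows <- which(anc$role == "catalytic")
    ser_row <- cat_rows[1]
    others <- setdiff(which(gating), ser_row)
    if (length(cat_rows) == 3 && !match_ok[ser_row] && !gaps[ser_row] &&
        all(match_ok[others]) && !any(gaps[others])) {
      activity <- "inactive_homolog"
      if (profile$family == "S9B") {
        notes <- c(notes, sprintf("DPP 10-like: catalytic Ser column holds %s",
                                  observed[ser_row]))
      }
    } else {
      activity <- "incomplete"
    }
  }

  if (profile$family == "S9B") {
    det <- which(grepl("^Asp663", anc$name))
    if (length(det) == 1 && observed[det] != "-") {
      notes <- c(notes, if (observed[det] %in% c("D", "N"))
        "exo-only (Asp/Asn at exopeptidase-determinant position)"
        else if (observed[det] == "A")
          "endo-capable (FAP-like Ala at exopeptidase-determinant position)"
        else sprintf("unusual residue %s at exopeptidase-determinant position",
                     observed[det]))
    }
  }
  if (profile$family == "S9A" && length(profile$motifs) > 0) {
    hits <- vapply(profile$motifs, function(m) grepl(m, candidate, fixed = TRUE),
                   logical(1))
    notes <- c(notes, sprintf("S9A motifs present: %d/%d",
                              sum(hits), length(hits)))
  }

  structure(list(candidate_id = candidate_id, best_family = profile$family,
                 best_reference = profile$reference_id,
                 score = scores[[best]], observed = observed,
                 activity_call = activity, notes = notes),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(x$candidate_id, "->", x$best_family,
      paste0("(", x$best_reference, "),"), x$activity_call, "\n")
  cat("  anchors:", paste(names(x$observed), x$observed, sep = "=",
                          collapse = " "), "\n")
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Batch classification to a table
#'
#' @param candidates Named character vector of candidate sequences.
#' @param profiles List of [anchor_profile()]s.
#' @param params An [alignment_params()].
#' @return data.frame with one row per candidate: `candidate_id`, `family`,
#'   `reference`, `activity_call`, `anchors` (observed residues,
#'   comma-separated `name=residue`), `notes`.
#' @export
classify_report <- function(candidates, profiles, params = alignment_params()) {
  rows <- lapply(names(candidates), function(nm) {
    r <- classify(candidates[[nm]], profiles, params, candidate_id = nm)
    data.frame(candidate_id = nm, family = r$best_family,
               reference = r$best_reference,
               activity_call = r$activity_call,
               anchors = paste(names(r$observed), r$observed, sep = "=",
                               collapse = ","),
               notes = paste(r$notes, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Human anchor positions of the studied peptidase families
#'
#' Reference diagnostic residues in human numbering: the catalytic triads
#' and substrate-binding subsites of the serine families (S9A prolyl
#' oligopeptidase, S9B dipeptidyl peptidases, S28 prolyl carboxypeptidase),
#' the Mn-binding sites of the M24B aminopeptidases P / prolidase, and the
#' metal sites of the broad-specificity LAP (M17) and CND (M20).  The S1
#' position Trp659 of DPP 4 admits the Leu/Phe substitutions seen in the
#' insect orthologs.
#'
#' @return data.frame with columns `family`, `reference_id`, `role`,
#'   `name`, `position`, `expected`.
#' @export
psp_anchor_positions <- function() {
  rbind(
    data.frame(family = "S9A", reference_id = "P48147",
               role = "catalytic", name = c("Ser554", "Asp641", "His680"),
               position = c(554, 641, 680), expected = c("S", "D", "H"),
               stringsAsFactors = FALSE),
    data.frame(family = "S9B", reference_id = "P27487",
               role = c("catalytic", "catalytic", "catalytic",
                        "S1", "S1", "S1", "S1", "S1", "S1",
                        "S2", "S2", "S2", "S2", "S1"),
               name = c("Ser630", "Asp708", "His740",
                        "Tyr631", "Val656", "Trp659", "Tyr662", "Tyr666",
                        "Val711", "Asn710", "Arg125", "Glu205", "Glu206",
                        "Asp663"),
               position = c(630, 708, 740, 631, 656, 659, 662, 666, 711,
                            710, 125, 205, 206, 663),
               expected = c("S", "D", "H", "Y", "V", "W/L/F", "Y", "Y", "V",
                            "N", "R", "E", "E", "D/N"),
               stringsAsFactors = FALSE),
    data.frame(family = "S28", reference_id = "P42785",
               role = c("catalytic", "catalytic", "catalytic",
                        "S1", "S1", "S1", "S1"),
               name = c("Ser179", "Asp430", "His455",
                        "Met183", "Trp359", "Met369", "Trp432"),
               position = c(179, 430, 455, 183, 359, 369, 432),
               expected = c("S", "D", "H", "M", "W", "M", "W"),
               stringsAsFactors = FALSE),
    data.frame(family = "M24B", reference_id = "Q9NQW7",
               role = "metal",
               name = c("Asp415", "Asp426", "His489", "Glu523", "Glu537"),
               position = c(415, 426, 489, 523, 537),
               expected = c("D", "D", "H", "E", "E"),
               stringsAsFactors = FALSE),
    data.frame(family = "M17", reference_id = "P28838",
               role = "metal",
               name = c("Lys282", "Asp287", "Lys294", "Asp305", "Asp364",
                        "Glu366", "Arg368"),
               position = c(282, 287, 294, 305, 364, 366, 368),
               expected = c("K", "D", "K", "D", "D", "E", "R"),
               stringsAsFactors = FALSE),
    data.frame(family = "M20", reference_id = "Q96KP4",
               role = "metal",
               name = c("His99", "Asp101", "Asp132", "Glu166", "Glu167",
                        "Asp195", "His228", "His445"),
               position = c(99, 101, 132, 166, 167, 195, 228, 445),
               expected = c("H", "D", "D", "E", "E", "D", "H", "H"),
               stringsAsFactors = FALSE)
  )
}

# S9A family conserved sequence motifs
S9A_MOTIFS <- c("NGGSNGG", "ADHDDRV", "RAGHGAG")

#' Read anchor profiles from a TSV config plus reference FASTA
#'
#' The TSV carries one row per anchor (`family`, `reference_id`, `role`,
#' `name`, `position`, `expected`, optional `motifs` comma-joined on the
#' first row of a family); reference sequences are matched by
#' `reference_id` against the FASTA ids.
#'
#' @param tsv_path Anchor table path.
#' @param fasta_path Reference sequence FASTA path.
#' @return List of [anchor_profile()]s, one per family in the table.
#' @export
read_profiles <- function(tsv_path, fasta_path) {
  df <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  refs <- read_fasta_peptides(fasta_path)
  lapply(split(df, df$family), function(fam) {
    rid <- fam$reference_id[1]
    if (!rid %in% names(refs)) {
      stop("reference sequence '", rid, "' not found in FASTA", call. = FALSE)
    }
    motifs <- if ("motifs" %in% names(fam) && nzchar(fam$motifs[1])) {
      strsplit(fam$motifs[1], ",", fixed = TRUE)[[1]]
    } else character(0)
    anchor_profile(fam$family[1], rid, refs[[rid]],
                   fam[, c("role", "name", "position", "expected")],
                   motifs = motifs)
  })
}
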