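# RPKM expression quantification and active-PSP percentage normalization.
#
# Counting rules: every read contributes exactly one unit in total
# (multireads are counted once, not once per target -- default assignment is
# best alignment score with a lexicographic tie-break; a fractional 1/k
# split is available); a partially aligned contig contributes
# proportionally to the aligned part only when the aligned part exceeds
# half the contig length, otherwise zero.

#' Partial-alignment contig weight
#'
#' @param contig_len Contig length (bases), `> 0`.
#' @param aligned_len Aligned length (bases), `0 <= aligned_len <=
#'   contig_len`.
#' @return `aligned_len / contig_len` when the aligned part exceeds half
#'   the contig length, else 0.  Vectorised.
#' @export
contig_weight <- function(contig_len, aligned_len) {
  if (any(contig_len <= 0)) stop("contig_len must be positive", call. = FALSE)
  if (any(aligned_len < 0) || any(aligned_len > contig_len)) {
    stop("aligned_len must lie in [0, contig_len]", call. = FALSE)
  }
  ifelse(aligned_len > 0.5 * contig_len, aligned_len / contig_len, 0)
}

#' Count read units per contig
#'
#' @param records data.frame of alignment records with columns `read_id`,
#'   `contig_id`, `score` (plus any others); one row per (read, target)
#'   pair, so a read with several rows is a multiread.
#' @param policy `"best"` (default): the whole unit goes to the
#'   best-scoring target, ties to the lexicographically first contig id;
#'   `"fractional"`: 1/k to each of the read's k targets.
#' @return Named numeric vector of units per contig id (zeros kept for
#'   contigs that appear in `records` but win no reads); the units sum to
#'   the number of distinct reads.
#' @export
count_units <- function(records, policy = c("best", "fractional")) {
  policy <- match.arg(policy)
  stopifnot(all(c("read_id", "contig_id", "score") %in% names(records)))
  contigs <- sort(unique(records$contig_id))
  units <- stats::setNames(numeric(length(contigs)), contigs)
  for (rows in split(seq_len(nrow(records)), records$read_id)) {
    if (policy == "best") {
      sc <- records$score[rows]
      best <- rows[sc == max(sc)]
      target <- sort(records$contig_id[best])[1]
      units[target] <- units[target] + 1
    } else {
      k <- length(rows)
      for (r in rows) {
        units[records$contig_id[r]] <- units[records$contig_id[r]] + 1 / k
      }
    }
  }
  units
}

#' Reads per kilobase per million mapped reads
#'
#' @param units Read units assigned to the gene.
#' @param gene_len Gene (contig/mRNA) length in bases, `> 0`.
#' @param total_mapped Total mapped reads in the library, `> 0`.
#' @return RPKM. Vectorised over `units`/`gene_len`.
#' @export
rpkm <- function(units, gene_len, total_mapped) {
  if (any(gene_len <= 0)) stop("gene_len must be positive", call. = FALSE)
  if (any(total_mapped <= 0)) stop("total_mapped must be positive", call. = FALSE)
  units / (gene_len / 1000) / (total_mapped / 1e6)
}

#' Quantify expression from an alignment record table
#'
#' Combines unit counting, partial-alignment weighting and RPKM into one
#' step.  Each read's unit is scaled by the contig weight of its assigned
#' record, so sub-half partial alignments contribute nothing.
#'
#' @param records data.frame with columns `read_id`, `contig_id`, `score`,
#'   `aligned_len`, `contig_len`.
#' @param policy Multiread policy, see [count_units()].
#' @param total_mapped Total mapped reads (default: number of distinct
#'   reads in `records`).
#' @return data.frame with one row per contig: `contig_id`, `length`,
#'   `units`, `rpkm`.
#' @export
quantify <- function(records, policy = c("best", "fractional"),
                     total_mapped = NULL) {
  policy <- match.arg(policy)
  stopifnot(all(c("read_id", "contig_id", "score", "aligned_len",
                  "contig_len") %in% names(records)))
  if (is.null(total_mapped)) total_mapped <- length(unique(records$read_id))
  contigs <- sort(unique(records$contig_id))
  units <- stats::setNames(numeric(length(contigs)), contigs)
  for (rows in split(seq_len(nrow(records)), records$read_id)) {
    if (policy == "best") {
      sc <- records$score[rows]
      best <- rows[sc == max(sc)]
      r <- best[order(records$contig_id[best])][1]
      w <- contig_weight(records$contig_len[r], records$aligned_len[r])
      units[records$contig_id[r]] <- units[records$contig_id[r]] + w
    } else {
      k <- length(rows)
      for (r in rows) {
        w <- contig_weight(records$contig_len[r], records$aligned_len[r])
        units[records$contig_id[r]] <- units[records$contig_id[r]] + w / k
      }
    }
  }
  len <- vapply(contigs, function(cg) {
    max(records$contig_len[records$contig_id == cg])
  }, numeric(1))
  data.frame(contig_id = contigs, length = unname(len),
             units = unname(units),
             rpkm = rpkm(unname(units), unname(len), total_mapped),
             stringsAsFactors = FALSE)
}

# peptidase types never entering the active-PSP normalization: DPP 10 is an
# inactive homolog; LAP and CND cleave post-proline bonds only incidentally
INACTIVE_TYPES <- c("DPP10", "LAP", "CND")

#' Active-PSP percentage shares
#'
#' Expresses each active PSP's RPKM as a percentage of the summed RPKM of
#' all active PSPs (POP, DPP 4, DPP 8, PRCP, APP1-3, XPD).  Inactive
#' homologs (DPP 10) and the broad-specificity LAP and CND are always
#' excluded.  Percentages are rounded to 1 decimal for reporting.
#'
#' @param records data.frame with columns `sequence_name`, `type`
#'   (peptidase type, e.g. `"DPP4"`, `"DPP10"`, `"LAP"`), `rpkm`, and
#'   optionally `active` (logical; defaults to `TRUE` for every type not in
#'   the always-excluded set).
#' @return The input with columns `active` (resolved) and `percent_active`
#'   (rounded to 1 decimal; `NA` for excluded records) added.
#' @export
active_psp_percentages <- function(records) {
  stopifnot(all(c("sequence_name", "type", "rpkm") %in% names(records)))
  if (!"active" %in% names(records)) records$active <- TRUE
  records$active <- records$active & !(records$type %in% INACTIVE_TYPES)
  total <- sum(records$rpkm[records$active], na.rm = TRUE)
  if (!(total > 0)) {
    stop("sum of active-PSP RPKM is zero; percentages undefined",
         call. = FALSE)
  }
  records$percent_active <- ifelse(
    records$active, round(100 * ifelse(is.na(records$rpkm), 0, records$rpkm)
                          / total, 1), NA_real_)
  records
}

#' Midgut fractionation percentages
#'
#' Arithmetic of the localization assay: anterior/posterior split of the
#' total activity and the tissue distribution over the four fractionation
#' compartments.
#'
#' @param am,pm Raw activity in the anterior and posterior midgut
#'   (arbitrary units, `>= 0`, not both zero).
#' @param fractions Named numeric vector of the four fraction activities
#'   (soluble/insoluble contents, soluble/insoluble tissue), `>= 0`, not
#'   all zero.
#' @return List with `am_pct`, `pm_pct` (summing to 100) and `tissue_pct`
#'   (named vector summing to 100).
#' @export
fraction_percentages <- function(am, pm, fractions) {
  stopifnot(am >= 0, pm >= 0, all(fractions >= 0))
  if (am + pm <= 0) stop("total AM+PM activity is zero", call. = FALSE)
  if (sum(fractions) <= 0) stop("total fraction activity is zero", call. = FALSE)
  list(am_pct = 100 * am / (am + pm),
       pm_pct = 100 * pm / (am + pm),
       tissue_pct = 100 * fractions / sum(fractions))
}

#' Read the packaged gut expression fixtures
#'
#' Gut mRNA expression tables (RPKM per PSP/PPCPbs sequence, with peptidase
#' type) for the two tenebrionid species, shipped as TSV under
#' `inst/extdata`.
#'
#' @param species `"tcastaneum"` or `"tmolitor"`.
#' @return data.frame with columns `sequence_name`, `type`, `rpkm`,
#'   `active`.
#' @export
read_expression_fixture <- function(species = c("tcastaneum", "tmolitor")) {
  species <- match.arg(species)
  path <- system.file("extdata", paste0("expression_", species, ".tsv"),
                      package = "pspdigest", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$active <- as.logical(df$active)
  df
}
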