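# Substrate-specificity rules of the digestive peptidase complex.
#
# Each peptidase is encoded as a cleavage rule built from the general
# formulas of the enzyme families, written with the Xaa/Xbb convention:
# Xaa is any amino acid, Xbb any amino acid except Pro.
#
#   CC    post-glutamine endopeptidase        ...Gln | Xbb...
#   POP   prolyl oligopeptidase (endo)        (Xaa)1-15-Xbb-Pro | Xbb-(Xaa)1-15
#   DPP4  dipeptidyl peptidase 4 (N-exo)      Xbb-Pro | Xbb-(Xaa)n
#   DPP8  dipeptidyl peptidase 8 (N-exo)      same formula as DPP 4
#   PRCP  prolyl carboxypeptidase (C-exo)     (Xaa)n-Xbb-Pro | Xbb
#   APP   aminopeptidase P (N-exo)            Xbb | Pro-(Xaa)1-9
#   XPD   prolidase (dipeptidase)             Xbb | Pro
#   LAP   leucyl aminopeptidase (N-exo)       Xaa | Xbb-(Xaa)n
#   CND   cytosolic non-specific dipeptidase  Xaa | Xbb (i.e. not Pro-Pro)
#
# Bond index k (1-based) denotes the peptide bond between residues k and
# k+1; enumerated sites always lie strictly inside the chain.

PSP_ENZYMES <- c("CC", "POP", "DPP4", "DPP8", "PRCP", "APP", "XPD", "LAP", "CND")

#' Construct a cleavage rule
#'
#' @param enzyme Enzyme identifier.
#' @param action One of `"endo"`, `"n_dipeptidyl"`, `"n_mono"`, `"c_mono"`,
#'   `"dipeptidase"`.
#' @param p2_class,p1_class,p1prime_class Residue-class predicates for the
#'   P2, P1 and P1' positions around the scissile bond: one of `"any"`,
#'   `"non_pro"`, `"pro"`, `"gln"`.
#' @param min_len,max_len Substrate length bounds in residues (`Inf` for
#'   unbounded).
#' @param flank_bounds Optional `c(min, max)` residue counts required
#'   N- and C-terminal of the P2..P1' core (used by POP).
#' @return An object of class `cleavage_rule`.
#' @export
cleavage_rule <- function(enzyme, action,
                          p2_class = "any", p1_class = "any",
                          p1prime_class = "any",
                          min_len = 2, max_len = Inf,
                          flank_bounds = NULL) {
  action <- match.arg(action,
                      c("endo", "n_dipeptidyl", "n_mono", "c_mono", "dipeptidase"))
  classes <- c("any", "non_pro", "pro", "gln")
  stopifnot(p2_class %in% classes, p1_class %in% classes,
            p1prime_class %in% classes)
  if (action == "dipeptidase" && !(min_len == 2 && max_len == 2)) {
    stop("dipeptidase rules must have min_len = max_len = 2", call. = FALSE)
  }
  structure(
    list(enzyme = enzyme, action = action,
         p2_class = p2_class, p1_class = p1_class,
         p1prime_class = p1prime_class,
         min_len = min_len, max_len = max_len,
         flank_bounds = flank_bounds),
    class = "cleavage_rule"
  )
}

.class_match <- function(residue, class) {
  switch(class,
         any = TRUE,
         non_pro = residue != "P",
         pro = residue == "P",
         gln = residue == "Q")
}

#' Default rules of the digestive peptidase complex
#'
#' The nine frozen rules covering the post-glutamine endopeptidase stage
#' (CC), the proline-specific peptidases (POP, DPP 4, DPP 8, PRCP, APP,
#' XPD) and the broad-specificity post-proline cleaving peptidases (LAP,
#' CND).
#'
#' @param cc_mode `"post_q"` (default) lets CC cleave after any Gln whose
#'   successor is not Pro; `"qq_only"` restricts CC to Gln-Gln bonds.
#' @return Named list of `cleavage_rule` objects.
#' @export
default_rules <- function(cc_mode = c("post_q", "qq_only")) {
  cc_mode <- match.arg(cc_mode)
  cc_p1prime <- if (cc_mode == "qq_only") "gln" else "non_pro"
  list(
    CC   = cleavage_rule("CC", "endo", p1_class = "gln",
                         p1prime_class = cc_p1prime, min_len = 3),
    POP  = cleavage_rule("POP", "endo", p2_class = "non_pro",
                         p1_class = "pro", p1prime_class = "non_pro",
                         min_len = 5, max_len = 33, flank_bounds = c(1, 15)),
    DPP4 = cleavage_rule("DPP4", "n_dipeptidyl", p2_class = "non_pro",
                         p1_class = "pro", p1prime_class = "non_pro",
                         min_len = 3),
    DPP8 = cleavage_rule("DPP8", "n_dipeptidyl", p2_class = "non_pro",
                         p1_class = "pro", p1prime_class = "non_pro",
                         min_len = 3),
    PRCP = cleavage_rule("PRCP", "c_mono", p2_class = "non_pro",
                         p1_class = "pro", p1prime_class = "non_pro",
                         min_len = 3),
    APP  = cleavage_rule("APP", "n_mono", p1_class = "non_pro",
                         p1prime_class = "pro", min_len = 3, max_len = 11),
    XPD  = cleavage_rule("XPD", "dipeptidase", p1_class = "non_pro",
                         p1prime_class = "pro", min_len = 2, max_len = 2),
    LAP  = cleavage_rule("LAP", "n_mono", p1_class = "any",
                         p1prime_class = "non_pro", min_len = 2),
    CND  = cleavage_rule("CND", "dipeptidase", min_len = 2, max_len = 2)
  )
}

#' Enumerate admissible cleavage sites on a peptide
#'
#' @param rule A `cleavage_rule`.
#' @param seq A single amino acid sequence (character scalar).
#' @return Sorted integer vector of bond indices (bond k lies between
#'   residues k and k+1); empty when the substrate violates the rule's
#'   length bounds or no position matches.
#' @export
applicable_sites <- function(rule, seq) {
  stopifnot(inherits(rule, "cleavage_rule"), is.character(seq),
            length(seq) == 1)
  n <- nchar(seq)
  if (n < rule$min_len || n > rule$max_len) return(integer(0))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]

  candidate <- switch(rule$action,
    endo = seq_len(n - 1),
    n_dipeptidyl = 2L,
    n_mono = 1L,
    c_mono = n - 1L,
    dipeptidase = 1L
  )

  ok <- vapply(candidate, function(k) {
    p1 <- chars[k]
    p1p <- chars[k + 1]
    if (!.class_match(p1, rule$p1_class)) return(FALSE)
    if (!.class_match(p1p, rule$p1prime_class)) return(FALSE)
    if (rule$p2_class != "any") {
      # P2 sits one residue before P1; for exopeptidase actions without a
      # residue at k-1 the constraint is checked only when present
      if (k >= 2 && !.class_match(chars[k - 1], rule$p2_class)) return(FALSE)
      if (k < 2 && rule$action %in% c("endo", "c_mono")) return(FALSE)
    }
    if (rule$action == "dipeptidase" && rule$enzyme == "CND" &&
        p1 == "P" && p1p == "P") return(FALSE)
    if (!is.null(rule$flank_bounds)) {
      # residues strictly outside the P2..P1' core: N flank 1..k-2,
      # C flank k+2..n
      nfl <- k - 2L
      cfl <- n - k - 1L
      if (nfl < rule$flank_bounds[1] || nfl > rule$flank_bounds[2]) return(FALSE)
      if (cfl < rule$flank_bounds[1] || cfl > rule$flank_bounds[2]) return(FALSE)
    }
    TRUE
  }, logical(1))

  sort(unique(as.integer(candidate[ok])))
}

#' Cleave a peptide at a bond
#'
#' @param seq A single amino acid sequence.
#' @param bond Bond index, `1 <= bond < nchar(seq)`.
#' @param id Parent id used to derive fragment ids with 1-based inclusive
#'   coordinates.
#' @return Named character vector of the two fragments (left, right).
#' @export
cleave_at <- function(seq, bond, id = "pep") {
  n <- nchar(seq)
  if (!(bond >= 1 && bond < n)) {
    stop("bond index ", bond, " out of range for length-", n, " peptide",
         call. = FALSE)
  }
  left <- substr(seq, 1, bond)
  right <- substr(seq, bond + 1, n)
  stats::setNames(c(left, right),
                  c(paste0(id, ":1-", bond), paste0(id, ":", bond + 1, "-", n)))
}

#' Serialize cleavage rules to a TSV config
#'
#' @param rules Named list of `cleavage_rule` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_rules_config <- function(rules, path) {
  df <- do.call(rbind, lapply(rules, function(r) {
    data.frame(enzyme = r$enzyme, action = r$action,
               p2_class = r$p2_class, p1_class = r$p1_class,
               p1prime_class = r$p1prime_class,
               min_len = r$min_len, max_len = r$max_len,
               flank_min = if (is.null(r$flank_bounds)) NA else r$flank_bounds[1],
               flank_max = if (is.null(r$flank_bounds)) NA else r$flank_bounds[2],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cleavage rules from a TSV config
#'
#' @param path TSV written by [write_rules_config()] (or hand-authored with
#'   the same columns).
#' @return Named list of `cleavage_rule` objects.
#' @export
read_rules_config <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  rules <- lapply(seq_len(nrow(df)), function(i) {
    fb <- if (is.na(df$flank_min[i])) NULL else c(df$flank_min[i], df$flank_max[i])
    cleavage_rule(df$enzyme[i], df$action[i],
                  p2_class = df$p2_class[i], p1_class = df$p1_class[i],
                  p1prime_class = df$p1prime_class[i],
                  min_len = df$min_len[i],
                  max_len = if (is.na(df$max_len[i])) Inf else df$max_len[i],
                  flank_bounds = fb)
  })
  stats::setNames(rules, df$enzyme)
}
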