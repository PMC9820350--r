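# Seeded generators producing inputs with the statistical structure each
# pipeline stage assumes: gliadin-like Q/P-rich peptides assembled from the
# canonical prolamin repeat motifs, tiling ORF fragments of a known source
# protein with substitution noise, and read-alignment tables with known
# truth RPKM.  All generators are pure functions of their spec (seed
# included): the same spec yields byte-identical output.

# run `expr` under a fixed RNG state without disturbing the caller's RNG
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# canonical gliadin repeat motifs: gamma-gliadin PQQPFPQ, omega-gliadin
# PQQPFPQQ, alpha-gliadin PQPQPFP and PQQPY
GLIADIN_MOTIFS <- c("PQQPFPQ", "PQQPFPQQ", "PQPQPFP", "PQQPY")

#' Specification of a synthetic gliadin-like peptide set
#'
#' Defaults emulate the composition of the natural substrate: prolamin
#' repeat units concatenated between short flanks drawn from non-Q/P
#' residues, with composition caps at the values characteristic of
#' gliadins (up to 50% glutamine; the proline cap is kept slightly above
#' the natural "up to 30%" because the repeat units themselves run at
#' about 44% proline and short flanks dilute them to about a third).
#'
#' @param motifs Character vector of repeat motifs.
#' @param repeats Number of motifs concatenated per peptide.
#' @param flank_len `c(min, max)` residues drawn uniformly for each flank.
#' @param max_q,max_p Composition caps (fractions) validated against the
#'   spec's expected composition; `NULL` disables the check.
#' @param seed RNG seed.
#' @return A `gliadin_spec` list.
#' @export
gliadin_spec <- function(motifs = GLIADIN_MOTIFS, repeats = 3,
                         flank_len = c(2, 6), max_q = 0.5, max_p = 0.35,
                         seed = 1) {
  stopifnot(length(motifs) >= 1, repeats >= 1,
            length(flank_len) == 2, flank_len[1] >= 0,
            flank_len[2] >= flank_len[1])
  spec <- structure(list(motifs = toupper(motifs), repeats = repeats,
                         flank_len = flank_len, max_q = max_q, max_p = max_p,
                         seed = seed),
                    class = "gliadin_spec")
  if (!is.null(max_q) || !is.null(max_p)) .check_composition_caps(spec)
  spec
}

.check_composition_caps <- function(spec) {
  # expected composition: average motif composition diluted by mean flank
  motif_q <- mean(vapply(spec$motifs, residue_fraction, numeric(1), "Q") *
                    nchar(spec$motifs)) /
    mean(nchar(spec$motifs))
  motif_p <- mean(vapply(spec$motifs, residue_fraction, numeric(1), "P") *
                    nchar(spec$motifs)) /
    mean(nchar(spec$motifs))
  core <- spec$repeats * mean(nchar(spec$motifs))
  flank <- 2 * mean(spec$flank_len)
  exp_q <- motif_q * core / (core + flank)
  exp_p <- motif_p * core / (core + flank)
  if (!is.null(spec$max_q) && exp_q > spec$max_q) {
    stop("impossible composition caps: expected Gln fraction ",
         round(exp_q, 3), " exceeds cap ", spec$max_q, call. = FALSE)
  }
  if (!is.null(spec$max_p) && exp_p > spec$max_p) {
    stop("impossible composition caps: expected Pro fraction ",
         round(exp_p, 3), " exceeds cap ", spec$max_p, call. = FALSE)
  }
  invisible(spec)
}

#' Generate gliadin-like peptides
#'
#' @param spec A [gliadin_spec()].
#' @param n Number of peptides (`>= 1`).
#' @return Named character vector of `n` peptides (`glia1`, `glia2`, ...).
#' @export
gen_gliadin_peptides <- function(spec = gliadin_spec(), n = 1) {
  stopifnot(inherits(spec, "gliadin_spec"), n >= 1)
  non_qp <- setdiff(aa_alphabet(), c("Q", "P"))
  .with_seed(spec$seed, {
    flank_range <- seq(spec$flank_len[1], spec$flank_len[2])
    draw_flank <- function() {
      if (length(flank_range) == 1) flank_range else sample(flank_range, 1)
    }
    seqs <- vapply(seq_len(n), function(i) {
      core <- paste(sample(spec$motifs, spec$repeats, replace = TRUE),
                    collapse = "")
      flank_n <- draw_flank()
      flank_c <- draw_flank()
      fl_n <- if (flank_n > 0)
        paste(sample(non_qp, flank_n, replace = TRUE), collapse = "") else ""
      fl_c <- if (flank_c > 0)
        paste(sample(non_qp, flank_c, replace = TRUE), collapse = "") else ""
      paste0(fl_n, core, fl_c)
    }, character(1))
    peptides(seqs, paste0("glia", seq_len(n)))
  })
}

#' Specification of a synthetic tiling-ORF set
#'
#' @param protein_len Length of each true source protein (residues).
#' @param n_proteins Number of unrelated source proteins.
#' @param window ORF window length (residues).
#' @param step Tiling step; `window - step` is the designed overlap, which
#'   must be at least `min_overlap_design`.
#' @param sub_rate Per-residue substitution rate in `[0, 1]`.
#' @param min_overlap_design Overlap the tiling must guarantee (default 10,
#'   matching the clustering threshold).
#' @param seed RNG seed.
#' @return An `orf_sim_spec` list.
#' @export
orf_sim_spec <- function(protein_len = 90, n_proteins = 1, window = 30,
                         step = 15, sub_rate = 0, min_overlap_design = 10,
                         seed = 1) {
  stopifnot(sub_rate >= 0, sub_rate <= 1, window <= protein_len,
            step >= 1)
  if (window - step < min_overlap_design) {
    stop("window - step must be at least ", min_overlap_design,
         " to guarantee clusterable overlaps", call. = FALSE)
  }
  structure(list(protein_len = protein_len, n_proteins = n_proteins,
                 window = window, step = step, sub_rate = sub_rate,
                 seed = seed),
            class = "orf_sim_spec")
}

#' Generate a tiling ORF set with truth labels
#'
#' @param spec An [orf_sim_spec()].
#' @return List with `orfs` (named character vector), `truth` (named
#'   character vector mapping ORF id to source protein id) and `proteins`
#'   (named character vector of the true source sequences).
#' @export
gen_orf_set <- function(spec = orf_sim_spec()) {
  stopifnot(inherits(spec, "orf_sim_spec"))
  .with_seed(spec$seed, {
    alphabet <- aa_alphabet()
    orfs <- character(0)
    truth <- character(0)
    proteins <- character(0)
    for (p in seq_len(spec$n_proteins)) {
      pid <- paste0("prot", p)
      prot <- paste(sample(alphabet, spec$protein_len, replace = TRUE),
                    collapse = "")
      proteins[pid] <- prot
      starts <- seq(1, spec$protein_len - spec$window + 1, by = spec$step)
      if (starts[length(starts)] + spec$window - 1 < spec$protein_len) {
        starts <- c(starts, spec$protein_len - spec$window + 1)
      }
      for (k in seq_along(starts)) {
        frag <- substr(prot, starts[k], starts[k] + spec$window - 1)
        if (spec$sub_rate > 0) {
          chars <- strsplit(frag, "")[[1]]
          hit <- stats::runif(length(chars)) < spec$sub_rate
          chars[hit] <- vapply(which(hit), function(i) {
            sample(setdiff(alphabet, chars[i]), 1)
          }, character(1))
          frag <- paste(chars, collapse = "")
        }
        oid <- paste0(pid, "_orf", k)
        orfs[oid] <- frag
        truth[oid] <- pid
      }
    }
    list(orfs = orfs, truth = truth, proteins = proteins)
  })
}

#' Specification of a synthetic read-alignment table
#'
#' @param gene_len Named numeric vector of gene (contig) lengths in bases.
#' @param true_rpkm Named numeric vector of target expression levels
#'   (same names as `gene_len`).
#' @param total_reads Total reads to draw.
#' @param multiread_frac Fraction of reads given one extra, strictly
#'   worse-scoring target.
#' @param partial_frac Fraction of reads whose record carries a partial
#'   alignment, with aligned fraction drawn uniformly from
#'   `partial_range`.
#' @param partial_range `c(lo, hi)` aligned-length fractions for partial
#'   records.
#' @param seed RNG seed.
#' @return A `read_sim_spec` list.
#' @export
read_sim_spec <- function(gene_len, true_rpkm, total_reads = 10000,
                          multiread_frac = 0, partial_frac = 0,
                          partial_range = c(0.55, 0.95), seed = 1) {
  stopifnot(length(gene_len) == length(true_rpkm),
            identical(names(gene_len), names(true_rpkm)),
            multiread_frac >= 0, multiread_frac <= 1,
            partial_frac >= 0, partial_frac <= 1)
  structure(list(gene_len = gene_len, true_rpkm = true_rpkm,
                 total_reads = total_reads, multiread_frac = multiread_frac,
                 partial_frac = partial_frac, partial_range = partial_range,
                 seed = seed),
            class = "read_sim_spec")
}

#' Generate an alignment-record table with truth RPKM
#'
#' Read counts are a multinomial draw with probabilities proportional to
#' `true_rpkm * gene_len`, so the spec's `true_rpkm` sets relative
#' expression; the absolute RPKM scale is fixed by the library size.  The
#' returned `truth_rpkm` is the RPKM implied by the realized counts (so
#' quantification recovers it exactly in the absence of partial
#' alignments), and `expected_rpkm` is the per-gene expectation of that
#' realized RPKM (`1e9 * true_rpkm / sum(true_rpkm * gene_len)`), to which
#' the realized truth converges as reads grow at the usual root-n rate.
#'
#' @param spec A [read_sim_spec()].
#' @return List with `records` (data.frame: `read_id`, `contig_id`,
#'   `score`, `aligned_len`, `contig_len`), `truth_rpkm`, `expected_rpkm`
#'   and `counts` (realized reads per gene).
#' @export
gen_alignment_table <- function(spec) {
  stopifnot(inherits(spec, "read_sim_spec"))
  genes <- names(spec$gene_len)
  .with_seed(spec$seed, {
    w <- spec$true_rpkm * spec$gene_len
    counts <- as.vector(stats::rmultinom(1, spec$total_reads, w / sum(w)))
    names(counts) <- genes
    gene_of_read <- rep(genes, counts)
    n <- length(gene_of_read)
    read_ids <- sprintf("read%06d", seq_len(n))

    contig_len <- spec$gene_len[gene_of_read]
    aligned_len <- contig_len
    partial <- stats::runif(n) < spec$partial_frac
    aligned_len[partial] <- round(contig_len[partial] *
      stats::runif(sum(partial), spec$partial_range[1], spec$partial_range[2]))

    records <- data.frame(read_id = read_ids, contig_id = gene_of_read,
                          score = 100, aligned_len = unname(aligned_len),
                          contig_len = unname(contig_len),
                          stringsAsFactors = FALSE)

    multi <- which(stats::runif(n) < spec$multiread_frac)
    if (length(multi) > 0 && length(genes) > 1) {
      extra <- lapply(multi, function(i) {
        other <- sample(setdiff(genes, gene_of_read[i]), 1)
        data.frame(read_id = read_ids[i], contig_id = other, score = 50,
                   aligned_len = unname(spec$gene_len[other]),
                   contig_len = unname(spec$gene_len[other]),
                   stringsAsFactors = FALSE)
      })
      records <- rbind(records, do.call(rbind, extra))
      records <- records[order(records$read_id, -records$score), ]
      rownames(records) <- NULL
    }

    truth <- rpkm(counts, spec$gene_len, n)
    expected <- 1e9 * spec$true_rpkm / sum(w)
    list(records = records, truth_rpkm = truth,
         expected_rpkm = expected, counts = counts)
  })
}

#' Synthetic reference profiles for classification
#'
#' The anchor tables of the studied families are keyed to human reference
#' accessions whose sequences are not shipped with the package; this
#' builder creates short synthetic reference sequences carrying the same
#' anchor structure (roles, expected residues, relative order, family
#' motifs) at compact positions, so classification can be exercised and
#' tested end to end without downloads.  Output is deterministic in the
#' seed.
#'
#' @param ref_len Reference length in residues (default 120).
#' @param seed RNG seed.
#' @return Named list of [anchor_profile()] objects, one per family
#'   (S9A, S9B, S28, M24B, M17, M20); reference ids carry a `_synthetic`
#'   suffix.
#' @export
synthetic_reference_profiles <- function(ref_len = 120, seed = 1) {
  anchors_all <- psp_anchor_positions()
  .with_seed(seed, {
    fams <- unique(anchors_all$family)
    profs <- lapply(fams, function(fam) {
      anc <- anchors_all[anchors_all$family == fam, , drop = FALSE]
      anc <- anc[order(anc$position), , drop = FALSE]
      k <- nrow(anc)
      # evenly spaced compact positions preserving the reference order
      pos <- round(seq(15, ref_len - 15, length.out = k))
      chars <- sample(aa_alphabet(), ref_len, replace = TRUE)
      for (i in seq_len(k)) {
        chars[pos[i]] <- .expected_set(anc$expected[i])[1]
      }
      seq <- paste(chars, collapse = "")
      motifs <- character(0)
      if (fam == "S9A") {
        # embed the family motifs in anchor-free space
        motifs <- S9A_MOTIFS
        seq <- paste0(substr(seq, 1, ref_len), paste(motifs, collapse = ""))
      }
      anc$position <- pos
      anchor_profile(fam, paste0(anc$reference_id[1], "_synthetic"),
                     seq, anc[, c("role", "name", "position", "expected")],
                     motifs = motifs)
    })
    stats::setNames(profs, fams)
  })
}
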