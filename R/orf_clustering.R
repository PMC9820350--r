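# Grouping of translated ORF blocks into unique-peptidase clusters.
#
# Two ORFs belong to the same peptidase when they share an overlap of at
# least `min_overlap` residues at no less than `id_threshold` identity;
# clusters are single-linkage components of that graph and each cluster is
# summarised by a majority-vote consensus laid out by progressive overlap
# alignment.  Identity is computed from an ends-free (overlap) alignment;
# the denominator counts all alignment columns between the first and last
# doubly-covered column, so internal gaps count against identity (a
# documented, switchable choice).

#' Identity and overlap length of two sequences
#'
#' Ends-free (overlap) global alignment: terminal overhangs are free, so
#' tiling fragments of a common source score on their shared block only.
#'
#' @param a,b Amino acid sequences (character scalars).
#' @param params An [alignment_params()].
#' @param count_gap_columns Count internal gap columns in the identity
#'   denominator (default `TRUE`).
#' @return Named numeric vector `c(identity, overlap)`: `identity` the
#'   match fraction over the overlap, `overlap` the number of columns in
#'   which both sequences carry a residue; `c(0, 0)` when no column is
#'   doubly covered.
#' @export
overlap_identity <- function(a, b, params = alignment_params(),
                             count_gap_columns = TRUE) {
  stopifnot(nzchar(a), nzchar(b))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
    type = "overlap", substitutionMatrix = .subst_matrix(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  both <- which(pa != "-" & pb != "-")
  if (length(both) == 0) {
    return(c(identity = 0, overlap = 0))
  }
  region <- seq(min(both), max(both))
  overlap <- length(both)
  matches <- sum(pa[both] == pb[both])
  denom <- if (count_gap_columns) length(region) else overlap
  c(identity = matches / denom, overlap = overlap)
}

#' Cluster ORFs into unique-peptidase blocks
#'
#' Single-linkage components over the graph with an edge between two ORFs
#' when their overlap identity and overlap length both reach the
#' thresholds.
#'
#' @param orfs Named character vector of translated ORF sequences.
#' @param id_threshold Minimum identity fraction (default 0.95).
#' @param min_overlap Minimum overlap in residues (default 10).
#' @param params An [alignment_params()].
#' @return List of clusters ordered by smallest member id; each cluster is
#'   a list with `members` (ids), `pairs` (data.frame `id_a`, `id_b`,
#'   `identity`, `overlap` of the edges found) and `consensus` (named
#'   character scalar, see [orf_consensus()]).
#' @export
cluster_orfs <- function(orfs, id_threshold = 0.95, min_overlap = 10,
                         params = alignment_params()) {
  stopifnot(id_threshold > 0, id_threshold <= 1, min_overlap >= 1)
  n <- length(orfs)
  ids <- names(orfs)
  pairs <- list()
  edges <- integer(0)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        oi <- overlap_identity(orfs[[i]], orfs[[j]], params)
        if (oi[["overlap"]] >= min_overlap &&
            oi[["identity"]] >= id_threshold) {
          edges <- c(edges, i, j)
          pairs[[length(pairs) + 1]] <- data.frame(
            id_a = ids[i], id_b = ids[j],
            identity = oi[["identity"]], overlap = oi[["overlap"]],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  pairs_df <- if (length(pairs) > 0) do.call(rbind, pairs) else
    data.frame(id_a = character(), id_b = character(),
               identity = numeric(), overlap = numeric(),
               stringsAsFactors = FALSE)

  clusters <- lapply(split(seq_len(n), comp), function(idx) {
    members <- ids[idx]
    cl_pairs <- pairs_df[pairs_df$id_a %in% members &
                           pairs_df$id_b %in% members, , drop = FALSE]
    list(members = members, pairs = cl_pairs,
         consensus = orf_consensus(orfs[idx], params = params))
  })
  # deterministic ordering by smallest member id
  ord <- order(vapply(clusters, function(cl) min(cl$members), character(1)))
  unname(clusters[ord])
}

#' Consensus sequence of a cluster of overlapping ORFs
#'
#' Members are laid out by progressive pairwise overlap alignment against
#' the growing scaffold, longest member first.  Each scaffold column takes
#' the majority residue; ties go to the residue contributed by the longest
#' covering member; columns covered by a single member take that member's
#' residue.  A member with no alignable overlap against the scaffold is
#' skipped with a warning, so the consensus covers the largest consistent
#' subset.
#'
#' @param orfs Named character vector of member sequences.
#' @param params An [alignment_params()].
#' @return Named character scalar (name `"consensus"` prefixed by the first
#'   member id).
#' @export
orf_consensus <- function(orfs, params = alignment_params()) {
  stopifnot(length(orfs) >= 1)
  ord <- order(-nchar(orfs), names(orfs))
  orfs <- orfs[ord]
  label <- paste0(names(orfs)[1], "_consensus")
  if (length(orfs) == 1) {
    return(stats::setNames(unname(orfs[1]), label))
  }

  # offsets[i]: 0-based start of member i in scaffold coordinates
  offsets <- c(0L)
  placed <- 1L
  scaffold <- unname(orfs[[1]])
  scaff_off <- 0L  # scaffold coordinate of scaffold[1]

  for (i in seq(2, length(orfs))) {
    m <- unname(orfs[[i]])
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(scaffold), Biostrings::AAString(m),
      type = "overlap", substitutionMatrix = .subst_matrix(params),
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    w <- Biostrings::nchar(Biostrings::pattern(aln))
    if (w == 0) {
      warning("ORF '", names(orfs)[i],
              "' has no alignable overlap with the cluster scaffold; skipped")
      offsets <- c(offsets, NA_integer_)
      next
    }
    sp <- Biostrings::start(Biostrings::pattern(aln))  # in scaffold
    ss <- Biostrings::start(Biostrings::subject(aln))  # in member
    off <- scaff_off + (sp - 1L) - (ss - 1L)
    offsets <- c(offsets, off)
    placed <- c(placed, i)
    # grow the scaffold string to cover the new member
    lo <- min(scaff_off, off)
    hi <- max(scaff_off + nchar(scaffold), off + nchar(m))
    new_scaffold <- strsplit(strrep("-", hi - lo), "")[[1]]
    new_scaffold[(scaff_off - lo + 1):(scaff_off - lo + nchar(scaffold))] <-
      strsplit(scaffold, "")[[1]]
    mm <- strsplit(m, "")[[1]]
    idx <- (off - lo + 1):(off - lo + nchar(m))
    fill <- new_scaffold[idx] == "-"
    new_scaffold[idx[fill]] <- mm[fill]
    scaffold <- paste(new_scaffold, collapse = "")
    scaff_off <- lo
  }

  # column-wise majority vote over the placed members
  lo <- min(offsets[placed])
  hi <- max(offsets[placed] + nchar(orfs[placed]))
  width <- hi - lo
  cons <- character(width)
  for (col in seq_len(width)) {
    pos <- lo + col - 1L  # 0-based scaffold coordinate
    votes <- character(0)
    for (i in placed) {
      k <- pos - offsets[i] + 1L
      if (k >= 1 && k <= nchar(orfs[[i]])) {
        votes <- c(votes, substr(orfs[[i]], k, k))
      }
    }
    tab <- table(votes)
    top <- names(tab)[tab == max(tab)]
    # ties broken by the earliest (longest) covering member's residue
    cons[col] <- if (length(top) == 1) top else {
      first <- votes[votes %in% top][1]
      first
    }
  }
  stats::setNames(paste(cons, collapse = ""), label)
}

#' Optional ORF length filter
#'
#' Retains ORFs covering at least `min_frac` of their source mRNA length, a
#' coding-sequence plausibility filter applied upstream of clustering when
#' mRNA lengths are known.
#'
#' @param orfs Named character vector of ORF sequences.
#' @param mrna_len Named numeric vector of source mRNA lengths in
#'   nucleotides (names matching `orfs`).
#' @param min_frac Minimum fraction of the mRNA covered by the coding
#'   region (default 0.2).
#' @return The retained subset of `orfs`.
#' @export
filter_orfs_by_coverage <- function(orfs, mrna_len, min_frac = 0.2) {
  stopifnot(all(names(orfs) %in% names(mrna_len)))
  keep <- (3 * nchar(orfs)) / mrna_len[names(orfs)] >= min_frac
  orfs[keep]
}
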