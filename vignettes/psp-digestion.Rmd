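---
title: "Methods: rule-based gliadin digestion and PSP complex analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based gliadin digestion and PSP complex analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pspdigest)
```

# The model

Gliadins — the wheat prolamins that are the main dietary protein of
tenebrionid stored-product pests — are so rich in glutamine (up to ~50%)
and proline (up to ~30%) that broad-specificity peptidases cannot finish
their hydrolysis: proline's imino-acid conformation protects its bonds.
Degradation requires a *complex*: post-glutamine cleaving endopeptidases
(cysteine cathepsins, CC) to open the chain, then proline-specific
exopeptidases (PSPs) to trim the Pro-rich products, then dipeptidases to
finish. `pspdigest` models that complex as a set of positional cleavage
rules applied by a staged, deterministic engine, alongside the supporting
analyses used to characterise such a complex: diagnostic-residue
classification of candidate peptidase sequences, clustering of translated
ORF blocks into unique peptidases, and RPKM-based expression comparison.

## Cleavage rules

Each enzyme's substrate specificity is a general formula over residue
classes (Xaa any residue; Xbb any residue but Pro), encoded as a
`cleavage_rule` with an action mode, P2/P1/P1′ class predicates, substrate
length bounds, and optional flank bounds:

| enzyme | action | admissible sites |
|---|---|---|
| CC | endo | after Gln, successor ≠ Pro, length ≥ 3 |
| POP | endo | Xbb-Pro↓Xbb core with 1–15 residues strictly outside it on each side (length 5–33) |
| DPP 4, DPP 8 | N-dipeptidyl | bond 2 only: pos1 ≠ Pro, pos2 = Pro, pos3 ≠ Pro |
| PRCP | C-mono | bond n−1 only: antepenultimate ≠ Pro, penultimate = Pro, terminal ≠ Pro |
| APP | N-mono | bond 1: pos1 ≠ Pro, pos2 = Pro, length 3–11 |
| XPD | dipeptidase | Xbb-Pro dipeptides only |
| LAP | N-mono | any pos1, pos2 ≠ Pro, length ≥ 2 |
| CND | dipeptidase | any dipeptide except Pro-Pro |

Choices made where the formulas are open:

* **CC mode.** CC most effectively cleaves between two glutamines but can
  cleave after Gln generally, sparing Gln-Pro bonds (proline bonds belong
  to the PSPs). The default rule is the general post-Gln form
  (`cc_mode = "post_q"`); `"qq_only"` restricts to Gln↓Gln. On the worked
  26-mer both modes yield the identical site set {5, 10, 13, 18, 21} —
  tested.
* **POP flanks.** The subscripts in (Xaa)₁₋₁₅ are read as 1–15 residues
  *strictly outside* the Xbb-Pro↓Xbb core, so POP substrates are 5–33
  residues and the scissile Pro is never within two residues of a
  terminus. A zero-length flank reading would admit shorter substrates;
  we require ≥ 1 (the literal subscript) and note the alternative here.
* **APP length.** Xbb↓Pro(Xaa)₁₋₉ is read as total length 3–11.
* **PRCP.** The formula's Xbb at the antepenultimate position is enforced
  (non-Pro), though tolerance there is not documented beyond the formula.
* **Indexing.** Bond *k* (1-based) is the bond between residues *k* and
  *k*+1; fragment ids carry 1-based inclusive coordinates derived from
  the parent.

## The staged digestion engine

`digest()` applies an `enzyme_panel` — ordered stages of ordered enzyme
lists — to a fixed point. Within a stage, the first applicable
(enzyme, fragment, site) fires: lowest enzyme priority first, then
fragment queue order, then lowest bond index. The narrative scheme orders
CC, then DPP 4, then PRCP, then XPD but never defines concurrency;
a fixed priority makes outputs reproducible and testable. Confluence
under within-stage reordering is *probed* (a shuffled-order panel is
compared in the tests, with residue conservation required either way) but
never assumed: the priority order is the contract. Fragments of length 1
move immediately to the free-residue pool and are never substrates.
Two invariants hold by construction and are property-tested over seeded
synthetic peptides: the residue multiset of input equals residuals ∪ free
residues, and each event splits one fragment in two, so events ≤ length−1.

The default panel is the three-stage luminal/epithelial scheme
(CC → DPP 4 + PRCP → XPD). The extended panel adds the remaining complex
members — POP beside CC; DPP 8, APP and LAP in the exopeptidase stage;
CND beside XPD. On QLQPFPQPQLPY the default panel strands the
proline-locked fragment LQPFPQP, while the extended complex frees all 12
residues — the engine reproduces both behaviours. Compartment labels
(lumen/epithelium) are annotations only and do not gate chemistry.

On tripeptides such as QPQ both DPP 4 and PRCP can act (QP + Q either
way); stage listing order assigns the event to DPP 4 when both share a
stage, and the product set is identical — the narrative's attribution to
PRCP is an ordering, not an outcome, difference.

`assess_residuals()` closes the loop: digestion is *complete* when every
residual is a free residue or on the non-immunogenic allowlist (default
{FLQP}, the known non-immunogenic endpoint of the 26-mer scheme).

## Classification by diagnostic residues

Candidates are aligned pairwise to reference profiles
(`anchor_profile`): the reference is globally aligned while the
candidate's terminal overhangs are free (Biostrings `"global-local"`,
BLOSUM62, gap open 10 / extend 1), which makes anchor read-off invariant
to N/C-terminal extensions — property-tested. Pairwise alignment against
each reference replaces the multiple alignment a full study would use; it
is sufficient for residue read-off and fully specified. Activity calls:

* `active` — all catalytic, metal and essential anchors carry admissible
  residues (expected sets admit documented synonymous substitutions, e.g.
  the DPP 4 S1 Trp659 admits W/L/F);
* `inactive_homolog` — the catalytic Ser column deviates to a residue
  (not a gap) while the rest of the triad and metal anchors are intact —
  the DPP 10 situation (Gly for Ser630), noted as "DPP 10-like" for S9B;
* `incomplete` — anything else (gaps spanning anchors, mutated metal
  sites).

Substrate-binding subsite anchors (S1/S2) never gate the activity call —
they vary synonymously among active orthologs. The S9B
exopeptidase-determinant column (Asp663 in the reference numbering) is
likewise non-gating: Asp/Asn there annotates exo-only action, a FAP-like
Ala annotates endopeptidase capability. S9A candidates are annotated with
family motif (NGGSNGG, ADHDDRV, RAGHGAG) presence.

Real reference sequences are database accessions not shipped with the
package; `psp_anchor_positions()` provides the human-numbered anchor
table for users who supply them, and `synthetic_reference_profiles()`
builds deterministic synthetic references with the same anchor structure
at compact positions — these are what the tests and the acceptance script
classify, and they are labelled `_synthetic` throughout.

## ORF block clustering and consensus

`overlap_identity()` uses an ends-free (overlap) alignment; overlap is
the number of doubly-covered columns, and identity divides matches by all
columns between the first and last doubly-covered column, so internal
gaps count against identity (the denominator choice is not dictated by
the block semantics; `count_gap_columns = FALSE` switches it).
`cluster_orfs()` draws an edge at identity ≥ 0.95 and overlap ≥ 10
residues and takes single-linkage components ("grouped into blocks"
implies transitivity). Boundary behaviour is pinned by tests: one
mismatch in a 20-residue overlap (0.95) merges, two (0.90) do not, and a
9-residue identical overlap does not.

`orf_consensus()` lays members out by progressive overlap alignment
against a growing scaffold, longest member first, then votes per column:
majority residue, ties to the longest covering member, single-covered
columns taken as-is. A member with no alignable overlap is skipped with a
warning (consensus of the largest consistent subset). Offsets come from
alignment starts, which is exact for the substitution-only error model
the generator produces; indel-bearing data would need column-level
layout. On error-free tilings the consensus equals the source protein
exactly; at ≤1% substitution the consensus mismatch rate on ≥3×-covered
columns is ≤0.2% (seeded test; tiling *ends* are 1×-covered and carry the
raw substitution rate, which is why the bound is stated for ≥3×
coverage).

## Expression quantification

* `contig_weight(len, aligned)` — a partial alignment contributes
  proportionally to the aligned part only when it exceeds half the contig
  length, else zero (only the >50% branch is defined; exactly half is
  "not more than half").
* `count_units()` — each read contributes exactly one unit in total;
  multireads are counted once, assigned to the best-scoring target with a
  lexicographic tie-break (a fractional 1/k policy is available since
  "counted as one unit" is ambiguous between the two readings).
* `rpkm(units, len, total)` = units / (len/1000) / (total/10⁶).
* `active_psp_percentages()` — shares of the summed RPKM over active PSPs
  only (POP, DPP 4, DPP 8, PRCP, APP1–3, XPD); DPP 10 (inactive homolog)
  and the broad-specificity LAP and CND are always excluded; reported at
  1 decimal, so the shares sum to 100 ± 0.3 after rounding.
* `fraction_percentages()` — anterior/posterior midgut split and
  four-fraction tissue distribution, each summing to 100.

## Synthetic data: what it emulates and what it does not

The generators are pure functions of their spec, seed included.

* `gen_gliadin_peptides()` concatenates prolamin repeat motifs (PQQPFPQ,
  PQQPFPQQ, PQPQPFP, PQQPY; defaults: 3 motifs, flanks of 2–6 non-Q/P
  residues per side) to emulate gliadin-like composition: mean Gln ≤ 0.5
  and mean Pro ≤ 0.35 across a generated set. The Pro cap sits slightly
  above the natural "up to 30%" because the repeat units themselves run
  at ~44% proline and the short flanks dilute them to about a third.
  Caps are validated on the spec's expected composition at construction
  time (an infeasible cap errors), not enforced per peptide — individual
  draws scatter around the mean. Flanks avoid Q/P so that composition
  stays controlled by the motif mix.
* `gen_orf_set()` tiles a uniformly random protein with fixed windows and
  step (geometry guarantees clusterable ≥10-residue overlaps) and applies
  i.i.d. substitutions. Real ORF sets have indels, uneven coverage and
  biased amino-acid composition; none of that is simulated, so passing
  clustering tests demonstrate threshold/consensus logic, not robustness
  to assembler artefacts.
* `gen_alignment_table()` draws per-gene read counts from a multinomial
  with probabilities ∝ rpkm × length: the spec's `true_rpkm` sets
  relative abundance and the absolute scale follows the library size, so
  the generator returns both `truth_rpkm` (implied by realized counts;
  recovered *exactly* by `quantify()` on clean tables, and still exactly
  under multireads with unique best targets) and `expected_rpkm` (its
  expectation, approached at the usual √n rate). Multireads get one extra
  strictly worse-scoring target; partial records draw an aligned fraction
  from 0.55–0.95. No sequencing errors, quality scores or nucleotide
  reads are simulated.

## Numerical and degenerate-input choices

* Residue alphabet is exactly the 20 standard codes; B/J/X/Z/U/O are
  rejected with record and position — the cleavage formulas are undefined
  over ambiguity codes.
* Masses use standard average residue masses with water 18.02 Da, frozen
  as package constants; the empty chain (allowed only in `average_mass()`)
  returns the water mass. Reported to 2 decimals; additivity holds to
  1e-6 Da.
* Alignment tie-breaking is delegated to Biostrings' deterministic
  dynamic programming; identical inputs give identical alignments.
* Problem sizes in tests and the acceptance script (1,000 synthetic
  peptides for digestion invariants, 90–120-residue proteins with 30–40
  residue windows for clustering, 4–5k reads for quantification) were
  chosen as the smallest sets that exercise every rule branch and give
  stable stochastic bounds.

## Known limitations

* No kinetics: rules are all-or-none; no kcat/Km, pH optima, enzyme
  amounts or time courses, so the engine cannot reproduce hydrolysis
  rate measurements — only endpoint fragment sets.
* The within-stage priority order is a modelling convention; where the
  rule system is non-confluent, different orders can yield different
  intermediate routes (conservation always holds).
* Consensus building assumes substitution-only divergence between
  overlapping ORFs.
* Percentage normalization inherits whatever is in the RPKM column; it
  does not model library composition effects between species.
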