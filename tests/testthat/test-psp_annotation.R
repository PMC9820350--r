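profiles <- synthetic_reference_profiles(seed = 1)
s9b <- profiles[["S9B"]]
ser_pos <- s9b$anchors$position[s9b$anchors$role == "catalytic"][1]

test_that("global alignment handles identity, substitutions and forced gaps", {
  a <- "MKVLQSTPWR"
  aln <- global_align(a, a)
  expect_identical(aln$aligned_a, a)
  expect_identical(aln$aligned_b, a)

  b <- "MKVLQSTPWK"  # one substitution, no gaps in the optimum
  aln2 <- global_align(a, b)
  expect_false(grepl("-", aln2$aligned_a, fixed = TRUE))
  expect_false(grepl("-", aln2$aligned_b, fixed = TRUE))
  chars_a <- strsplit(aln2$aligned_a, "")[[1]]
  chars_b <- strsplit(aln2$aligned_b, "")[[1]]
  expect_identical(sum(chars_a == chars_b), 9L)

  aln3 <- global_align("A", "AA")
  expect_identical(nchar(aln3$aligned_a), 2L)
  expect_identical(sum(strsplit(aln3$aligned_a, "")[[1]] == "-"), 1L)
})

test_that("anchor extraction reads the reference residues off a candidate", {
  obs <- extract_anchor_residues(s9b$reference_seq, s9b)
  expected_first <- vapply(strsplit(s9b$anchors$expected, "/"),
                           `[`, character(1), 1)
  expect_identical(unname(obs), expected_first)

  # N/C-terminal extensions do not disturb anchor read-off
  padded <- paste0("MGGT", s9b$reference_seq, "KKLV")
  expect_identical(extract_anchor_residues(padded, s9b), obs)

  # a deletion spanning an anchor reports a gap
  del <- paste0(substr(s9b$reference_seq, 1, ser_pos - 3),
                substr(s9b$reference_seq, ser_pos + 3,
                       nchar(s9b$reference_seq)))
  obs_del <- extract_anchor_residues(del, s9b)
  expect_true("-" %in% obs_del)
})

test_that("every packaged synthetic reference self-classifies active", {
  for (fam in names(profiles)) {
    r <- classify(profiles[[fam]]$reference_seq, profiles,
                  candidate_id = fam)
    expect_identical(r$best_family, fam)
    expect_identical(r$activity_call, "active")
  }
})

test_that("catalytic Ser -> Gly gives an inactive homolog (DPP 10-like)", {
  cand <- s9b$reference_seq
  substr(cand, ser_pos, ser_pos) <- "G"
  r <- classify(cand, profiles)
  expect_identical(r$best_family, "S9B")
  expect_identical(r$activity_call, "inactive_homolog")
  expect_true(any(grepl("DPP 10-like", r$notes)))
})

test_that("a mutated metal anchor or an anchor-spanning gap is incomplete", {
  m24 <- profiles[["M24B"]]
  pos <- m24$anchors$position[1]
  cand <- m24$reference_seq
  substr(cand, pos, pos) <- "A"
  expect_identical(classify(cand, profiles)$activity_call, "incomplete")

  del <- paste0(substr(s9b$reference_seq, 1, ser_pos - 2),
                substr(s9b$reference_seq, ser_pos + 2,
                       nchar(s9b$reference_seq)))
  expect_identical(classify(del, profiles)$activity_call, "incomplete")
})

test_that("point mutations at non-anchor positions never change the call", {
  set.seed(17)
  anchor_pos <- s9b$anchors$position
  free_pos <- setdiff(seq_len(nchar(s9b$reference_seq)), anchor_pos)
  for (p in sample(free_pos, 12)) {
    cand <- s9b$reference_seq
    old <- substr(cand, p, p)
    substr(cand, p, p) <- sample(setdiff(aa_alphabet(), old), 1)
    r <- classify(cand, profiles)
    expect_identical(r$best_family, "S9B")
    expect_identical(r$activity_call, "active")
  }
})

test_that("S9B reports exo/endo determinant and S9A reports motifs", {
  r <- classify(s9b$reference_seq, profiles)
  expect_true(any(grepl("exo-only", r$notes)))

  det_pos <- s9b$anchors$position[grepl("^Asp663", s9b$anchors$name)]
  fap_like <- s9b$reference_seq
  substr(fap_like, det_pos, det_pos) <- "A"
  # the determinant does not gate activity: a FAP-like Ala stays active
  # but gains endopeptidase capability in the notes
  r2 <- classify(fap_like, profiles)
  expect_identical(r2$activity_call, "active")
  expect_true(any(grepl("endo-capable", r2$notes)))

  s9a <- profiles[["S9A"]]
  r3 <- classify(s9a$reference_seq, profiles)
  expect_true(any(grepl("S9A motifs present: 3/3", r3$notes)))
})

test_that("profiles round-trip through the TSV + FASTA interface", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".fasta")
  anc <- psp_anchor_positions()
  df <- do.call(rbind, lapply(names(profiles), function(fam) {
    p <- profiles[[fam]]
    cbind(data.frame(family = fam, reference_id = p$reference_id,
                     stringsAsFactors = FALSE),
          p$anchors,
          motifs = paste(p$motifs, collapse = ","))
  }))
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  refs <- vapply(profiles, function(p) p$reference_seq, character(1))
  names(refs) <- vapply(profiles, function(p) p$reference_id, character(1))
  write_fasta_peptides(refs, fa)
  back <- read_profiles(tsv, fa)
  expect_setequal(names(back), names(profiles))
  rpt <- classify_report(refs[1:2], back)
  expect_identical(rpt$activity_call, c("active", "active"))
})

test_that("anchor profiles validate their structure", {
  expect_error(anchor_profile("S9B", "x", "MKV",
                              data.frame(role = "catalytic", name = "S",
                                         position = 10, expected = "S")),
               "outside reference")
  expect_error(anchor_profile("S9B", "x", strrep("A", 50),
                              data.frame(role = "catalytic",
                                         name = c("S", "D"),
                                         position = c(5, 10),
                                         expected = c("S", "D"))),
               "three catalytic anchors")
})
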