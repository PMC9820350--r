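# printed gut-expression percentages used as frozen expected values
tc_expected <- c(POP_Tc = 0.0, DPP4.1_Tc = 25.1, DPP4.2_Tc = 7.9,
                 DPP8_Tc = 1.1, PRCP.1_Tc = 0.4, PRCP.2_Tc = 10.0,
                 APP1.1_Tc = 35.9, APP1.2_Tc = 0.1, APP3_Tc = 0.9,
                 XPD_Tc = 18.6)
tm_expected <- c(POP_Tm = 4.2, DPP4.1_Tm = 24.6, DPP4.2_Tm = 17.1,
                 DPP8_Tm = 3.3, PRCP_Tm = 8.9, APP1_Tm = 14.7,
                 APP2_Tm = 0.5, APP3_Tm = 2.0, XPD_Tm = 24.7)

test_that("contig weight implements the >50% partial-alignment rule", {
  expect_equal(contig_weight(1000, 1000), 1.0)
  expect_equal(contig_weight(1000, 800), 0.8)
  expect_equal(contig_weight(1000, 400), 0)
  expect_equal(contig_weight(1000, 500), 0)  # exactly half is not "more than"
  expect_equal(contig_weight(c(1000, 1000), c(800, 400)), c(0.8, 0))
  expect_error(contig_weight(0, 0), "positive")
  expect_error(contig_weight(1000, 1200), "aligned_len")
  expect_error(contig_weight(1000, -1), "aligned_len")
})

test_that("unit counting conserves reads and breaks ties lexicographically", {
  rec <- data.frame(read_id = paste0("r", 1:10), contig_id = "c1", score = 60)
  expect_equal(count_units(rec), c(c1 = 10))

  multi <- data.frame(read_id = c("r1", "r1"), contig_id = c("c2", "c1"),
                      score = c(60, 60))
  expect_equal(count_units(multi), c(c1 = 1, c2 = 0))
  expect_equal(count_units(multi, policy = "fractional"),
               c(c1 = 0.5, c2 = 0.5))

  best <- data.frame(read_id = c("r1", "r1"), contig_id = c("c2", "c1"),
                     score = c(80, 60))
  expect_equal(count_units(best), c(c1 = 0, c2 = 1))

  set.seed(19)
  rec2 <- data.frame(read_id = rep(paste0("r", 1:50),
                                   times = sample(1:3, 50, TRUE)))
  rec2$contig_id <- sample(paste0("c", 1:5), nrow(rec2), TRUE)
  rec2$score <- sample(50:100, nrow(rec2), TRUE)
  expect_equal(sum(count_units(rec2)), 50)
  expect_equal(sum(count_units(rec2, policy = "fractional")), 50)
})

test_that("rpkm is the unit/kilobase/million normalization", {
  expect_equal(rpkm(1000, 1000, 1e6), 1000)
  expect_equal(rpkm(147, 1000, 1e6), 147)
  expect_equal(rpkm(2 * 147, 1000, 2 * 1e6), 147)  # scale invariance
  expect_equal(rpkm(10, 500, 1e6), rpkm(10, 1000, 1e6) * 2)  # 1/length
  expect_error(rpkm(1, 0, 1e6), "gene_len")
  expect_error(rpkm(1, 1000, 0), "total_mapped")
})

test_that("active-PSP percentages reproduce both printed expression columns", {
  for (case in list(list(sp = "tcastaneum", exp = tc_expected),
                    list(sp = "tmolitor", exp = tm_expected))) {
    df <- active_psp_percentages(read_expression_fixture(case$sp))
    got <- stats::setNames(df$percent_active, df$sequence_name)
    expect_equal(got[names(case$exp)], case$exp)
    # excluded types never receive a share
    expect_true(all(is.na(df$percent_active[df$type %in%
                                              c("DPP10", "LAP", "CND")])))
    # shares sum to 100 within 1-decimal rounding slack
    expect_lt(abs(sum(df$percent_active, na.rm = TRUE) - 100), 0.3)
  }
})

test_that("single active gene takes 100% and all-zero sums are an error", {
  one <- data.frame(sequence_name = "XPD_x", type = "XPD", rpkm = 5,
                    active = TRUE)
  expect_equal(active_psp_percentages(one)$percent_active, 100.0)
  zero <- data.frame(sequence_name = "XPD_x", type = "XPD", rpkm = 0,
                     active = TRUE)
  expect_error(active_psp_percentages(zero), "zero")
})

test_that("fractionation percentages sum to 100", {
  fp <- fraction_percentages(60, 40, c(sc = 25, ic = 25, st = 25, it = 25))
  expect_equal(fp$am_pct, 60)
  expect_equal(fp$pm_pct, 40)
  expect_equal(unname(fp$tissue_pct), c(25, 25, 25, 25))

  set.seed(23)
  for (i in 1:10) {
    x <- runif(2, 0.01, 10)
    f <- runif(4, 0.01, 10)
    fp <- fraction_percentages(x[1], x[2], f)
    expect_equal(fp$am_pct + fp$pm_pct, 100, tolerance = 1e-9)
    expect_equal(sum(fp$tissue_pct), 100, tolerance = 1e-9)
  }
  expect_error(fraction_percentages(0, 0, c(1, 1, 1, 1)), "zero")
})

test_that("quantification recovers simulated truth", {
  genes <- stats::setNames(c(1000, 1500, 2000, 800), paste0("g", 1:4))
  truth <- stats::setNames(c(100, 50, 25, 200), names(genes))

  # clean table: exact recovery
  sim <- gen_alignment_table(read_sim_spec(genes, truth, total_reads = 4000,
                                           seed = 11))
  q <- quantify(sim$records)
  expect_equal(stats::setNames(q$rpkm, q$contig_id)[names(genes)],
               sim$truth_rpkm)

  # multireads with unique best targets: still exact under best-score policy
  sim2 <- gen_alignment_table(read_sim_spec(genes, truth, total_reads = 4000,
                                            multiread_frac = 0.2, seed = 12))
  q2 <- quantify(sim2$records)
  expect_equal(stats::setNames(q2$rpkm, q2$contig_id)[names(genes)],
               sim2$truth_rpkm)

  # partial alignments only lower units, never raise them
  sim3 <- gen_alignment_table(read_sim_spec(genes, truth, total_reads = 4000,
                                            partial_frac = 0.3, seed = 13))
  q3 <- quantify(sim3$records)
  expect_true(all(q3$rpkm <= sim3$truth_rpkm[q3$contig_id] + 1e-9))
  expect_true(all(q3$rpkm >= 0.5 * sim3$truth_rpkm[q3$contig_id]))

  # generator determinism
  sim_b <- gen_alignment_table(read_sim_spec(genes, truth,
                                             total_reads = 4000, seed = 11))
  expect_identical(sim$records, sim_b$records)
})
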