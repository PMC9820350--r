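# deterministic sequences for the boundary checks
set.seed(5)
base40 <- paste(sample(aa_alphabet(), 40, TRUE), collapse = "")

test_that("overlap identity is exact on constructed overlaps", {
  a <- substr(base40, 1, 20)
  expect_equal(overlap_identity(a, a), c(identity = 1, overlap = 20))

  # 10-residue identical suffix/prefix, remainders disjoint random
  suffix <- substr(base40, 11, 20)
  b <- paste0(suffix, substr(base40, 21, 30))
  oi <- overlap_identity(a, b)
  expect_equal(oi[["overlap"]], 10)
  expect_equal(oi[["identity"]], 1)

  # 20-residue overlap with exactly one mismatch
  a2 <- a
  substr(a2, 5, 5) <- if (substr(a, 5, 5) == "A") "G" else "A"
  expect_equal(overlap_identity(a, a2), c(identity = 0.95, overlap = 20))

  # symmetry
  expect_equal(overlap_identity(a, b)[["identity"]],
               overlap_identity(b, a)[["identity"]])
  expect_equal(overlap_identity(a, a2), overlap_identity(a2, a))
})

test_that("clustering respects the 95% identity and 10-residue overlap bounds", {
  mutate_at <- function(s, pos) {
    for (p in pos) {
      substr(s, p, p) <- if (substr(s, p, p) == "A") "G" else "A"
    }
    s
  }
  # two ORFs tiling a 50-mer with a 20-residue overlap
  set.seed(6)
  src <- paste(sample(aa_alphabet(), 50, TRUE), collapse = "")
  left <- substr(src, 1, 35)
  right <- substr(src, 16, 50)

  expect_length(cluster_orfs(c(a = left, b = right)), 1)

  # one mismatch in the 20-residue overlap: identity 0.95, still merges
  right1 <- mutate_at(right, 3)
  expect_length(cluster_orfs(c(a = left, b = right1)), 1)

  # two mismatches: identity 0.90, splits
  right2 <- mutate_at(right, c(3, 12))
  expect_length(cluster_orfs(c(a = left, b = right2)), 2)

  # an identical overlap of only 9 residues splits
  left9 <- substr(src, 1, 24)
  right9 <- substr(src, 16, 50)
  expect_length(cluster_orfs(c(a = left9, b = right9)), 2)
})

test_that("tiling ORFs of one protein form one cluster; unrelated split", {
  sim <- gen_orf_set(orf_sim_spec(protein_len = 90, window = 30, step = 15,
                                  sub_rate = 0, seed = 7))
  expect_length(sim$orfs, 5)
  cl <- cluster_orfs(sim$orfs)
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$members, names(sim$orfs))

  sim2 <- gen_orf_set(orf_sim_spec(protein_len = 80, n_proteins = 2,
                                   window = 30, step = 15, seed = 3))
  cl2 <- cluster_orfs(sim2$orfs)
  expect_length(cl2, 2)
  for (c2 in cl2) {
    expect_length(unique(sim2$truth[c2$members]), 1)
  }

  # heavy substitution noise fragments the clusters
  sim3 <- gen_orf_set(orf_sim_spec(protein_len = 90, window = 30, step = 15,
                                   sub_rate = 0.2, seed = 9))
  expect_gt(length(cluster_orfs(sim3$orfs)), 1)
})

test_that("raising thresholds never merges previously separate clusters", {
  sim <- gen_orf_set(orf_sim_spec(protein_len = 100, n_proteins = 2,
                                  window = 30, step = 15, sub_rate = 0.03,
                                  seed = 13))
  loose <- cluster_orfs(sim$orfs, id_threshold = 0.90, min_overlap = 8)
  strict <- cluster_orfs(sim$orfs, id_threshold = 0.97, min_overlap = 12)
  # refinement: every strict cluster sits inside one loose cluster
  loose_of <- unlist(lapply(seq_along(loose), function(i) {
    stats::setNames(rep(i, length(loose[[i]]$members)), loose[[i]]$members)
  }))
  for (cl in strict) {
    expect_length(unique(loose_of[cl$members]), 1)
  }
  expect_gte(length(strict), length(loose))
})

test_that("consensus reconstructs the source protein", {
  # singleton
  expect_identical(unname(orf_consensus(c(x = "MKVLQ"))), "MKVLQ")

  # two error-free tiling fragments of a known 60-mer
  set.seed(8)
  src <- paste(sample(aa_alphabet(), 60, TRUE), collapse = "")
  frags <- c(f1 = substr(src, 1, 35), f2 = substr(src, 21, 60))
  expect_identical(unname(orf_consensus(frags)), src)

  # error-free tiling via the generator, >= 3x coverage columns included
  sim <- gen_orf_set(orf_sim_spec(protein_len = 90, window = 30, step = 10,
                                  sub_rate = 0, seed = 15))
  cl <- cluster_orfs(sim$orfs)
  expect_length(cl, 1)
  expect_identical(unname(cl[[1]]$consensus), unname(sim$proteins["prot1"]))
})

test_that("majority vote restores the true residue in a 3x-covered column", {
  set.seed(9)
  src <- paste(sample(aa_alphabet(), 50, TRUE), collapse = "")
  f1 <- substr(src, 1, 30)
  f2 <- substr(src, 11, 40)
  f3 <- substr(src, 21, 50)
  # inject one substitution into f2 inside the 3x-covered region (21..30)
  bad <- f2
  substr(bad, 15, 15) <- if (substr(f2, 15, 15) == "C") "W" else "C"
  cons <- orf_consensus(c(f1 = f1, f2 = bad, f3 = f3))
  expect_identical(unname(cons), src)
})

test_that("low-rate substitutions leave consensus mismatch rate <= 0.2%
          on >=3x-covered columns", {
  mismatches <- 0
  columns <- 0
  for (seed in 41:45) {
    sim <- gen_orf_set(orf_sim_spec(protein_len = 120, window = 40,
                                    step = 10, sub_rate = 0.01, seed = seed))
    cl <- cluster_orfs(sim$orfs)
    cons <- unname(cl[[1]]$consensus)
    truth <- unname(sim$proteins["prot1"])
    if (nchar(cons) == nchar(truth)) {
      # coverage per column from the tiling geometry (window 40, step 10)
      starts <- seq(1, 120 - 40 + 1, by = 10)
      cov <- vapply(seq_len(120), function(p) {
        sum(starts <= p & starts + 39 >= p)
      }, numeric(1))
      deep <- cov >= 3
      cc <- strsplit(cons, "")[[1]]
      tt <- strsplit(truth, "")[[1]]
      mismatches <- mismatches + sum(cc[deep] != tt[deep])
      columns <- columns + sum(deep)
    }
  }
  expect_gt(columns, 0)
  expect_lte(mismatches / columns, 0.002)
})

test_that("the mRNA coverage filter keeps plausible coding ORFs", {
  orfs <- c(a = strrep("M", 30), b = strrep("M", 5))
  mrna <- c(a = 300, b = 300)
  expect_identical(names(filter_orfs_by_coverage(orfs, mrna)), "a")
})
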