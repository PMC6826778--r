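test_that("segregating sites count distinct-base columns", {
  expect_equal(segregating_sites(c("AAA", "AAT", "AAT")), 1)
  expect_equal(segregating_sites(c("ACGT", "ACGT")), 0)
  expect_error(segregating_sites("ACGT"), "argument error")
  # simulator bookkeeping oracle: every placed mutation is one column
  set.seed(11)
  for (rep in 1:5) {
    cs <- coalescent_sample(8, 3, 200)
    expect_equal(segregating_sites(cs$seqs), cs$S)
  }
  # gap/ambiguity columns are excluded globally
  expect_equal(segregating_sites(c("A-GT", "ATGT", "ATGA")), 1)
  expect_equal(segregating_sites(c("ARGT", "ATGT", "ATGA")), 1)
})

test_that("coding-change classification separates syn from nonsyn sites", {
  # codons: GGC (Gly) vs GGT (Gly) at third position -> synonymous
  a <- c("GGCAAA", "GGTAAA", "GGTAAA")
  cc <- classify_coding_changes(ace1_alignment(a))
  expect_equal(cc$n_syn, 1); expect_equal(cc$n_nonsyn, 0)
  # GGC (Gly) vs AGC (Ser) at first position -> nonsynonymous (G119S-like)
  b <- c("GGCAAA", "AGCAAA", "AGCAAA")
  cb <- classify_coding_changes(ace1_alignment(b))
  expect_equal(cb$n_syn, 0); expect_equal(cb$n_nonsyn, 1)
  # one nonsynonymous among several polymorphic sites
  d <- c("GGCAAAGGC", "AGCAAAGGT", "AGCAAAGGT")
  cd <- classify_coding_changes(ace1_alignment(d))
  expect_equal(cd$n_nonsyn, 1)
  expect_equal(cd$n_syn, 1)
  # site in an incomplete terminal codon is excluded, not classified
  e <- c("GGCAAAG", "GGCAAAT", "GGCAAAT")
  ce <- classify_coding_changes(ace1_alignment(e))
  expect_equal(ce$n_syn + ce$n_nonsyn, 0)
  expect_equal(attr(ce, "excluded"), 7L)
})

test_that("haplotype collapse merges identical sequences with group bookkeeping", {
  expect_equal(nrow(collapse_haplotypes(rep("ACGT", 4))), 1)
  h <- collapse_haplotypes(c(a = "AAAA", b = "AAAA", c = "AAAT"))
  expect_equal(h$frequency, c(2L, 1L))
  expect_equal(h$haplotype, c("H1", "H2"))
  groups <- c(a = "dead", b = "alive", c = "alive")
  hg <- collapse_haplotypes(c(a = "AAAA", b = "AAAA", c = "AAAT"),
                            groups = groups)
  expect_equal(hg$dead, c(1L, 0L))
  expect_equal(hg$alive, c(1L, 1L))
  sh <- shared_haplotype_table(hg)
  expect_true(sh$table$shared[1])   # H1 in both groups
  expect_false(sh$table$shared[2])
  expect_equal(sum(sh$counts), nrow(hg))
  # ambiguous sequences are excluded by default, expanded on request
  mix <- c(x = "AAAA", y = "ARAA")
  expect_equal(nrow(collapse_haplotypes(mix)), 1)
  ex <- collapse_haplotypes(mix, ambiguity = "expand")
  expect_setequal(ex$seq, c("AAAA", "AGAA"))
  expect_equal(sum(ex$frequency), 3L)
})

test_that("haplotype diversity follows the unbiased formula", {
  expect_equal(haplotype_diversity(c(4)), 0)
  expect_equal(haplotype_diversity(rep(1, 4)), 1)
  expect_equal(haplotype_diversity(c(2, 2)), (4 / 3) * 0.5, tolerance = 1e-12)
  set.seed(21)
  for (rep in 1:10) {
    f <- sample(1:5, sample(2:5, 1), replace = TRUE)
    hd <- haplotype_diversity(f)
    expect_gte(hd, 0); expect_lte(hd, 1)
  }
  # hd = 0 iff a single haplotype
  expect_equal(haplotype_diversity(c(7)), 0)
  expect_gt(haplotype_diversity(c(7, 1)), 0)
})

test_that("nucleotide diversity equals the brute-force pairwise mean", {
  two <- c(paste(rep("A", 100), collapse = ""),
           paste(c(rep("A", 99), "T"), collapse = ""))
  expect_equal(nucleotide_diversity(two), 0.01)
  expect_equal(nucleotide_diversity(c("ACGT", "ACGT", "ACGT")), 0)
  set.seed(31)
  for (rep in 1:10) {
    seqs <- random_related_alignment(sample(3:10, 1), 50)
    expect_equal(nucleotide_diversity(seqs), oracle_pi(seqs),
                 tolerance = 1e-12)
  }
})

test_that("Tajima's D matches a constant-by-constant hand computation", {
  seqs <- c("AAGTCC", "AAGTCT", "ATGTCT", "AAGACT")
  # hand oracle: n = 4, S = 3 (columns 2, 4, 6)
  n <- 4; S <- 3
  kbar <- mean(c(1, 2, 2, 1, 1, 2))  # all 6 pairs, recounted by eye
  a1 <- 1 + 1 / 2 + 1 / 3; a2 <- 1 + 1 / 4 + 1 / 9
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  d_hand <- (kbar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(tajimas_d(seqs), d_hand, tolerance = 1e-12)
  # numerator is exactly zero when kbar = S/a1; scale a balanced case
  # n = 4, one site with a 2/2 split: kbar = 4/6 * 1 ... not zero, so
  # instead check the sign logic: an excess of intermediate-frequency
  # variants (2/2 splits) pushes D positive, singletons push it negative
  expect_gt(tajimas_d(c("AATT", "AATT", "AAAA", "AAAA")), 0)
  expect_lt(tajimas_d(c("TAAA", "ATCA", "AACA", "AACG")), 0)
  expect_message(expect_true(is.na(tajimas_d(c("AAA", "AAA")))),
                 "not available")
})

test_that("Fu & Li's D* matches a hand computation and sign expectations", {
  seqs <- c("AAGTCC", "AAGTCT", "ATGTCT", "AAGACT")
  n <- 4; eta <- 3; eta_s <- 3   # all three mutations are singletons
  an <- 1 + 1 / 2 + 1 / 3; bn <- 1 + 1 / 4 + 1 / 9; an1 <- an + 1 / 4
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vd <- ((n / (n - 1))^2 * bn + an^2 * dn -
           2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
  ud <- (n / (n - 1)) * (an - n / (n - 1)) - vd
  dstar_hand <- ((n / (n - 1)) * eta - an * eta_s) /
    sqrt(ud * eta + vd * eta^2)
  expect_equal(fu_li_d_star(seqs), dstar_hand, tolerance = 1e-12)
  # no singletons, eta > 0 -> numerator positive
  no_singletons <- c("AATT", "AATT", "AAAA", "AAAA")
  expect_gt(fu_li_d_star(no_singletons), 0)
  expect_message(expect_true(is.na(fu_li_d_star(c("AA", "AA", "AA")))),
                 "not available")
})

test_that("Fu's Fs matches the exact Stirling-number oracle for n <= 8", {
  # n = 2, one difference: theta = 1, P(K >= 2) = 1/2, Fs = 0
  expect_equal(fu_fs(c("AT", "AA")), 0, tolerance = 1e-12)
  # k_obs = 1 with polymorphism impossible; monomorphic -> NA
  expect_message(expect_true(is.na(fu_fs(c("AA", "AA")))), "not available")
  set.seed(41)
  n_checked <- 0
  for (rep in 1:20) {
    seqs <- random_related_alignment(sample(3:8, 1), 40)
    core <- ace1kit:::polymorphism_core(seqs)
    if (core$kbar <= 0 || core$K == 1) next
    expect_equal(fu_fs(seqs),
                 oracle_fs(core$n, core$kbar, core$K), tolerance = 1e-9)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 5)
})

test_that("neutrality significance is seeded, calibrated at the extremes", {
  null <- simulate_neutral_null(10, 8, n_reps = 300, seed = 9)
  med <- stats::median(null$D, na.rm = TRUE)
  r_med <- neutrality_significance(med, 10, 8, "D", n_reps = 300, seed = 9)
  expect_gt(r_med$p, 0.5)
  r_lo <- neutrality_significance(-50, 10, 8, "D", n_reps = 300, seed = 9)
  expect_lte(r_lo$p, 2 / 301 + 1e-12)
  r_fs <- neutrality_significance(-50, 10, 8, "Fs", n_reps = 300, seed = 9)
  expect_lte(r_fs$p, 1 / 301 + 1e-12)
  # determinism under the same seed
  r2 <- neutrality_significance(med, 10, 8, "D", n_reps = 300, seed = 9)
  expect_identical(r_med$p, r2$p)
  expect_warning(neutrality_significance(0, 10, 8, "D", n_reps = 50,
                                         seed = 1), "100")
})

test_that("group summary mirrors per-group statistics and pools totals", {
  set.seed(61)
  seqs <- c(random_related_alignment(6, 30), random_related_alignment(4, 30))
  names(seqs) <- paste0("m", 1:10)
  groups <- setNames(rep(c("alive", "dead"), c(6, 4)), names(seqs))
  aln <- ace1_alignment(seqs, codon_column = 1)
  tab <- summarize_polymorphism(aln, groups)
  expect_equal(tab$group, c("alive", "dead", "Total"))
  expect_equal(tab$two_n[3], sum(tab$two_n[1:2]))
  alive_only <- seqs[1:6]
  expect_equal(tab$pi[1], nucleotide_diversity(alive_only))
  expect_equal(tab$S[1], segregating_sites(alive_only))
  expect_equal(tab$h[1], nrow(collapse_haplotypes(alive_only)))
})
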