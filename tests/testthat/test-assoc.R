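test_that("mortality summary classifies WHO status from pooled mortality", {
  full <- mortality_summary(data.frame(n_exposed = c(25, 25),
                                       n_dead = c(25, 25)))
  expect_equal(full$mortality, 100)
  expect_equal(full$status, "susceptible")
  res <- mortality_summary(data.frame(n_exposed = c(54, 54),
                                      n_dead = c(35, 35)))
  expect_lt(res$mortality, 90)
  expect_equal(res$status, "resistant")
  susp <- mortality_summary(data.frame(n_exposed = 100, n_dead = 95))
  expect_equal(susp$status, "suspected_resistance")
  same <- mortality_summary(data.frame(n_exposed = rep(20, 4),
                                       n_dead = rep(13, 4)))
  expect_equal(same$sem, 0)
  expect_error(mortality_summary(data.frame(n_exposed = numeric(0),
                                            n_dead = numeric(0))),
               "argument error")
})

test_that("printed percentages recover the published genotype counts", {
  ben <- counts_from_percentages(25, c(76, 8, 16), "alive", "bendiocarb")
  expect_equal(c(ben$n_SS, ben$n_GS, ben$n_GG), c(19L, 2L, 4L))
  prop <- counts_from_percentages(30, c(96.6, 0, 3.4), "alive", "propoxur")
  expect_equal(c(prop$n_SS, prop$n_GS, prop$n_GG), c(29L, 0L, 1L))
  all_ss <- counts_from_percentages(10, c(100, 0, 0))
  expect_equal(c(all_ss$n_SS, all_ss$n_GS, all_ss$n_GG), c(10L, 0L, 0L))
  # rounding slack lands on the largest class
  dead <- counts_from_percentages(67, c(4.5, 1.5, 94), "dead", "bendiocarb")
  expect_equal(c(dead$n_SS, dead$n_GS, dead$n_GG), c(3L, 1L, 63L))
  expect_equal(dead$total, 67L)
})

test_that("allelic and genotypic tables are assembled as counted", {
  alive_b <- genotype_counts("alive", 19, 2, 4, "bendiocarb")
  dead_b <- genotype_counts("dead", 3, 1, 63, "bendiocarb")
  ta <- allelic_table(alive_b, dead_b)
  expect_equal(c(ta$a, ta$b, ta$c, ta$d), c(40, 10, 7, 127))
  tg <- genotypic_table(alive_b, dead_b)
  expect_equal(c(tg$a, tg$b, tg$c, tg$d), c(19, 4, 3, 63))
  alive_p <- genotype_counts("alive", 29, 0, 1, "propoxur")
  dead_p <- genotype_counts("dead", 0, 0, 38, "propoxur")
  tp <- allelic_table(alive_p, dead_p)
  expect_equal(c(tp$a, tp$b, tp$c, tp$d), c(58, 2, 0, 76))
  tpg <- genotypic_table(alive_p, dead_p)
  expect_equal(c(tpg$a, tpg$b, tpg$c, tpg$d), c(29, 1, 0, 38))
})

test_that("odds ratio and Woolf CI reproduce the published propoxur values", {
  t <- fourfold_table(29, 1, 0, 38)
  r <- odds_ratio_ci(t)   # haldane_all_cells default
  expect_equal(round(r$OR), 1514)
  expect_equal(round(r$ci_low, 1), 59.5)
  expect_equal(round(r$ci_high, -1), 38530)  # exp(logOR + 1.96 se)
  expect_true(r$ci_low <= r$OR && r$OR <= r$ci_high)
  # balanced table: OR exactly 1 regardless of correction
  expect_equal(odds_ratio_ci(fourfold_table(1, 1, 1, 1),
                             correction = "none")$OR, 1)
  # uncorrected classical OR on a positive table
  expect_equal(odds_ratio_ci(fourfold_table(40, 10, 7, 127),
                             correction = "none")$OR, 40 * 127 / (10 * 7))
  expect_error(odds_ratio_ci(fourfold_table(29, 1, 0, 38),
                             correction = "none"), "correction")
})

test_that("Fisher exact p matches full hypergeometric enumeration", {
  expect_equal(fisher_exact_p(c(5, 0, 0, 5)), 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_exact_p(c(1, 1, 1, 1)), 1)
  expect_lt(fisher_exact_p(c(29, 1, 0, 38)), 1e-10)
  set.seed(202)
  for (rep in 1:30) {
    cells <- as.integer(sample(0:12, 4, replace = TRUE))
    if (sum(cells) == 0) next
    expect_equal(fisher_exact_p(cells),
                 oracle_fisher(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-8)
  }
  expect_error(fisher_exact_p(c(1.5, 1, 1, 1)), "integer")
})

test_that("swapping phenotype groups inverts OR and preserves p", {
  set.seed(303)
  for (rep in 1:20) {
    cells <- as.integer(sample(0:15, 4, replace = TRUE))
    t1 <- fourfold_table(cells[1], cells[2], cells[3], cells[4])
    t2 <- fourfold_table(cells[3], cells[4], cells[1], cells[2])
    r1 <- odds_ratio_ci(t1); r2 <- odds_ratio_ci(t2)
    expect_equal(r1$OR, 1 / r2$OR, tolerance = 1e-12)
    expect_equal(fisher_exact_p(t1), fisher_exact_p(t2), tolerance = 1e-10)
  }
})

test_that("carrier and allele frequency match the published field screen", {
  f0 <- genotype_counts("F0", 34, 2, 57)
  expect_equal(round(100 * carrier_frequency(f0), 1), 38.7)
  expect_equal(carrier_frequency(f0), 36 / 93)
  expect_equal(allele_frequency(f0), 70 / 186)
  expect_equal(carrier_frequency(genotype_counts("g", 0, 0, 12)), 0)
  expect_equal(allele_frequency(genotype_counts("g", 9, 0, 0)), 1)
  expect_equal(allele_frequency(genotype_counts("g", 0, 10, 0)), 0.5)
  # carrier >= allele always
  set.seed(404)
  for (rep in 1:25) {
    cc <- genotype_counts("g", sample(0:20, 1), sample(0:20, 1),
                          sample(0:20, 1))
    if (cc$total == 0) next
    expect_gte(carrier_frequency(cc), allele_frequency(cc))
  }
})

test_that("HWE exact test matches enumeration and flags the het deficit", {
  expect_equal(hwe_exact_test(genotype_counts("g", 1, 2, 1)), 1)
  expect_lt(hwe_exact_test(genotype_counts("F0", 34, 2, 57)), 1e-3)
  set.seed(505)
  for (rep in 1:25) {
    cc <- genotype_counts("g", sample(0:15, 1), sample(0:15, 1),
                          sample(0:15, 1))
    if (cc$total == 0) next
    expect_equal(hwe_exact_test(cc),
                 oracle_hwe(cc$n_SS, cc$n_GS, cc$n_GG), tolerance = 1e-8)
  }
  # het-excess direction is handled by the same two-sided rule
  expect_equal(hwe_exact_test(genotype_counts("g", 0, 10, 0)),
               oracle_hwe(0, 10, 0), tolerance = 1e-8)
})

test_that("Woolf CI brackets the OR and Haldane correction is continuous", {
  set.seed(606)
  for (rep in 1:20) {
    cells <- sample(0:10, 4, replace = TRUE)
    r <- odds_ratio_ci(fourfold_table(cells[1], cells[2], cells[3],
                                      cells[4]))
    expect_true(r$ci_low <= r$OR && r$OR <= r$ci_high)
  }
  # small perturbation of a cell moves the corrected OR smoothly
  base <- odds_ratio_ci(fourfold_table(5, 3, 2, 7))$OR
  up <- odds_ratio_ci(fourfold_table(6, 3, 2, 7))$OR
  expect_gt(up, base)
  expect_lt(abs(up / base), 1.5)
})
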