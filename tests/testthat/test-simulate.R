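test_that("coalescent sampler is seeded and matches Watterson's expectation", {
  a <- coalescent_sample(8, 2, 300, seed = 13)
  b <- coalescent_sample(8, 2, 300, seed = 13)
  expect_identical(a$seqs, b$seqs)
  # E[S] = theta * a1(n); check over replicates within Monte-Carlo error
  set.seed(17)
  n <- 10; theta <- 3
  S <- replicate(400, coalescent_sample(n, theta, 500)$S)
  a1 <- sum(1 / seq_len(n - 1))
  expect_lt(abs(mean(S) - theta * a1) / (sd(S) / sqrt(400)), 4)
  # n = 2: mean pairwise difference ~ theta
  k2 <- replicate(400, coalescent_sample(2, theta, 500)$S)
  expect_lt(abs(mean(k2) - theta) / (sd(k2) / sqrt(400)), 4)
  # too many mutations for the grid is a clear error
  expect_error(coalescent_sample(50, 5000, 10, seed = 1), "increase L")
})

test_that("pools carry the diagnostic states and the sweep's hd contrast", {
  cfg <- sim_config(seed = 5)
  pools <- simulate_pools(cfg)
  expect_true(all(substr(pools$resistant, cfg$codon_column,
                         cfg$codon_column) == "A"))
  expect_true(all(substr(pools$susceptible, cfg$codon_column,
                         cfg$codon_column) == "G"))
  # no shared haplotype is possible across pools
  expect_length(intersect(pools$resistant, pools$susceptible), 0)
  # determinism
  pools2 <- simulate_pools(cfg)
  expect_identical(pools, pools2)
  # the founder is a member of the susceptible sample
  expect_true(pools$founder %in% pools$susceptible)
})

test_that("individuals obey copy-composition, call and survival rules", {
  cfg <- sim_config(seed = 23, dup_fraction = 0.3)
  pools <- simulate_pools(cfg)
  sim <- simulate_individuals(cfg, pools)
  tr <- sim$truth
  expect_equal(nrow(tr), cfg$n_f0 + sum(cfg$n_exposed))
  # copy counts match duplication status
  expect_true(all(tr$n_R_copies[tr$duplicated] == 3 &
                    tr$n_S_copies[tr$duplicated] == 1))
  expect_true(all(tr$n_R_copies[!tr$duplicated] +
                    tr$n_S_copies[!tr$duplicated] == 2))
  # TaqMan call is the dosage prediction of the copy make-up
  expect_equal(tr$taqman,
               mapply(predict_taqman_call, tr$n_R_copies, tr$n_S_copies))
  # with a strong effect survivors are mostly RR, dead mostly SS
  alive <- tr[!is.na(tr$phenotype) & tr$phenotype == "alive", ]
  dead <- tr[!is.na(tr$phenotype) & tr$phenotype == "dead", ]
  expect_gt(mean(alive$taqman == "RR"), 0.5)
  expect_gt(mean(dead$taqman == "SS"), 0.5)
  # overall mortality approaches the mixture complement of survival
  cfg_big <- sim_config(seed = 29, n_f0 = 0, dup_fraction = 0,
                        n_exposed = c(bendiocarb = 2000L))
  sim_big <- simulate_individuals(cfg_big, pools)
  p <- cfg_big$p_resistant_copy
  gf <- c(RR = p^2, RS = 2 * p * (1 - p), SS = (1 - p)^2)
  expected_mortality <- sum(gf * (1 - cfg_big$survival_probs[names(gf)]))
  observed <- mean(sim_big$truth$phenotype == "dead")
  expect_lt(abs(observed - expected_mortality), 0.04)
})

test_that("clone simulation recovers copies exactly at zero PCR error", {
  cfg <- sim_config(seed = 31, pcr_error_rate = 0,
                    clones_per_individual = 50L)
  pools <- simulate_pools(cfg)
  copies <- c(pools$resistant[1:3], pools$susceptible[1])
  cs <- simulate_clones(unname(copies), cfg, "i", seed = 37)
  expect_true(all(cs$clones %in% copies))
  # many clones recover every distinct copy
  expect_setequal(unique(cs$clones), unique(unname(copies)))
  # determinism
  cs2 <- simulate_clones(unname(copies), cfg, "i", seed = 37)
  expect_identical(cs$clones, cs2$clones)
  # dup_fraction 0 and zero error can never show > 2 distinct haplotypes
  cfg0 <- sim_config(seed = 41, dup_fraction = 0, pcr_error_rate = 0,
                     n_f0 = 30L, n_exposed = c(bendiocarb = 0L))
  sim0 <- simulate_individuals(cfg0, pools)
  for (id in sim0$truth$id[1:10]) {
    cs0 <- simulate_clones(sim0$copies[[id]], cfg0, id)
    expect_lte(nrow(collapse_clones(cs0)), 2)
  }
})

test_that("an emitted study re-parses to its own truth tables", {
  dir <- tempfile()
  cfg <- sim_config(seed = 47, n_f0 = 20L,
                    n_exposed = c(bendiocarb = 30L, propoxur = 20L),
                    n_cloned_per_insecticide = 3L)
  study <- emit_study(cfg, dir)
  truth <- read.csv(file.path(dir, "truth.csv"), stringsAsFactors = FALSE)
  expect_equal(truth$id, study$truth$id)
  expect_equal(truth$taqman, study$truth$taqman)
  # genotype counts aggregate the truth exactly
  gt <- read_genotype_counts(file.path(dir, "genotypes.csv"))
  for (i in seq_len(nrow(gt))) {
    sel <- if (gt$group[i] == "F0") study$truth$group == "F0" else
      !is.na(study$truth$insecticide) &
        study$truth$insecticide == gt$insecticide[i] &
        study$truth$group == gt$group[i]
    expect_equal(gt$n_SS[i], sum(study$truth$taqman[sel] == "RR"))
    expect_equal(gt$n_GG[i], sum(study$truth$taqman[sel] == "SS"))
  }
  # bioassay totals match the phenotype truth
  bio <- read_bioassay_counts(file.path(dir, "bioassay.csv"))
  agg <- aggregate(cbind(n_exposed, n_dead) ~ insecticide, bio, sum)
  for (ins in names(cfg$n_exposed)) {
    sel <- !is.na(study$truth$insecticide) & study$truth$insecticide == ins
    expect_equal(agg$n_exposed[agg$insecticide == ins],
                 unname(cfg$n_exposed[ins]))
    expect_equal(agg$n_dead[agg$insecticide == ins],
                 sum(study$truth$phenotype[sel] == "dead"))
  }
  # the direct alignment has one consensus per individual
  aln <- read_fasta(file.path(dir, "direct.fasta"), codon_column = 397)
  expect_setequal(aln$id, study$truth$id)
  # byte-identical re-emission under the same config
  dir2 <- tempfile()
  emit_study(cfg, dir2)
  for (f in c("direct.fasta", "genotypes.csv", "bioassay.csv", "truth.csv"))
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
})
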