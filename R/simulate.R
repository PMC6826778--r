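# Seeded synthetic-study generator.  Emulates the statistical structure a
# target-site resistance study assumes: a low-diversity resistant haplotype
# pool carrying the G->A substitution at the diagnostic codon (the sweep),
# a high-diversity susceptible pool, individuals with 2 or 4 gene copies,
# dosage-based genotype calls, genotype-dependent bioassay survival, and
# clone sampling with PCR error.

#' Configuration for a synthetic resistance study
#'
#' Defaults encode the study conditions the analysis is designed around: a
#' 705 bp locus, diagnostic column 397, a swept resistant pool
#' (`theta_R = 0.5`) against a diverse susceptible pool (`theta_S = 5`),
#' duplicated individuals carrying a 3R+1S copy make-up, five clones per
#' individual, and survival probabilities that make survivors mostly
#' homozygote resistant and dead mosquitoes mostly homozygote susceptible.
#'
#' @param seed RNG seed driving every draw of the study
#' @param L locus length in columns
#' @param theta_R,theta_S scaled mutation rates of the resistant (swept)
#'   and susceptible pools; `theta_R << theta_S`
#' @param codon_column 1-based diagnostic column
#' @param n_pool haplotype pool sample size per allele class
#' @param n_f0 field-collected (unexposed) individuals
#' @param n_exposed named integer vector: exposed individuals per
#'   insecticide
#' @param dup_fraction fraction of individuals with a duplicated (4-copy)
#'   locus
#' @param dup_composition copy make-up of duplicated individuals,
#'   `c(R = , S = )`
#' @param p_resistant_copy probability a non-duplicated copy is resistant
#' @param survival_probs per-genotype survival probability on exposure
#' @param clones_per_individual clones sequenced per cloned individual
#' @param pcr_error_rate expected substitutions per clone sequence
#'   (Poisson mean per clone)
#' @param n_cloned_per_insecticide alive individuals cloned per insecticide
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed = 1L, L = 705L, theta_R = 0.5, theta_S = 5,
                       codon_column = 397L, n_pool = 16L, n_f0 = 93L,
                       n_exposed = c(bendiocarb = 92L, propoxur = 68L),
                       dup_fraction = 0.25,
                       dup_composition = c(R = 3L, S = 1L),
                       p_resistant_copy = 0.4,
                       survival_probs = c(RR = 0.95, RS = 0.7, SS = 0.05),
                       clones_per_individual = 5L,
                       pcr_error_rate = 1e-3,
                       n_cloned_per_insecticide = 10L) {
  stopifnot(theta_R > 0, theta_S > 0, L >= 3,
            codon_column >= 1, codon_column <= L,
            dup_fraction >= 0, dup_fraction <= 1,
            p_resistant_copy >= 0, p_resistant_copy <= 1,
            all(survival_probs >= 0), all(survival_probs <= 1),
            pcr_error_rate >= 0, clones_per_individual >= 1,
            sum(dup_composition) >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate the resistant (swept) and susceptible haplotype pools
#'
#' The susceptible pool is a neutral coalescent sample at `theta_S` over a
#' random ancestral background carrying `G` at the diagnostic column.  The
#' sweep is emulated the way it happens: one susceptible haplotype (the
#' sweep founder) acquires the G-to-A substitution, and the resistant pool
#' is a shallow coalescent sample at `theta_R` descending from that
#' founder.  The resistant cluster therefore hangs off one point of the
#' susceptible diversity, with the founder haplotype one mutational step
#' away -- the geometry a swept target-site allele produces.  Because the
#' diagnostic state differs, the pools can never share a haplotype.
#'
#' @param cfg a `sim_config`
#' @param seed RNG seed; defaults to the config's
#' @return list of class `sim_pools` with `resistant`, `susceptible`
#'   (named character vectors), `founder` (the susceptible background the
#'   sweep arose on) and `ancestral`
#' @export
simulate_pools <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed, {
    ancestral <- sample(DNA_BASES, cfg$L, replace = TRUE)
    ancestral[cfg$codon_column] <- "G"
    ps <- coalescent_sample(cfg$n_pool, cfg$theta_S, cfg$L,
                            ancestral = ancestral,
                            exclude_columns = cfg$codon_column)
    founder <- unname(sample(ps$seqs, 1))
    founder_bg <- strsplit(founder, "", fixed = TRUE)[[1]]
    founder_bg[cfg$codon_column] <- "A"
    pr <- coalescent_sample(cfg$n_pool, cfg$theta_R, cfg$L,
                            ancestral = founder_bg,
                            exclude_columns = cfg$codon_column)
    res <- pr$seqs
    names(res) <- paste0("R", seq_along(res))
    sus <- ps$seqs
    names(sus) <- paste0("S", seq_along(sus))
    structure(list(resistant = res, susceptible = sus, founder = founder,
                   ancestral = ancestral), class = "sim_pools")
  })
}

draw_copies <- function(cfg, pools, duplicated) {
  if (duplicated) {
    n_r <- cfg$dup_composition[["R"]]; n_s <- cfg$dup_composition[["S"]]
  } else {
    n_r <- rbinom(1, 2, cfg$p_resistant_copy); n_s <- 2L - n_r
  }
  copies <- c(sample(pools$resistant, n_r, replace = TRUE),
              sample(pools$susceptible, n_s, replace = TRUE))
  list(copies = unname(copies), n_R = n_r, n_S = n_s)
}

#' Simulate individuals with copy compositions, genotype calls, phenotypes
#'
#' Non-duplicated individuals draw two copies (each resistant with
#' probability `p_resistant_copy`); duplicated individuals (probability
#' `dup_fraction`) draw the configured copy make-up.  The dosage genotype
#' call follows [predict_taqman_call()]; exposed individuals survive with
#' the call's survival probability.
#'
#' @param cfg a `sim_config`
#' @param pools from [simulate_pools()]
#' @param seed RNG seed; defaults to `cfg$seed + 1`
#' @return list with data.frame `truth` (id, group, insecticide,
#'   duplicated, n_R_copies, n_S_copies, taqman, phenotype) and list
#'   `copies` keyed by id
#' @export
simulate_individuals <- function(cfg, pools, seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "sim_config"), inherits(pools, "sim_pools"))
  with_seed(seed, {
    specs <- list()
    for (i in seq_len(cfg$n_f0))
      specs[[length(specs) + 1L]] <-
        list(id = sprintf("F0_%03d", i), insecticide = NA_character_,
             exposed = FALSE)
    for (ins in names(cfg$n_exposed))
      for (i in seq_len(cfg$n_exposed[[ins]]))
        specs[[length(specs) + 1L]] <-
          list(id = sprintf("%s_%03d", ins, i), insecticide = ins,
               exposed = TRUE)
    copies <- list()
    rows <- lapply(specs, function(sp) {
      dup <- runif(1) < cfg$dup_fraction
      dr <- draw_copies(cfg, pools, dup)
      copies[[sp$id]] <<- dr$copies
      call <- predict_taqman_call(dr$n_R, dr$n_S)
      phen <- if (!sp$exposed) NA_character_ else
        if (runif(1) < cfg$survival_probs[[call]]) "alive" else "dead"
      data.frame(id = sp$id,
                 group = if (sp$exposed) phen else "F0",
                 insecticide = sp$insecticide, duplicated = dup,
                 n_R_copies = dr$n_R, n_S_copies = dr$n_S,
                 taqman = call, phenotype = phen,
                 stringsAsFactors = FALSE)
    })
    list(truth = do.call(rbind, rows), copies = copies)
  })
}

#' Simulate clone sequencing of one individual
#'
#' Draws `clones_per_individual` sequences uniformly with replacement from
#' the individual's gene copies and applies `Poisson(pcr_error_rate)`
#' random substitutions to each clone.
#'
#' @param copies character vector of the individual's copy sequences
#' @param cfg a `sim_config`
#' @param individual_id label for the resulting clone set
#' @param seed RNG seed; `NULL` uses the current stream
#' @return a `clone_set`
#' @export
simulate_clones <- function(copies, cfg, individual_id = "ind",
                            seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"), length(copies) >= 1)
  with_seed(seed, {
    clones <- sample(copies, cfg$clones_per_individual, replace = TRUE)
    clones <- vapply(clones, function(s) {
      k <- rpois(1, cfg$pcr_error_rate)
      if (k > 0) {
        pos <- sample.int(nchar(s), min(k, nchar(s)))
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
        s <- paste(ch, collapse = "")
      }
      s
    }, character(1), USE.NAMES = FALSE)
    clone_set(individual_id, clones)
  })
}

iupac_consensus_seq <- function(copies) {
  m <- seq_char_matrix(copies)
  paste(apply(m, 2, iupac_consensus_base), collapse = "")
}

#' Emit a complete synthetic study to disk
#'
#' Writes every file the analysis pipeline consumes, plus the generating
#' truth: `direct.fasta` (per-individual direct-sequencing emulation: IUPAC
#' consensus of the gene copies), `groups.csv`, `genotypes.csv` (TaqMan
#' counts per group per insecticide), `bioassay.csv` (per-tube mortality,
#' tubes of up to 25), `clones/<id>.fasta` for cloned alive individuals,
#' and `truth.csv`.  Fully deterministic given the config seed.
#'
#' @param cfg a `sim_config`
#' @param out_dir output directory (created if needed)
#' @return invisibly, a list of class `sim_study` with `truth`, `copies`,
#'   `pools`, `files`
#' @export
emit_study <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "clones"), showWarnings = FALSE)
  pools <- simulate_pools(cfg)
  sim <- simulate_individuals(cfg, pools)
  truth <- sim$truth

  direct <- vapply(truth$id, function(id)
    iupac_consensus_seq(sim$copies[[id]]), character(1))
  f_direct <- file.path(out_dir, "direct.fasta")
  write_fasta(setNames(unname(direct), truth$id), f_direct)

  f_groups <- file.path(out_dir, "groups.csv")
  write_report_csv(truth[, c("id", "group", "insecticide")], f_groups)

  gt <- do.call(rbind, lapply(split(truth, list(truth$group,
                                                truth$insecticide),
                                    drop = TRUE), function(dd)
    data.frame(group = dd$group[1], insecticide = dd$insecticide[1],
               n_SS = sum(dd$taqman == "RR"),
               n_GS = sum(dd$taqman == "RS"),
               n_GG = sum(dd$taqman == "SS"))))
  f0 <- truth[truth$group == "F0", ]
  gt <- rbind(gt, data.frame(group = "F0", insecticide = "none",
                             n_SS = sum(f0$taqman == "RR"),
                             n_GS = sum(f0$taqman == "RS"),
                             n_GG = sum(f0$taqman == "SS")))
  rownames(gt) <- NULL
  f_geno <- file.path(out_dir, "genotypes.csv")
  write_genotype_counts(gt, f_geno)

  bio <- do.call(rbind, lapply(names(cfg$n_exposed), function(ins) {
    dd <- truth[!is.na(truth$insecticide) & truth$insecticide == ins, ]
    idx <- split(seq_len(nrow(dd)), ceiling(seq_len(nrow(dd)) / 25))
    do.call(rbind, lapply(idx, function(ii)
      data.frame(insecticide = ins, n_exposed = length(ii),
                 n_dead = sum(dd$phenotype[ii] == "dead"))))
  }))
  rownames(bio) <- NULL
  f_bio <- file.path(out_dir, "bioassay.csv")
  write_report_csv(bio, f_bio)

  clone_files <- character(0)
  with_seed(cfg$seed + 2L, {
    for (ins in names(cfg$n_exposed)) {
      alive <- truth$id[!is.na(truth$insecticide) &
                          truth$insecticide == ins &
                          truth$phenotype == "alive"]
      alive <- alive[!is.na(alive)]
      take <- utils::head(alive, cfg$n_cloned_per_insecticide)
      for (id in take) {
        cs <- simulate_clones(sim$copies[[id]], cfg, individual_id = id)
        f <- file.path(out_dir, "clones", paste0(id, ".fasta"))
        write_fasta(setNames(cs$clones,
                             paste0(id, "_c", seq_along(cs$clones))), f)
        clone_files <- c(clone_files, f)
      }
    }
  })

  f_truth <- file.path(out_dir, "truth.csv")
  write_report_csv(truth, f_truth)

  invisible(structure(list(
    truth = truth, copies = sim$copies, pools = pools,
    files = list(direct = f_direct, groups = f_groups,
                 genotypes = f_geno, bioassay = f_bio,
                 truth = f_truth, clones = clone_files)),
    class = "sim_study"))
}
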