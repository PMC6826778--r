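# End-to-end orchestration of the analysis stages over a study directory
# laid out like emit_study()'s output.  Every stage reads and writes plain
# files (CSV/FASTA/DOT/newick) so any stage can be re-run on its own.

#' Run the full resistance-study analysis pipeline
#'
#' Stages (subset with `stages`): `mortality` (WHO bioassay summary),
#' `assoc` (allelic and genotypic odds ratios, Fisher exact p, F0 carrier
#' and allele frequency, HWE exact test), `popgen` (per-group polymorphism
#' panel), `network` (statistical-parsimony haplotype network, DOT),
#' `tree` (Tamura-3 + neighbor joining, newick), `dupcall` (duplication
#' calls from clone FASTAs).  A run log records the package version, seed,
#' and every policy setting in force.
#'
#' @param study_dir directory containing `bioassay.csv`, `genotypes.csv`,
#'   `direct.fasta`, `groups.csv` and a `clones/` subdirectory (see
#'   [emit_study()])
#' @param out_dir output directory (created if needed)
#' @param codon_column 1-based diagnostic column of `direct.fasta`
#' @param frame_offset reading-frame offset of `direct.fasta`
#' @param correction zero-cell policy for odds ratios
#' @param confidence statistical-parsimony confidence for the network limit
#' @param null_reps coalescent replicates for neutrality p-values (0 skips)
#' @param seed RNG seed recorded and used for every stochastic step
#' @param min_support,max_err_dist clone-filtering policy for `dupcall`
#' @param ambiguity how heterozygous direct sequences enter the haplotype
#'   stages: `"expand"` (default; each diploid consensus contributes its
#'   two pseudo-phases, the 2n treatment a diploid sequencing panel gets)
#'   or `"exclude"`
#' @param stages character vector of stages to run
#' @return invisibly, named list of output file paths
#' @export
run_ace1_pipeline <- function(study_dir, out_dir,
                              codon_column = 397L, frame_offset = 0L,
                              correction = "haldane_all_cells",
                              confidence = 0.95, null_reps = 200L,
                              seed = 1L, min_support = 1L,
                              max_err_dist = 0L,
                              ambiguity = c("expand", "exclude"),
                              stages = c("mortality", "assoc", "popgen",
                                         "network", "tree", "dupcall")) {
  ambiguity <- match.arg(ambiguity)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  log_lines <- c(
    sprintf("ace1kit %s pipeline run", as.character(packageVersion("ace1kit"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("study_dir: %s", normalizePath(study_dir)),
    sprintf("seed: %d", seed),
    sprintf("codon_column: %d (1-based)", codon_column),
    sprintf("frame_offset: %d", frame_offset),
    sprintf("odds-ratio zero-cell correction: %s", correction),
    sprintf("network confidence: %g", confidence),
    sprintf("neutrality null replicates: %d (fixed_S)", null_reps),
    sprintf("clone filtering: min_support=%d max_err_dist=%d",
            min_support, max_err_dist),
    "site policy: complete deletion for S/D/D*/Fs, pairwise for pi",
    sprintf("ambiguous direct sequences: %s", ambiguity),
    "WHO thresholds: >=98 susceptible, 90-<98 suspected, <90 resistant")

  if ("mortality" %in% stages) stage("mortality", {
    bio <- read_bioassay_counts(file.path(study_dir, "bioassay.csv"))
    rows <- do.call(rbind, lapply(split(bio, bio$insecticide), function(b) {
      ms <- mortality_summary(b)
      data.frame(insecticide = b$insecticide[1], n_exposed = ms$n_exposed,
                 n_dead = ms$n_dead, mortality = ms$mortality,
                 sem = ms$sem, status = ms$status)
    }))
    out$mortality <- file.path(out_dir, "mortality.csv")
    write_report_csv(rows, out$mortality)
  })

  if ("assoc" %in% stages) stage("assoc", {
    gt <- read_genotype_counts(file.path(study_dir, "genotypes.csv"))
    mk <- function(r) genotype_counts(r$group, r$n_SS, r$n_GS, r$n_GG,
                                      r$insecticide)
    assoc_rows <- list()
    for (ins in setdiff(unique(gt$insecticide), "none")) {
      alive <- gt[gt$insecticide == ins & gt$group == "alive", ]
      dead <- gt[gt$insecticide == ins & gt$group == "dead", ]
      if (nrow(alive) == 1 && nrow(dead) == 1)
        assoc_rows[[ins]] <- association_summary(mk(alive), mk(dead),
                                                 correction = correction)
    }
    res <- do.call(rbind, assoc_rows)
    f0 <- gt[gt$group == "F0", ]
    if (nrow(f0) == 1) {
      c0 <- mk(f0)
      res_f0 <- data.frame(insecticide = "none", comparison = "F0_summary",
                           a = c0$n_SS, b = c0$n_GS, c = c0$n_GG, d = 0,
                           OR = NA, ci_low = carrier_frequency(c0),
                           ci_high = allele_frequency(c0),
                           p_fisher = hwe_exact_test(c0))
      names(res_f0) <- names(res)
      log_lines <- c(log_lines, sprintf(
        "F0: carrier frequency %.4f, allele frequency %.4f, HWE exact p %.3g",
        carrier_frequency(c0), allele_frequency(c0), hwe_exact_test(c0)))
      res <- rbind(res, res_f0)
    }
    rownames(res) <- NULL
    out$association <- file.path(out_dir, "association.csv")
    write_report_csv(res, out$association)
  })

  aln <- NULL; haps <- NULL; groups <- NULL
  need_seq <- any(c("popgen", "network", "tree") %in% stages)
  if (need_seq) stage("seq_io", {
    aln <- read_fasta(file.path(study_dir, "direct.fasta"),
                       codon_column = codon_column,
                       frame_offset = frame_offset)
    gdf <- read.csv(file.path(study_dir, "groups.csv"),
                    stringsAsFactors = FALSE)
    groups <- setNames(gdf$group, gdf$id)
    haps <- collapse_haplotypes(aln, groups = groups,
                                ambiguity = ambiguity)
  })

  if ("popgen" %in% stages) stage("popgen", {
    tab <- summarize_polymorphism(aln, groups, null_reps = null_reps,
                                  seed = seed, ambiguity = ambiguity)
    out$polymorphism <- file.path(out_dir, "polymorphism.csv")
    write_report_csv(tab, out$polymorphism)
  })

  if ("network" %in% stages) stage("network", {
    net <- build_network(haps, confidence = confidence,
                         codon_column = codon_column)
    out$network <- file.path(out_dir, "network.dot")
    write_dot(net, out$network)
    sh <- shared_haplotype_table(haps)
    log_lines <- c(log_lines,
                   sprintf("network: limit %d steps, %d haplotypes, %d components",
                           net$limit, sum(!net$nodes$latent),
                           length(unique(stats::na.omit(net$nodes$component)))),
                   sprintf("haplotype sharing: %s",
                           paste(names(sh$counts), sh$counts,
                                 sep = "=", collapse = ", ")))
  })

  if ("tree" %in% stages) stage("tree", {
    if (nrow(haps) < 3)
      stop("need at least 3 distinct haplotypes for a tree")
    dm <- tamura3_matrix(haps)
    tr <- nj_tree(dm)
    out$tree <- file.path(out_dir, "tree.nwk")
    write_newick(tr, out$tree)
  })

  if ("dupcall" %in% stages) stage("dupcall", {
    clone_sets <- read_clone_sets(file.path(study_dir, "clones"))
    tab <- duplication_table(clone_sets, codon_column = codon_column,
                             min_support = min_support,
                             max_err_dist = max_err_dist)
    out$duplication <- file.path(out_dir, "duplication_calls.csv")
    write_report_csv(tab, out$duplication)
  })

  out$log <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, out$log)
  invisible(out)
}
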