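#' Genotype counts for one phenotype group
#'
#' @param group phenotype group label, one of `"alive"`, `"dead"`, `"F0"`
#' @param n_SS,n_GS,n_GG non-negative integer counts of homozygote resistant
#'   (119S/119S), heterozygote and homozygote susceptible individuals
#' @param insecticide insecticide label (optional)
#' @return object of class `genotype_counts`
#' @export
genotype_counts <- function(group, n_SS, n_GS, n_GG, insecticide = NA) {
  counts <- c(n_SS = n_SS, n_GS = n_GS, n_GG = n_GG)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  structure(list(group = group, insecticide = insecticide,
                 n_SS = as.integer(n_SS), n_GS = as.integer(n_GS),
                 n_GG = as.integer(n_GG),
                 total = as.integer(n_SS + n_GS + n_GG)),
            class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("genotype_counts [%s%s]: SS=%d GS=%d GG=%d (n=%d)\n",
              x$group, if (is.na(x$insecticide)) "" else
                paste0(", ", x$insecticide),
              x$n_SS, x$n_GS, x$n_GG, x$total))
  invisible(x)
}

#' Recover genotype counts from printed percentages
#'
#' Field studies often report genotype distributions only as percentages of
#' a known group total.  Each percentage is converted to a count by rounding
#' `percentage/100 * total` to the nearest integer; if the rounded counts
#' miss the total (by at most the rounding slack), the largest class is
#' adjusted by the difference.
#'
#' @param total group size (non-negative integer)
#' @param percentages length-3 numeric `(SS, GS, GG)` summing to ~100
#'   (within 1 for rounding)
#' @inheritParams genotype_counts
#' @return a `genotype_counts`
#' @export
counts_from_percentages <- function(total, percentages, group = "group",
                                    insecticide = NA) {
  if (length(total) != 1 || total < 0 || total != round(total))
    stop("total must be a single non-negative integer")
  if (length(percentages) != 3)
    stop("percentages must have length 3 (SS, GS, GG)")
  if (abs(sum(percentages) - 100) > 1)
    stop("percentages must sum to ~100 (within 1)")
  counts <- round(percentages / 100 * total)
  diff <- total - sum(counts)
  if (diff != 0) {
    k <- which.max(counts)
    counts[k] <- counts[k] + diff
  }
  if (any(counts < 0)) stop("rounding produced a negative count")
  genotype_counts(group, counts[1], counts[2], counts[3], insecticide)
}

#' Bioassay mortality summary with WHO resistance classification
#'
#' Mortality is the pooled percentage of exposed mosquitoes dead at 24 h;
#' the standard error is that of the per-replicate (per-tube) mortalities.
#' Status follows the WHO 2016 test procedures: mortality >= 98% means a
#' susceptible population, 90% to < 98% suspected resistance, and < 90%
#' confirmed resistance.
#'
#' @param replicates data.frame with columns `n_exposed`, `n_dead` (one row
#'   per replicate tube), or a list of `c(n_exposed, n_dead)` pairs
#' @return list of class `mortality_summary` with `mortality` (%), `sem`
#'   (%), `status`, and the pooled totals
#' @export
mortality_summary <- function(replicates) {
  if (is.list(replicates) && !is.data.frame(replicates))
    replicates <- do.call(rbind, lapply(replicates, function(r)
      data.frame(n_exposed = r[[1]], n_dead = r[[2]])))
  if (NROW(replicates) == 0)
    stop("argument error: need at least one replicate")
  if (any(replicates$n_exposed <= 0))
    stop("argument error: each replicate needs n_exposed > 0")
  if (any(replicates$n_dead < 0 | replicates$n_dead > replicates$n_exposed))
    stop("argument error: need 0 <= n_dead <= n_exposed")
  per_rep <- 100 * replicates$n_dead / replicates$n_exposed
  mortality <- 100 * sum(replicates$n_dead) / sum(replicates$n_exposed)
  sem <- if (NROW(replicates) > 1) sd(per_rep) / sqrt(NROW(replicates)) else 0
  status <- if (mortality >= 98) "susceptible"
            else if (mortality >= 90) "suspected_resistance"
            else "resistant"
  structure(list(mortality = mortality, sem = sem, status = status,
                 n_exposed = sum(replicates$n_exposed),
                 n_dead = sum(replicates$n_dead),
                 n_replicates = NROW(replicates)),
            class = "mortality_summary")
}

#' @export
print.mortality_summary <- function(x, ...) {
  cat(sprintf("mortality %.1f%% +/- %.1f%% (%d/%d dead, %d replicates): %s\n",
              x$mortality, x$sem, x$n_dead, x$n_exposed, x$n_replicates,
              x$status))
  invisible(x)
}

#' Construct a 2x2 (fourfold) association table
#'
#' Orientation is fixed so that an odds ratio above 1 means the resistance
#' category is enriched among survivors: `a` = resistant-category count in
#' survivors, `b` = susceptible-category in survivors, `c` = resistant in
#' dead, `d` = susceptible in dead.
#'
#' @param a,b,c,d non-negative cell counts
#' @param correction zero-cell policy carried with the table:
#'   `"haldane_all_cells"` (add 0.5 to every cell; the default convention),
#'   `"haldane_if_zero"` (add 0.5 to every cell only when some cell is 0),
#'   or `"none"`
#' @return object of class `fourfold_table`
#' @export
fourfold_table <- function(a, b, c, d,
                           correction = c("haldane_all_cells",
                                          "haldane_if_zero", "none")) {
  correction <- match.arg(correction)
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  structure(list(a = a, b = b, c = c, d = d, correction = correction),
            class = "fourfold_table")
}

corrected_cells <- function(t, correction = t$correction) {
  cells <- c(t$a, t$b, t$c, t$d)
  if (correction == "haldane_all_cells") cells <- cells + 0.5
  else if (correction == "haldane_if_zero" && any(cells == 0))
    cells <- cells + 0.5
  cells
}

#' Allelic 2x2 table from alive/dead genotype counts
#'
#' Each individual contributes two alleles: the resistant-allele count per
#' group is `2*n_SS + n_GS` and the susceptible count `2*n_GG + n_GS`.
#'
#' @param alive,dead `genotype_counts` for the two phenotype groups
#' @inheritParams fourfold_table
#' @return a `fourfold_table`
#' @export
allelic_table <- function(alive, dead,
                          correction = "haldane_all_cells") {
  stopifnot(inherits(alive, "genotype_counts"),
            inherits(dead, "genotype_counts"))
  if (!is.na(alive$insecticide) && !is.na(dead$insecticide) &&
      alive$insecticide != dead$insecticide)
    stop("alive and dead groups come from different insecticides")
  fourfold_table(2 * alive$n_SS + alive$n_GS, 2 * alive$n_GG + alive$n_GS,
                 2 * dead$n_SS + dead$n_GS, 2 * dead$n_GG + dead$n_GS,
                 correction = correction)
}

#' Genotypic (homozygote resistant vs homozygote susceptible) 2x2 table
#'
#' Heterozygotes are excluded; the table compares SS against GG individuals
#' between survivors and dead.
#'
#' @inheritParams allelic_table
#' @return a `fourfold_table`
#' @export
genotypic_table <- function(alive, dead,
                            correction = "haldane_all_cells") {
  stopifnot(inherits(alive, "genotype_counts"),
            inherits(dead, "genotype_counts"))
  if (!is.na(alive$insecticide) && !is.na(dead$insecticide) &&
      alive$insecticide != dead$insecticide)
    stop("alive and dead groups come from different insecticides")
  fourfold_table(alive$n_SS, alive$n_GG, dead$n_SS, dead$n_GG,
                 correction = correction)
}

#' Odds ratio with a Woolf (logit) 95% confidence interval
#'
#' `OR = (a'd')/(b'c')` on the correction-adjusted cells, with
#' `CI = exp(ln OR +/- 1.96 * sqrt(1/a' + 1/b' + 1/c' + 1/d'))`.  With
#' `correction = "none"` a zero cell is an error (choose a Haldane
#' correction instead).  When all original cells are integers the two-tailed
#' Fisher exact p on the uncorrected table is attached.
#'
#' @param t a `fourfold_table`
#' @param correction override of the table's correction policy
#' @param conf_z normal quantile for the interval (1.96 for 95%)
#' @return list of class `association_result` with `OR`, `ci_low`,
#'   `ci_high`, `p_fisher`, and the cells used
#' @export
odds_ratio_ci <- function(t, correction = t$correction, conf_z = 1.96) {
  stopifnot(inherits(t, "fourfold_table"))
  cells <- corrected_cells(t, correction)
  if (any(cells == 0))
    stop("divide-by-zero: table has an empty cell; use correction = ",
         "\"haldane_all_cells\" or \"haldane_if_zero\"")
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1, 1) * conf_z * se)
  orig <- c(t$a, t$b, t$c, t$d)
  p <- if (all(orig == round(orig))) fisher_exact_p(t) else NA_real_
  structure(list(OR = or, ci_low = ci[1], ci_high = ci[2], p_fisher = p,
                 cells = cells, correction = correction),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("OR = %.4g (95%% CI %.4g-%.4g)", x$OR, x$ci_low, x$ci_high))
  if (!is.na(x$p_fisher)) cat(sprintf(", Fisher p = %.3g", x$p_fisher))
  cat("\n")
  invisible(x)
}

#' Two-tailed Fisher exact probability for a 2x2 table
#'
#' The exact two-sided rule: with margins fixed, sum the hypergeometric
#' probabilities of every table whose probability does not exceed that of
#' the observed table.  Cells must be (uncorrected) integers.
#'
#' @param t a `fourfold_table` (or length-4 integer vector `a,b,c,d`)
#' @return the two-tailed p-value
#' @export
fisher_exact_p <- function(t) {
  cells <- if (inherits(t, "fourfold_table")) c(t$a, t$b, t$c, t$d) else t
  if (length(cells) != 4 || any(cells != round(cells)) || any(cells < 0))
    stop("argument error: Fisher exact test needs non-negative integer cells")
  m <- matrix(as.integer(round(cells)), nrow = 2, byrow = TRUE)
  stats::fisher.test(m)$p.value
}

#' Proportion of individuals carrying at least one resistant allele
#' @param c a `genotype_counts`
#' @return `(n_SS + n_GS) / total`
#' @export
carrier_frequency <- function(c) {
  stopifnot(inherits(c, "genotype_counts"))
  if (c$total == 0) stop("argument error: zero group total")
  (c$n_SS + c$n_GS) / c$total
}

#' Resistant (119S) allele frequency
#' @param c a `genotype_counts`
#' @return `(2*n_SS + n_GS) / (2*total)`
#' @export
allele_frequency <- function(c) {
  stopifnot(inherits(c, "genotype_counts"))
  if (c$total == 0) stop("argument error: zero group total")
  (2 * c$n_SS + c$n_GS) / (2 * c$total)
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Two-sided exact conditional test: conditioned on the observed allele
#' counts, heterozygote counts of matching parity are enumerated and the
#' probabilities of all outcomes no more likely than the observed one are
#' summed (the standard exact HWE test of Wigginton, Cutler and Abecasis).
#' A chi-square test is available as an option.
#'
#' @param c a `genotype_counts`
#' @param method `"exact"` (default) or `"chisq"`
#' @return p-value
#' @export
hwe_exact_test <- function(c, method = c("exact", "chisq")) {
  stopifnot(inherits(c, "genotype_counts"))
  method <- match.arg(method)
  n <- c$total
  if (n == 0) stop("argument error: zero group total")
  n_a <- 2 * c$n_SS + c$n_GS        # resistant allele count
  n_b <- 2 * c$n_GG + c$n_GS
  if (method == "chisq") {
    p <- n_a / (2 * n)
    expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    if (any(expd == 0)) return(1)
    x2 <- sum((c(c$n_SS, c$n_GS, c$n_GG) - expd)^2 / expd)
    return(stats::pchisq(x2, df = 1, lower.tail = FALSE))
  }
  if (n_a == 0 || n_b == 0) return(1)
  hets <- seq(n_a %% 2, min(n_a, n_b), by = 2)
  # log P(n_het = h | n, n_a), uniform-pairing exact distribution
  logp <- lgamma(n + 1) - lgamma((n_a - hets) / 2 + 1) -
    lgamma(hets + 1) - lgamma((n_b - hets) / 2 + 1) +
    hets * log(2) + lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
  pr <- exp(logp - logsumexp(logp))
  obs <- pr[match(c$n_GS, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

#' Association summary for one insecticide
#'
#' Convenience wrapper producing the allelic and genotypic comparisons for
#' an alive/dead pair in one data.frame row each.
#'
#' @inheritParams allelic_table
#' @return data.frame with columns `insecticide`, `comparison`, the four
#'   cells, `OR`, `ci_low`, `ci_high`, `p_fisher`
#' @export
association_summary <- function(alive, dead,
                                correction = "haldane_all_cells") {
  rows <- lapply(c(allelic = allelic_table, genotypic = genotypic_table),
                 function(f) f(alive, dead, correction = correction))
  do.call(rbind, lapply(names(rows), function(nm) {
    t <- rows[[nm]]
    r <- odds_ratio_ci(t)
    data.frame(insecticide = alive$insecticide, comparison = nm,
               a = t$a, b = t$b, c = t$c, d = t$d,
               OR = r$OR, ci_low = r$ci_low, ci_high = r$ci_high,
               p_fisher = r$p_fisher)
  }))
}
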