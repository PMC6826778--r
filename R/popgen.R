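# Polymorphism and neutrality statistics over an alignment.
#
# Site policy (the common polymorphism-software default, "complete
# deletion"): columns containing a gap or an ambiguity code are excluded
# globally for S, eta, Tajima's D, Fu & Li's D* and Fu's Fs; for nucleotide
# diversity they are excluded pairwise.  Sequences containing ambiguity
# codes are excluded from haplotype collapsing by default (a direct diploid
# read is a composite of two alleles, not a haplotype).

# Core per-alignment quantities computed once on the complete-deletion
# column set: n, S (segregating sites), kbar (mean pairwise differences),
# eta (total mutations), eta_s (singletons), K (distinct haplotypes).
polymorphism_core <- function(x) {
  seqs <- as_seq_vector(x)
  if (length(seqs) < 2)
    stop("argument error: need at least 2 sequences")
  m <- seq_char_matrix(seqs)
  keep <- apply(m, 2, function(col) all(is_unambiguous(col)))
  mm <- m[, keep, drop = FALSE]
  n <- nrow(mm)
  npairs <- choose(n, 2)
  S <- 0L; eta <- 0L; eta_s <- 0L; kbar <- 0
  if (ncol(mm) > 0) {
    for (j in seq_len(ncol(mm))) {
      tab <- tabulate(factor(mm[, j], levels = DNA_BASES), nbins = 4)
      tab <- tab[tab > 0]
      k <- length(tab)
      if (k > 1) {
        S <- S + 1L
        eta <- eta + (k - 1L)
        eta_s <- eta_s + min(sum(tab == 1L), k - 1L)
        kbar <- kbar + (npairs - sum(choose(tab, 2))) / npairs
      }
    }
  }
  key <- apply(mm, 1, paste, collapse = "")
  list(n = n, S = S, kbar = kbar, eta = eta, eta_s = eta_s,
       K = length(unique(key)), L_used = ncol(mm), L = ncol(m))
}

#' Number of segregating (polymorphic) sites
#'
#' Columns with at least two distinct unambiguous bases, after globally
#' excluding columns that contain gaps or ambiguity codes.
#'
#' @param x an `ace1_alignment` or character vector of aligned sequences
#' @return integer count
#' @export
segregating_sites <- function(x) polymorphism_core(x)$S

#' Classify polymorphic sites as synonymous or nonsynonymous
#'
#' Each biallelic polymorphic site (complete-deletion column set) is placed
#' in its codon (standard genetic code, reading frame from `frame_offset`);
#' the other two codon positions take the majority unambiguous base.  The
#' site is synonymous when swapping the two observed bases leaves the amino
#' acid unchanged.  Sites in incomplete terminal codons, or with more than
#' two alleles, are excluded and reported in the `excluded` attribute.
#'
#' @param aln an `ace1_alignment`
#' @param frame_offset reading-frame offset; defaults to the alignment's
#' @return list with `n_syn`, `n_nonsyn`, and data.frame `sites`
#' @export
classify_coding_changes <- function(aln, frame_offset = aln$frame_offset) {
  stopifnot(inherits(aln, "ace1_alignment"))
  m <- seq_char_matrix(as_seq_vector(aln))
  keep <- which(apply(m, 2, function(col) all(is_unambiguous(col))))
  code <- Biostrings::GENETIC_CODE
  res <- list(); excluded <- integer(0)
  for (j in keep) {
    alleles <- names(sort(table(m[, j]), decreasing = TRUE))
    if (length(alleles) < 2) next
    if (length(alleles) > 2) { excluded <- c(excluded, j); next }
    codon_idx <- (j - 1L - frame_offset) %/% 3L
    c1 <- frame_offset + 3L * codon_idx + 1L
    if (codon_idx < 0 || c1 + 2L > ncol(m)) { excluded <- c(excluded, j); next }
    cols <- c1:(c1 + 2L)
    ctx <- vapply(cols, function(cc) {
      if (cc == j) return(NA_character_)
      b <- m[is_unambiguous(m[, cc]), cc]
      if (!length(b)) NA_character_ else names(which.max(table(b)))
    }, character(1))
    if (anyNA(ctx[cols != j])) { excluded <- c(excluded, j); next }
    pos_in_codon <- which(cols == j)
    mk <- function(base) {
      cd <- ctx; cd[pos_in_codon] <- base
      paste(cd, collapse = "")
    }
    aa <- code[c(mk(alleles[1]), mk(alleles[2]))]
    res[[length(res) + 1L]] <- data.frame(
      column = j, base_major = alleles[1], base_minor = alleles[2],
      aa_major = aa[1], aa_minor = aa[2],
      synonymous = aa[1] == aa[2])
  }
  sites <- if (length(res)) do.call(rbind, res) else
    data.frame(column = integer(0), base_major = character(0),
               base_minor = character(0), aa_major = character(0),
               aa_minor = character(0), synonymous = logical(0))
  out <- list(n_syn = sum(sites$synonymous),
              n_nonsyn = sum(!sites$synonymous), sites = sites)
  attr(out, "excluded") <- excluded
  out
}

#' Collapse aligned sequences into haplotypes
#'
#' Identical sequences are merged and labelled `H1..Hk` in order of first
#' appearance.  Sequences containing IUPAC ambiguity codes are excluded by
#' default (`ambiguity = "exclude"`); `"expand"` applies a naive two-phase
#' expansion in which each ambiguous sequence contributes two pseudo-phases
#' (first and second base of every code), labelled `<id>.a`/`<id>.b` --
#' a crude device, clearly not real phasing.
#'
#' @param x an `ace1_alignment` or character vector of aligned sequences
#' @param groups optional named character vector mapping sequence id to
#'   phenotype group (`alive`/`dead`/`F0`/...)
#' @param ambiguity `"exclude"` (default) or `"expand"`
#' @return data.frame of class `haplotype_set` with columns `haplotype`,
#'   `seq`, `frequency`, `members` (comma-separated ids) and one count
#'   column per group
#' @export
collapse_haplotypes <- function(x, groups = NULL,
                                ambiguity = c("exclude", "expand")) {
  ambiguity <- match.arg(ambiguity)
  seqs <- as_seq_vector(x)
  ex <- resolve_ambiguous(seqs, groups, ambiguity)
  seqs <- ex$seqs; groups <- ex$groups
  if (!length(seqs)) stop("no unambiguous sequences left to collapse")
  uniq <- unique(unname(seqs))
  lab <- paste0("H", seq_along(uniq))
  idx <- match(seqs, uniq)
  out <- data.frame(haplotype = lab, seq = uniq,
                    frequency = as.integer(tabulate(idx, length(uniq))),
                    members = vapply(seq_along(uniq), function(i)
                      paste(names(seqs)[idx == i], collapse = ","),
                      character(1)),
                    stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    glev <- unique(unname(groups))
    for (g in glev) {
      ids_g <- names(groups)[groups == g]
      out[[g]] <- vapply(seq_along(uniq), function(i)
        sum(names(seqs)[idx == i] %in% ids_g), integer(1))
    }
    attr(out, "group_levels") <- glev
  }
  class(out) <- c("haplotype_set", "data.frame")
  out
}

# Apply the ambiguity policy to a named sequence vector (and its group
# map): "exclude" drops sequences containing ambiguity codes, "expand"
# replaces each with its two naive pseudo-phases (<id>.a / <id>.b); phases
# still containing a 3/4-fold code (N) are dropped.
resolve_ambiguous <- function(seqs, groups = NULL,
                              ambiguity = c("exclude", "expand")) {
  ambiguity <- match.arg(ambiguity)
  amb <- vapply(strsplit(seqs, "", fixed = TRUE),
                function(ch) any(!ch %in% c(DNA_BASES, "-")), logical(1))
  if (!any(amb)) return(list(seqs = seqs, groups = groups))
  if (ambiguity == "exclude") {
    keep <- seqs[!amb]
    return(list(seqs = keep,
                groups = if (is.null(groups)) NULL else
                  groups[names(groups) %in% names(keep)]))
  }
  extra <- character(0); extra_groups <- character(0)
  for (id in names(seqs)[amb]) {
    two <- iupac_two_phase(strsplit(seqs[[id]], "", fixed = TRUE)[[1]])
    nm <- paste0(id, c(".a", ".b"))
    ok <- !grepl("N", two, fixed = TRUE)
    extra <- c(extra, setNames(two[ok], nm[ok]))
    if (!is.null(groups) && id %in% names(groups))
      extra_groups <- c(extra_groups,
                        setNames(rep(groups[[id]], sum(ok)), nm[ok]))
  }
  keep <- seqs[!amb]
  list(seqs = c(keep, extra),
       groups = if (is.null(groups)) NULL else
         c(groups[names(groups) %in% names(keep)], extra_groups))
}

iupac_two_phase <- function(ch) {
  pairs <- list(R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"))
  p1 <- ch; p2 <- ch
  for (i in seq_along(ch)) {
    if (ch[i] %in% names(pairs)) {
      p1[i] <- pairs[[ch[i]]][1]
      p2[i] <- pairs[[ch[i]]][2]
    } else if (!ch[i] %in% c(DNA_BASES, "-")) {
      p1[i] <- "N"; p2[i] <- "N"   # 3/4-fold codes cannot be two-phased
    }
  }
  c(paste(p1, collapse = ""), paste(p2, collapse = ""))
}

#' Haplotype (gene) diversity
#'
#' `hd = n/(n-1) * (1 - sum(p_i^2))` with `p_i = f_i/n`: the unbiased
#' probability that two sequences drawn without replacement differ.
#'
#' @param frequencies haplotype frequencies (counts), or a `haplotype_set`
#' @return hd in `[0, 1]`
#' @export
haplotype_diversity <- function(frequencies) {
  if (inherits(frequencies, "haplotype_set"))
    frequencies <- frequencies$frequency
  f <- frequencies[frequencies > 0]
  n <- sum(f)
  if (n < 2) stop("argument error: need at least 2 sequences")
  n / (n - 1) * (1 - sum((f / n)^2))
}

#' Nucleotide diversity (pi)
#'
#' Mean over all sequence pairs of the proportion of differing sites,
#' counted over the sites comparable in that pair (both bases unambiguous;
#' pairwise deletion).
#'
#' @inheritParams segregating_sites
#' @return pi per site
#' @export
nucleotide_diversity <- function(x) {
  seqs <- as_seq_vector(x)
  if (length(seqs) < 2) stop("argument error: need at least 2 sequences")
  m <- seq_char_matrix(seqs)
  ok <- matrix(is_unambiguous(m), nrow = nrow(m))
  n <- nrow(m)
  tot <- 0; np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    comp <- ok[i, ] & ok[j, ]
    nc <- sum(comp)
    if (nc == 0) next
    tot <- tot + sum(m[i, comp] != m[j, comp]) / nc
    np <- np + 1
  }
  if (np == 0) stop("no comparable sites in any pair")
  tot / np
}

#' Watterson's estimator of theta
#'
#' `theta_W = S / a1` with `a1 = sum(1/i, i = 1..n-1)`; per locus, or per
#' site when `per_site = TRUE` (divided by the number of complete-deletion
#' columns).
#'
#' @inheritParams segregating_sites
#' @param per_site divide by the usable alignment length
#' @return theta estimate
#' @export
watterson_theta <- function(x, per_site = FALSE) {
  core <- polymorphism_core(x)
  a1 <- sum(1 / seq_len(core$n - 1))
  th <- core$S / a1
  if (per_site) th / core$L_used else th
}

# ---- neutrality statistics from summary quantities --------------------------

tajima_d_from <- function(n, S, kbar) {
  if (S < 1) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (kbar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

fu_li_dstar_from <- function(n, eta, eta_s) {
  if (eta < 1) return(NA_real_)
  if (n < 3) return(NA_real_)
  i <- seq_len(n - 1)
  an <- sum(1 / i); bn <- sum(1 / i^2)
  an1 <- an + 1 / n
  cn <- if (n == 2) 1 else 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vd <- ((n / (n - 1))^2 * bn + an^2 * dn -
           2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
  ud <- (n / (n - 1)) * (an - n / (n - 1)) - vd
  ((n / (n - 1)) * eta - an * eta_s) / sqrt(ud * eta + vd * eta^2)
}

# log |s(n, k)| for k = 1..n (unsigned Stirling numbers of the first kind),
# computed in log space so n up to ~60 is safe.
log_stirling_first <- function(n) {
  logS <- c(0)                       # n = 1: |s(1,1)| = 1
  if (n == 1) return(logS)
  for (m in 1:(n - 1)) {
    prev <- logS
    cur <- numeric(m + 1)
    for (k in seq_len(m + 1)) {
      from_k1 <- if (k >= 2) prev[k - 1] else -Inf
      from_k  <- if (k <= m) log(m) + prev[k] else -Inf
      cur[k] <- logsumexp(c(from_k1, from_k))
    }
    logS <- cur
  }
  logS
}

# P(K >= k_obs | theta) under the Ewens sampling formula.
ewens_p_k_ge <- function(n, k_obs, theta) {
  logS <- log_stirling_first(n)
  k <- seq_len(n)
  log_rising <- sum(log(theta + 0:(n - 1)))
  logp <- logS + k * log(theta) - log_rising
  sum(exp(logp[k >= k_obs]))
}

fu_fs_from <- function(n, kbar, K) {
  if (!is.finite(kbar) || kbar <= 0) return(NA_real_)
  sp <- ewens_p_k_ge(n, K, kbar)
  if (sp <= 0 || sp >= 1) return(NA_real_)   # boundary (e.g. K = 1)
  log(sp / (1 - sp))
}

#' Tajima's D
#'
#' `D = (kbar - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the constants of
#' Tajima (1989).  Returns `NA` (with a message) when there are no
#' segregating sites.
#'
#' @inheritParams segregating_sites
#' @return D, or `NA` for monomorphic data
#' @export
tajimas_d <- function(x) {
  core <- polymorphism_core(x)
  if (core$S < 1) {
    message("tajimas_d: no segregating sites; statistic not available")
    return(NA_real_)
  }
  tajima_d_from(core$n, core$S, core$kbar)
}

#' Fu and Li's D* (without outgroup)
#'
#' Contrasts the total number of mutations `eta` with the singleton count
#' `eta_s` (mutations whose minor allele occurs in exactly one sequence),
#' using the corrected variance constants adopted by standard polymorphism
#' software.
#'
#' @inheritParams segregating_sites
#' @return D*, or `NA` for monomorphic data
#' @export
fu_li_d_star <- function(x) {
  core <- polymorphism_core(x)
  if (core$eta < 1) {
    message("fu_li_d_star: no mutations; statistic not available")
    return(NA_real_)
  }
  fu_li_dstar_from(core$n, core$eta, core$eta_s)
}

#' Fu's Fs
#'
#' `S' = P(K >= k_obs | theta_pi)` under the Ewens sampling formula,
#' `P(K = k) = |s(n,k)| theta^k / (theta)_n` with unsigned Stirling numbers
#' of the first kind and the rising factorial, where `theta_pi` is the mean
#' number of pairwise differences; `Fs = ln(S'/(1 - S'))`.  Monomorphic
#' data, or a boundary `S'` of 0/1 (e.g. a single haplotype), return `NA`.
#'
#' @inheritParams segregating_sites
#' @return Fs, or `NA` when undefined
#' @export
fu_fs <- function(x) {
  core <- polymorphism_core(x)
  if (core$kbar <= 0) {
    message("fu_fs: monomorphic data; statistic not available")
    return(NA_real_)
  }
  out <- fu_fs_from(core$n, core$kbar, core$K)
  if (is.na(out)) message("fu_fs: boundary haplotype count; not available")
  out
}

#' Empirical significance of a neutrality statistic
#'
#' Compares an observed statistic with its distribution over neutral
#' coalescent replicates conditioned on the sample size and the observed
#' number of segregating sites (`fixed_S`, the default) or on a mutation
#' rate (`fixed_theta`).  `D` and `D*` get a two-sided empirical p (twice
#' the smaller tail, capped at 1); `Fs` a one-sided lower-tail p.
#'
#' @param stat_value observed statistic
#' @param n sample size
#' @param S observed segregating sites (or theta in `fixed_theta` mode)
#' @param statistic one of `"D"`, `"D_star"`, `"Fs"`
#' @param n_reps coalescent replicates (warns below 100)
#' @param seed RNG seed (required for reproducibility)
#' @param theta_mode `"fixed_S"` or `"fixed_theta"`
#' @return list with `p`, `n_reps`, and the sampled `distribution`
#' @export
neutrality_significance <- function(stat_value, n, S,
                                    statistic = c("D", "D_star", "Fs"),
                                    n_reps = 1000, seed = NULL,
                                    theta_mode = c("fixed_S", "fixed_theta")) {
  statistic <- match.arg(statistic)
  theta_mode <- match.arg(theta_mode)
  if (n_reps < 100)
    warning("fewer than 100 null replicates; p-value is coarse")
  null <- simulate_neutral_null(n = n, S = S, n_reps = n_reps, seed = seed,
                                theta_mode = theta_mode)
  dist <- null[[statistic]]
  dist <- dist[is.finite(dist)]
  m <- length(dist)
  if (m == 0) stop("null distribution is empty (all replicates undefined)")
  p_low <- (1 + sum(dist <= stat_value)) / (m + 1)
  p_high <- (1 + sum(dist >= stat_value)) / (m + 1)
  p <- if (statistic == "Fs") p_low else min(1, 2 * min(p_low, p_high))
  list(p = p, n_reps = m, distribution = dist, statistic = statistic)
}

#' Per-group polymorphism summary (the standard per-locus panel)
#'
#' One row per phenotype group plus a pooled `Total` row, each with: `two_n`
#' (sequences), `S`, `n_syn`, `n_nonsyn`, `h`, `hd`, `pi`, `theta_w` (per
#' site), `D`, `D_star`, `Fs`, and (when `null_reps > 0`) their empirical
#' p-values from the fixed-S coalescent null.
#'
#' With `ambiguity = "exclude"` (the default) sequences containing
#' ambiguity codes are dropped from haplotype counting and the site
#' statistics use the sequences as given; with `"expand"` every
#' heterozygous sequence is replaced by its two naive pseudo-phases before
#' *all* statistics are computed, so a diploid direct-sequencing panel is
#' summarised on the 2n chromosome scale.  Groups with fewer than 2 usable
#' sequences get `NA` statistics.
#'
#' @param aln an `ace1_alignment`
#' @param groups named character vector mapping sequence id to group
#' @param null_reps coalescent replicates for significance (0 = skip)
#' @param seed RNG seed for the null
#' @param ambiguity `"exclude"` or `"expand"` (see Details)
#' @return data.frame, one row per group plus `Total`
#' @export
summarize_polymorphism <- function(aln, groups, null_reps = 0, seed = NULL,
                                   ambiguity = c("exclude", "expand")) {
  stopifnot(inherits(aln, "ace1_alignment"))
  ambiguity <- match.arg(ambiguity)
  seqs <- as_seq_vector(aln)
  if (is.null(names(groups)) || !all(names(groups) %in% names(seqs)))
    stop("groups must be a named vector over the alignment's sequence ids")
  if (ambiguity == "expand") {
    ex <- resolve_ambiguous(seqs, groups, "expand")
    seqs <- ex$seqs; groups <- ex$groups
  }
  glev <- unique(unname(groups[names(seqs)[names(seqs) %in% names(groups)]]))
  panels <- c(setNames(as.list(glev), glev), list(Total = NULL))
  rows <- lapply(names(panels), function(g) {
    ids <- if (g == "Total") names(seqs) else
      names(groups)[groups == g]
    sub <- seqs[names(seqs) %in% ids]
    row <- data.frame(group = g, two_n = length(sub), S = NA_integer_,
                      n_syn = NA_integer_, n_nonsyn = NA_integer_,
                      h = NA_integer_, hd = NA_real_, pi = NA_real_,
                      theta_w = NA_real_, D = NA_real_, D_star = NA_real_,
                      Fs = NA_real_, p_D = NA_real_, p_Dstar = NA_real_,
                      p_Fs = NA_real_)
    if (length(sub) < 2) return(row)
    core <- polymorphism_core(sub)
    sub_aln <- ace1_alignment(unname(sub), names(sub),
                              codon_column = aln$codon_column,
                              frame_offset = aln$frame_offset)
    cc <- classify_coding_changes(sub_aln)
    haps <- tryCatch(collapse_haplotypes(sub), error = function(e) NULL)
    row$S <- core$S
    row$n_syn <- cc$n_syn; row$n_nonsyn <- cc$n_nonsyn
    if (!is.null(haps)) {
      row$h <- nrow(haps)
      row$hd <- if (sum(haps$frequency) >= 2)
        haplotype_diversity(haps$frequency) else NA_real_
    }
    row$pi <- nucleotide_diversity(sub)
    row$theta_w <- watterson_theta(sub, per_site = TRUE)
    row$D <- tajima_d_from(core$n, core$S, core$kbar)
    row$D_star <- fu_li_dstar_from(core$n, core$eta, core$eta_s)
    row$Fs <- fu_fs_from(core$n, core$kbar, core$K)
    if (null_reps > 0 && core$S >= 1) {
      null <- simulate_neutral_null(core$n, core$S, n_reps = null_reps,
                                    seed = seed)
      emp <- function(obs, dist, two_sided) {
        dist <- dist[is.finite(dist)]
        if (!length(dist) || is.na(obs)) return(NA_real_)
        pl <- (1 + sum(dist <= obs)) / (length(dist) + 1)
        ph <- (1 + sum(dist >= obs)) / (length(dist) + 1)
        if (two_sided) min(1, 2 * min(pl, ph)) else pl
      }
      row$p_D <- emp(row$D, null$D, TRUE)
      row$p_Dstar <- emp(row$D_star, null$D_star, TRUE)
      row$p_Fs <- emp(row$Fs, null$Fs, FALSE)
    }
    row
  })
  do.call(rbind, rows)
}
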