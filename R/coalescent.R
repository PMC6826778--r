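# Neutral coalescent machinery: genealogy sampling, infinite-sites mutation
# placement, and the fixed-S null used by the neutrality tests.

# Sample a standard n-coalescent genealogy.  Returns, for each of the
# 2n - 2 branches, its length (in coalescent time units), the set of leaves
# it subtends, and that set's size.
sim_genealogy <- function(n) {
  stopifnot(n >= 2)
  active_sets <- as.list(seq_len(n))
  active_len <- numeric(n)
  nb <- 2L * n - 2L
  sets <- vector("list", nb); lens <- numeric(nb); sizes <- integer(nb)
  b <- 0L
  k <- n
  while (k > 1) {
    t <- rexp(1, rate = k * (k - 1) / 2)
    active_len <- active_len + t
    pick <- sample.int(k, 2)
    for (idx in pick) {
      b <- b + 1L
      sets[[b]] <- active_sets[[idx]]
      lens[b] <- active_len[idx]
      sizes[b] <- length(active_sets[[idx]])
    }
    merged <- c(active_sets[[pick[1]]], active_sets[[pick[2]]])
    keep <- setdiff(seq_len(k), pick)
    active_sets <- c(active_sets[keep], list(merged))
    active_len <- c(active_len[keep], 0)
    k <- k - 1L
  }
  list(sets = sets, lens = lens, sizes = sizes)
}

# Place `S` mutations on a genealogy (multinomially, proportional to branch
# length) and return the n x S binary incidence matrix (1 = derived).
place_mutations <- function(gen, S, n) {
  mat <- matrix(0L, nrow = n, ncol = S)
  if (S > 0) {
    idx <- sample.int(length(gen$lens), S, replace = TRUE, prob = gen$lens)
    for (j in seq_len(S)) mat[gen$sets[[idx[j]]], j] <- 1L
  }
  mat
}

stats_from_incidence <- function(mat) {
  n <- nrow(mat); S <- ncol(mat)
  if (S == 0)
    return(list(n = n, S = 0L, kbar = 0, eta = 0L, eta_s = 0L, K = 1L))
  cs <- colSums(mat)
  kbar <- sum(cs * (n - cs)) / choose(n, 2)
  eta_s <- sum(cs == 1L | cs == n - 1L)
  K <- length(unique(apply(mat, 1, paste, collapse = "")))
  list(n = n, S = S, kbar = kbar, eta = S, eta_s = eta_s, K = K)
}

#' Neutral coalescent null distributions for D, D* and Fs
#'
#' Simulates `n_reps` neutral coalescent samples of size `n`, conditioning
#' either on the observed number of segregating sites (`fixed_S`: exactly
#' `S` mutations dropped multinomially on the genealogy, the standard
#' practice when comparing to an observed S) or on a mutation rate
#' (`fixed_theta`: `S ~ Poisson(theta * L_tree / 2)` with `theta = S`
#' interpreted as the rate).
#'
#' @param n sample size (>= 3 recommended)
#' @param S observed segregating sites (or theta in `fixed_theta` mode)
#' @param n_reps number of replicates
#' @param seed RNG seed; `NULL` uses the current RNG stream
#' @param theta_mode `"fixed_S"` or `"fixed_theta"`
#' @return list with numeric vectors `D`, `D_star`, `Fs` of length `n_reps`
#'   (entries `NA` where a statistic is undefined for that replicate)
#' @export
simulate_neutral_null <- function(n, S, n_reps = 1000, seed = NULL,
                                  theta_mode = c("fixed_S", "fixed_theta")) {
  theta_mode <- match.arg(theta_mode)
  stopifnot(n >= 2, n_reps >= 1)
  with_seed(seed, {
    D <- Ds <- Fs <- rep(NA_real_, n_reps)
    for (r in seq_len(n_reps)) {
      gen <- sim_genealogy(n)
      s_r <- if (theta_mode == "fixed_S") S else
        rpois(1, S * sum(gen$lens) / 2)
      mat <- place_mutations(gen, s_r, n)
      st <- stats_from_incidence(mat)
      if (st$S >= 1) {
        D[r] <- tajima_d_from(st$n, st$S, st$kbar)
        Ds[r] <- fu_li_dstar_from(st$n, st$eta, st$eta_s)
        Fs[r] <- fu_fs_from(st$n, st$kbar, st$K)
      }
    }
    list(D = D, D_star = Ds, Fs = Fs)
  })
}

#' Sample haplotypes under the neutral coalescent with infinite sites
#'
#' Draws a genealogy, places `Poisson(theta * L_tree / 2)` mutations on it
#' (so a pair of sequences is expected to differ at `theta` sites), assigns
#' each mutation a distinct column of an `L`-column grid, and writes derived
#' bases over an ancestral background sequence.
#'
#' @param n sample size (>= 2)
#' @param theta scaled mutation rate for the whole locus (4Nu)
#' @param L locus length in columns
#' @param seed RNG seed; `NULL` uses the current RNG stream
#' @param ancestral ancestral background (character vector of `L` bases);
#'   generated uniformly at random when `NULL`
#' @param exclude_columns columns mutations may never hit (e.g. the
#'   diagnostic codon column)
#' @return list with `seqs` (named character vector of `n` sequences),
#'   `sites` (mutated columns), `incidence` (n x S matrix), `S`,
#'   `ancestral`
#' @export
coalescent_sample <- function(n, theta, L, seed = NULL, ancestral = NULL,
                              exclude_columns = integer(0)) {
  stopifnot(n >= 2, theta > 0, L >= 1)
  with_seed(seed, {
    if (is.null(ancestral))
      ancestral <- sample(DNA_BASES, L, replace = TRUE)
    stopifnot(length(ancestral) == L)
    gen <- sim_genealogy(n)
    total_len <- sum(gen$lens)
    S <- rpois(1, theta * total_len / 2)
    avail <- setdiff(seq_len(L), exclude_columns)
    if (S > length(avail))
      stop(sprintf(
        "%d mutations exceed the %d available columns; increase L",
        S, length(avail)))
    sites <- if (S > 0) sort(sample(avail, S)) else integer(0)
    mat <- place_mutations(gen, S, n)
    m <- matrix(rep(ancestral, each = n), nrow = n)
    for (j in seq_len(S)) {
      derived <- sample(setdiff(DNA_BASES, ancestral[sites[j]]), 1)
      m[mat[, j] == 1L, sites[j]] <- derived
    }
    seqs <- setNames(apply(m, 1, paste, collapse = ""),
                     paste0("h", seq_len(n)))
    list(seqs = seqs, sites = sites, incidence = mat, S = S,
         ancestral = ancestral)
  })
}
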