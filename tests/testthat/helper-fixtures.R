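# Shared fixtures and independent oracles, built in code.

# random unambiguous alignment (n sequences, L columns)
random_alignment <- function(n, L, bases = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i)
    paste(sample(bases, L, replace = TRUE), collapse = ""),
    character(1)) |> setNames(paste0("s", seq_len(n)))
}

# random low-divergence alignment: mutate a common backbone at a few sites
random_related_alignment <- function(n, L, n_mut = 5) {
  backbone <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  vapply(seq_len(n), function(i) {
    ch <- backbone
    k <- sample(0:n_mut, 1)
    if (k > 0) {
      pos <- sample(L, k)
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    }
    paste(ch, collapse = "")
  }, character(1)) |> setNames(paste0("s", seq_len(n)))
}

# brute-force mean pairwise difference per site (pairwise deletion)
oracle_pi <- function(seqs) {
  n <- length(seqs)
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  tot <- 0; np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] %in% c("A", "C", "G", "T") & m[j, ] %in% c("A", "C", "G", "T")
    tot <- tot + sum(m[i, ok] != m[j, ok]) / sum(ok)
    np <- np + 1
  }
  tot / np
}

# exact unsigned Stirling numbers of the first kind, plain integer recurrence
# (safe in doubles up to n ~ 15)
oracle_stirling <- function(n) {
  s <- matrix(0, n + 1, n + 1)
  s[1, 1] <- 1  # s(0,0)
  for (m in 1:n) for (k in 1:m)
    s[m + 1, k + 1] <- s[m, k] + (m - 1) * s[m, k + 1]
  s[n + 1, 2:(n + 1)]
}

# Fu's Fs by direct Ewens-formula evaluation with exact Stirling numbers
oracle_fs <- function(n, theta, k_obs) {
  st <- oracle_stirling(n)
  rising <- prod(theta + 0:(n - 1))
  pk <- st * theta^(1:n) / rising
  sp <- sum(pk[k_obs:n])
  log(sp / (1 - sp))
}

# two-tailed Fisher exact by hypergeometric enumeration with choose()
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  pr <- vapply(lo:hi, function(x)
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1), numeric(1))
  p_obs <- pr[a - lo + 1]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# exact HWE p by direct enumeration of the conditional distribution
oracle_hwe <- function(n_SS, n_GS, n_GG) {
  n <- n_SS + n_GS + n_GG
  na <- 2 * n_SS + n_GS; nb <- 2 * n_GG + n_GS
  if (na == 0 || nb == 0) return(1)
  hets <- seq(na %% 2, min(na, nb), by = 2)
  pr <- vapply(hets, function(h) {
    naa <- (na - h) / 2; nbb <- (nb - h) / 2
    exp(lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
          h * log(2) + lfactorial(na) + lfactorial(nb) - lfactorial(2 * n))
  }, numeric(1))
  p_obs <- pr[match(n_GS, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-10)]))
}

# Kimura 2-parameter distance, written independently of the package
oracle_k2p <- function(x, y) {
  cx <- strsplit(x, "")[[1]]; cy <- strsplit(y, "")[[1]]
  diff <- cx != cy
  ts <- diff & ((cx %in% c("A", "G") & cy %in% c("A", "G")) |
                  (cx %in% c("C", "T") & cy %in% c("C", "T")))
  P <- mean(ts); Q <- mean(diff & !ts)
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

# pair of sequences with exactly balanced base composition (pair GC = 0.5):
# differences are introduced by exchanging the values of two sites, which
# preserves composition; A/G and C/T exchanges give transitions, A/T and
# C/G exchanges give transversions
gc_balanced_pair <- function(L = 80, n_ts = 3, n_tv = 2) {
  x <- sample(rep(c("A", "C", "G", "T"), L / 4))
  y <- x
  swap <- function(b1, b2, k) {
    i <- sample(which(y == b1 & x == y), k)
    j <- sample(which(y == b2 & x == y), k)
    y[i] <<- b2; y[j] <<- b1
  }
  swap("A", "G", n_ts)
  swap("C", "T", n_ts)
  if (n_tv > 0) { swap("A", "T", n_tv); swap("C", "G", n_tv) }
  c(paste(x, collapse = ""), paste(y, collapse = ""))
}

# write a temporary fasta and return its path
tmp_fasta <- function(seqs, ids = names(seqs)) {
  f <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(seq_along(seqs), function(i)
    c(paste0(">", ids[i]), seqs[[i]]))), f)
  f
}
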