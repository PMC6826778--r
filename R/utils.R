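# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide codes accepted on input (DNA only; U is rejected).
IUPAC_CHARS <- c(DNA_BASES, "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

# base-set -> ambiguity code, keyed by sorted concatenation of bases
IUPAC_FROM_SET <- c(
  A = "A", C = "C", G = "G", T = "T",
  AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M",
  CGT = "B", AGT = "D", ACT = "H", ACG = "V", ACGT = "N"
)

iupac_consensus_base <- function(bases) {
  key <- paste(sort(unique(bases[bases %in% DNA_BASES])), collapse = "")
  if (!nzchar(key)) return("N")
  unname(IUPAC_FROM_SET[key])
}

is_unambiguous <- function(x) x %in% DNA_BASES

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL uses the ambient RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# split equal-length sequences into an n x L character matrix
seq_char_matrix <- function(seqs) {
  stopifnot(length(seqs) >= 1)
  L <- unique(nchar(seqs))
  if (length(L) != 1)
    stop("sequences must have equal length", call. = FALSE)
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), ncol = L, byrow = TRUE)
  rownames(m) <- names(seqs)
  m
}

# Accept either an ace1_alignment or a (named) character vector of sequences.
as_seq_vector <- function(x) {
  if (inherits(x, "ace1_alignment")) return(setNames(x$seq, x$id))
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(x)
  }
  stop("expected an ace1_alignment or a character vector of sequences",
       call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
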