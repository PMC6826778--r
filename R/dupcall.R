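# Duplication inference from cloned amplicon haplotypes.  A diploid
# single-copy locus can show at most two distinct haplotypes per
# individual; more than two distinct cloned haplotypes (after PCR/cloning
# error filtering) is the signature of a gene duplication.

#' Per-individual set of cloned haplotype sequences
#'
#' @param individual_id specimen label (e.g. `BenA1`, `PropA5`)
#' @param clones character vector of equal-length aligned clone sequences
#'   (haploid by construction; ambiguity codes are rejected)
#' @param insecticide,phenotype optional metadata
#' @return object of class `clone_set`
#' @export
clone_set <- function(individual_id, clones, insecticide = NA,
                      phenotype = NA) {
  if (length(clones) == 0) stop("argument error: empty clone set")
  clones <- toupper(as.character(clones))
  if (length(unique(nchar(clones))) != 1)
    stop("clone sequences must be aligned to equal length")
  bad <- vapply(strsplit(clones, "", fixed = TRUE),
                function(ch) any(!ch %in% c(DNA_BASES, "-")), logical(1))
  if (any(bad))
    stop(sprintf(
      "clone sequences must be unambiguous (clone %d of '%s' has IUPAC codes)",
      which(bad)[1], individual_id))
  structure(list(individual_id = individual_id, clones = unname(clones),
                 insecticide = insecticide, phenotype = phenotype),
            class = "clone_set")
}

#' Collapse clones into supported haplotypes under a PCR-error model
#'
#' Identical clones are merged.  A haplotype supported by fewer than
#' `min_support` clones that lies within `max_err_dist` substitutions of a
#' better-supported haplotype is absorbed into that haplotype (its support
#' transfers); absorption sweeps repeat until stable, so the operation is
#' idempotent.  The literal defaults (`min_support = 1`, `max_err_dist =
#' 0`) keep every distinct clone as an allele; the error-aware setting
#' (`min_support = 2`, `max_err_dist = 1`) absorbs likely single-substitution
#' PCR/cloning artefacts.
#'
#' @param cs a `clone_set`
#' @param min_support minimum clone support for a free-standing haplotype
#' @param max_err_dist absorption radius in substitutions
#' @return data.frame with columns `seq`, `support`, ordered by decreasing
#'   support then first appearance
#' @export
collapse_clones <- function(cs, min_support = 1L, max_err_dist = 0L) {
  stopifnot(inherits(cs, "clone_set"))
  uniq <- unique(cs$clones)
  support <- vapply(uniq, function(u) sum(cs$clones == u), integer(1))
  repeat {
    ord <- order(-support, match(uniq, unique(cs$clones)))
    uniq <- uniq[ord]; support <- unname(support[ord])
    if (length(uniq) == 1) break
    d <- hamming_matrix(setNames(uniq, paste0("u", seq_along(uniq))))
    absorbed <- FALSE
    for (i in rev(seq_along(uniq))) {
      if (support[i] >= min_support) next
      cand <- which(support > support[i] & d[i, ] <= max_err_dist &
                      seq_along(uniq) != i)
      if (length(cand)) {
        k <- cand[which.max(support[cand])]
        support[k] <- support[k] + support[i]
        uniq <- uniq[-i]; support <- support[-i]
        absorbed <- TRUE
        break
      }
    }
    if (!absorbed) break
  }
  data.frame(seq = uniq, support = support, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Call a gene duplication from an individual's haplotypes
#'
#' `duplicated` is true exactly when more than two distinct haplotypes
#' remain after filtering (a diploid single-copy locus carries at most
#' two).  Resistance composition is read at the diagnostic column, and the
#' dosage-based genotyping call the individual would receive is predicted
#' from that composition.
#'
#' @param haplotypes data.frame from [collapse_clones()] (columns `seq`,
#'   `support`), or a character vector of distinct haplotypes
#' @param codon_column 1-based diagnostic column
#' @param dominance_threshold passed to [predict_taqman_call()]
#' @return object of class `duplication_call` with `distinct_haplotypes`,
#'   `n_resistant`, `n_susceptible`, `n_undetermined`, `duplicated`,
#'   `predicted_taqman`, `evidence`
#' @export
call_duplication <- function(haplotypes, codon_column,
                             dominance_threshold = 0.75) {
  if (is.character(haplotypes))
    haplotypes <- data.frame(seq = unique(haplotypes),
                             support = 1L, stringsAsFactors = FALSE)
  stopifnot(all(c("seq", "support") %in% names(haplotypes)))
  base <- substr(haplotypes$seq, codon_column, codon_column)
  n_r <- sum(base == "A"); n_s <- sum(base == "G")
  n_u <- nrow(haplotypes) - n_r - n_s
  call <- if (n_r + n_s == 0) "undetermined" else
    predict_taqman_call(n_r, n_s, dominance_threshold)
  structure(list(distinct_haplotypes = nrow(haplotypes),
                 n_resistant = n_r, n_susceptible = n_s,
                 n_undetermined = n_u,
                 duplicated = nrow(haplotypes) > 2L,
                 predicted_taqman = call,
                 evidence = haplotypes),
            class = "duplication_call")
}

#' @export
print.duplication_call <- function(x, ...) {
  cat(sprintf(
    "duplication_call: %d distinct haplotypes (%dR/%dS%s) -> %s, predicted TaqMan %s\n",
    x$distinct_haplotypes, x$n_resistant, x$n_susceptible,
    if (x$n_undetermined) sprintf("/%d?", x$n_undetermined) else "",
    if (x$duplicated) "DUPLICATED" else "not duplicated",
    x$predicted_taqman))
  invisible(x)
}

#' Predict the dosage-based (TaqMan) genotype call from copy composition
#'
#' Allelic-discrimination genotyping reads allele dosage, not copy number:
#' an individual whose resistant-copy fraction is at least
#' `dominance_threshold` is scored homozygote resistant (`RR`), at most
#' `1 - dominance_threshold` homozygote susceptible (`SS`), and otherwise
#' heterozygote (`RS`).  The default 0.75 makes a duplicated 3R+1S
#' individual read as `RR` -- the dosage artefact behind the apparent
#' heterozygote deficit in duplicated populations.
#'
#' @param n_R_copies,n_S_copies non-negative copy counts, sum >= 1
#' @param dominance_threshold fraction in (0.5, 1]
#' @return one of `"RR"`, `"RS"`, `"SS"`
#' @export
predict_taqman_call <- function(n_R_copies, n_S_copies,
                                dominance_threshold = 0.75) {
  if (n_R_copies < 0 || n_S_copies < 0)
    stop("argument error: copy counts must be non-negative")
  total <- n_R_copies + n_S_copies
  if (total < 1) stop("argument error: zero total copies")
  fr <- n_R_copies / total
  if (fr >= dominance_threshold) "RR"
  else if (fr <= 1 - dominance_threshold) "SS"
  else "RS"
}

#' Merge direct-sequencing and cloned alignments over their common region
#'
#' Both alignments are truncated to the intersection of their coordinate
#' intervals (each `ace1_alignment` carries a `start` coordinate in a
#' shared reference system); cloned-specimen sequence ids get a `-d`
#' suffix.  The merged alignment feeds the polymorphism, network and tree
#' stages unchanged.
#'
#' @param direct,cloned `ace1_alignment`s covering overlapping intervals
#' @return merged `ace1_alignment` over the common interval
#' @export
joint_haplotype_merge <- function(direct, cloned) {
  stopifnot(inherits(direct, "ace1_alignment"),
            inherits(cloned, "ace1_alignment"))
  s <- max(direct$start, cloned$start)
  e <- min(direct$start + direct$length - 1L,
           cloned$start + cloned$length - 1L)
  if (e < s) stop("empty intersection between the two alignments")
  cut <- function(aln) substr(aln$seq, s - aln$start + 1L,
                              e - aln$start + 1L)
  ids <- c(direct$id, paste0(cloned$id, "-d"))
  cc <- direct$codon_column
  if (!is.null(cc)) {
    cc_abs <- cc + direct$start - 1L
    cc <- if (cc_abs >= s && cc_abs <= e) cc_abs - s + 1L else NULL
  }
  ace1_alignment(c(cut(direct), cut(cloned)), ids, codon_column = cc,
                 frame_offset = (direct$frame_offset +
                                   (s - direct$start)) %% 3L,
                 start = s)
}

#' Read per-individual clone FASTA files from a directory
#'
#' @param dir directory containing one FASTA per individual
#' @param pattern filename glob whose stem is the individual id (default
#'   `*.fasta`)
#' @return list of `clone_set`
#' @export
read_clone_sets <- function(dir, pattern = "*.fasta") {
  files <- Sys.glob(file.path(dir, pattern))
  if (!length(files)) stop(sprintf("no clone files matching '%s' in %s",
                                   pattern, dir))
  lapply(files, function(f) {
    seqs <- read_fasta(f, aligned = FALSE)
    clone_set(sub("\\.[^.]*$", "", basename(f)), unname(seqs))
  })
}

#' Duplication calls for a list of clone sets
#'
#' @param clone_sets list of `clone_set`
#' @param codon_column 1-based diagnostic column
#' @param min_support,max_err_dist passed to [collapse_clones()]
#' @param min_clones clone sets with fewer clones are skipped (the
#'   convention is to require at least three cloned haplotypes)
#' @return data.frame, one row per individual
#' @export
duplication_table <- function(clone_sets, codon_column, min_support = 1L,
                              max_err_dist = 0L, min_clones = 3L) {
  rows <- lapply(clone_sets, function(cs) {
    if (length(cs$clones) < min_clones) {
      return(data.frame(individual = cs$individual_id,
                        n_clones = length(cs$clones),
                        distinct_haplotypes = NA_integer_,
                        n_resistant = NA_integer_,
                        n_susceptible = NA_integer_,
                        duplicated = NA, predicted_taqman = NA_character_))
    }
    haps <- collapse_clones(cs, min_support, max_err_dist)
    dc <- call_duplication(haps, codon_column)
    data.frame(individual = cs$individual_id, n_clones = length(cs$clones),
               distinct_haplotypes = dc$distinct_haplotypes,
               n_resistant = dc$n_resistant,
               n_susceptible = dc$n_susceptible,
               duplicated = dc$duplicated,
               predicted_taqman = dc$predicted_taqman)
  })
  do.call(rbind, rows)
}
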