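#' Construct an aligned set of Ace-1 amplicon sequences
#'
#' An `ace1_alignment` holds equal-length nucleotide sequences (IUPAC
#' ambiguity codes allowed) together with the 1-based column of the
#' diagnostic G119S site and the reading-frame offset of the amplicon.
#'
#' Coordinates are 1-based and inclusive throughout: the diagnostic
#' substitution quoted at "position 397" of a 705 bp alignment is column
#' 397.  Because published coordinates may index either the raw amplicon or
#' the trimmed alignment, `codon_column` is always supplied by the caller
#' and never hard-coded.
#'
#' @param seqs character vector of upper-case nucleotide sequences of equal
#'   length.  Lower-case input is upper-cased; `U` is rejected (DNA only).
#' @param ids sequence identifiers; unique, non-empty.  Defaults to
#'   `names(seqs)`.
#' @param codon_column 1-based column of the diagnostic site (first base of
#'   codon 119), or `NULL` if not yet known.
#' @param frame_offset integer in `0:2`; the first complete codon starts at
#'   column `frame_offset + 1`.
#' @param start 1-based coordinate of the first column in a shared reference
#'   system (used when merging alignments that cover different intervals).
#' @return an object of class `ace1_alignment` with fields `id`, `seq`,
#'   `length`, `codon_column`, `frame_offset`, `start`.
#' @export
ace1_alignment <- function(seqs, ids = names(seqs), codon_column = NULL,
                           frame_offset = 0L, start = 1L) {
  force(ids)   # the default reads names(seqs) before they are stripped
  seqs <- toupper(as.character(seqs))
  if (length(seqs) == 0) stop("alignment needs at least one sequence")
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  ids <- as.character(ids)
  if (any(!nzchar(ids)) || anyDuplicated(ids))
    stop("sequence ids must be non-empty and unique")
  validate_dna(seqs, ids)
  L <- unique(nchar(seqs))
  if (length(L) != 1)
    stop(sprintf("alignment error: unequal sequence lengths (%s)",
                 paste(sort(unique(nchar(seqs))), collapse = ", ")))
  if (!is.null(codon_column)) {
    codon_column <- as.integer(codon_column)
    if (codon_column < 1L || codon_column > L)
      stop("codon_column must lie within the alignment (1-based)")
  }
  frame_offset <- as.integer(frame_offset)
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")
  structure(
    list(id = ids, seq = unname(seqs), length = L,
         codon_column = codon_column, frame_offset = frame_offset,
         start = as.integer(start)),
    class = "ace1_alignment")
}

validate_dna <- function(seqs, ids) {
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    if (length(ch) == 0)
      stop(sprintf("parse error: record '%s' has an empty sequence", ids[i]))
    bad <- which(!ch %in% IUPAC_CHARS)
    if (length(bad)) {
      extra <- if (ch[bad[1]] == "U") " (RNA 'U' not accepted; DNA only)" else ""
      stop(sprintf(
        "parse error: record '%s' has illegal character '%s' at position %d%s",
        ids[i], ch[bad[1]], bad[1], extra))
    }
  }
  invisible(TRUE)
}

#' @export
print.ace1_alignment <- function(x, ...) {
  cat(sprintf("ace1_alignment: %d sequences x %d columns\n",
              length(x$id), x$length))
  if (!is.null(x$codon_column))
    cat(sprintf("  diagnostic column: %d (1-based), frame offset %d\n",
                x$codon_column, x$frame_offset))
  invisible(x)
}

#' Number of sequences in an alignment
#' @param aln an `ace1_alignment`
#' @return integer count
#' @export
n_seq <- function(aln) length(aln$id)

#' Read a FASTA file of nucleotide sequences
#'
#' Parsing is done with [Biostrings::readBStringSet]; records are then
#' validated against the IUPAC DNA alphabet (plus `-` and `N`), upper-cased,
#' and (in aligned mode) checked for equal lengths.
#'
#' @param path FASTA file
#' @param aligned enforce equal lengths (default `TRUE`)
#' @inheritParams ace1_alignment
#' @return an `ace1_alignment` (or, with `aligned = FALSE`, a named
#'   character vector of sequences)
#' @export
read_fasta <- function(path, aligned = TRUE, codon_column = NULL,
                       frame_offset = 0L, start = 1L) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop(sprintf("parse error in '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE))
  seqs <- toupper(as.character(set))
  ids <- names(set)
  ids <- sub("\\s.*$", "", ids)   # id = first whitespace-delimited token
  if (any(!nzchar(ids)))
    stop(sprintf("parse error in '%s': empty record header", path))
  if (anyDuplicated(ids))
    stop(sprintf("parse error in '%s': duplicate record id '%s'",
                 path, ids[anyDuplicated(ids)]))
  validate_dna(seqs, ids)
  if (!aligned) return(setNames(seqs, ids))
  ace1_alignment(seqs, ids, codon_column = codon_column,
                 frame_offset = frame_offset, start = start)
}

#' Write sequences to FASTA
#'
#' @param x an `ace1_alignment` or named character vector of sequences
#' @param path output file
#' @param width line-wrap width (default 70)
#' @return `path`, invisibly
#' @export
write_fasta <- function(x, path, width = 70L) {
  seqs <- as_seq_vector(x)
  set <- Biostrings::BStringSet(seqs)
  tryCatch(Biostrings::writeXStringSet(set, filepath = path, width = width),
           error = function(e)
             stop(sprintf("I/O error writing '%s': %s", path,
                          conditionMessage(e)), call. = FALSE))
  invisible(path)
}

#' Classify a sequence at the diagnostic resistance codon
#'
#' Reads the single diagnostic column (the G-to-A substitution site of codon
#' 119): `G` is susceptible (119G/Gly), `A` resistant (119S/Ser), `R` (the
#' A/G ambiguity from overlapping chromatogram peaks) heterozygous, and any
#' other code or a gap undetermined.  Classification is a pure function of
#' that one column.
#'
#' @param aln an `ace1_alignment` with `codon_column` set
#' @param record_id id of the sequence to classify (omit to classify all)
#' @return one of `"resistant"`, `"susceptible"`, `"heterozygous"`,
#'   `"undetermined"` (a named vector when `record_id` is omitted)
#' @export
classify_at_codon <- function(aln, record_id = NULL) {
  stopifnot(inherits(aln, "ace1_alignment"))
  if (is.null(aln$codon_column))
    stop("codon_column is not set on this alignment")
  states <- codon_states(aln)
  if (is.null(record_id)) return(states)
  if (!record_id %in% aln$id)
    stop(sprintf("lookup error: no record '%s' in alignment", record_id))
  unname(states[record_id])
}

#' Diagnostic-codon states for every sequence in an alignment
#' @inheritParams classify_at_codon
#' @return named character vector of states
#' @export
codon_states <- function(aln) {
  stopifnot(inherits(aln, "ace1_alignment"))
  if (is.null(aln$codon_column))
    stop("codon_column is not set on this alignment")
  base <- substr(aln$seq, aln$codon_column, aln$codon_column)
  state <- rep("undetermined", length(base))
  state[base == "G"] <- "susceptible"
  state[base == "A"] <- "resistant"
  state[base == "R"] <- "heterozygous"
  setNames(state, aln$id)
}

#' Translate the coding portion of a sequence (validation helper)
#'
#' Translates complete codons starting at `frame_offset + 1` using the
#' standard genetic code; codons containing ambiguity codes or gaps
#' translate to `X`.  Intended as a cross-check of codon coordinates, not as
#' the diagnostic classifier.
#'
#' @param aln an `ace1_alignment`
#' @return character vector of amino-acid strings, named by record id
#' @export
translate_frame <- function(aln) {
  stopifnot(inherits(aln, "ace1_alignment"))
  code <- Biostrings::GENETIC_CODE
  vapply(aln$seq, function(s) {
    s <- substr(s, aln$frame_offset + 1L, nchar(s))
    n_codon <- nchar(s) %/% 3L
    if (n_codon == 0) return("")
    codons <- substring(s, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
    aa <- ifelse(codons %in% names(code), code[codons], "X")
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE) |> setNames(aln$id)
}

#' Read a genotype-count table
#'
#' CSV with header `group,insecticide,n_SS,n_GS,n_GG`; one row per phenotype
#' group (`alive`, `dead`, `F0`) per insecticide.  SS is the homozygote
#' resistant (119S/119S) class, GS the heterozygote, GG the homozygote
#' susceptible.
#'
#' @param path CSV file
#' @return data.frame with the five columns, counts as integers
#' @export
read_genotype_counts <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "insecticide", "n_SS", "n_GS", "n_GG")
  if (!all(need %in% names(df)))
    stop(sprintf("parse error in '%s': expected columns %s",
                 path, paste(need, collapse = ", ")))
  for (cl in c("n_SS", "n_GS", "n_GG")) {
    v <- df[[cl]]
    if (any(is.na(v)) || any(v < 0) || any(v != round(v)))
      stop(sprintf("parse error in '%s': %s must be non-negative integers",
                   path, cl))
    df[[cl]] <- as.integer(v)
  }
  df[need]
}

#' Write a genotype-count table
#' @param df data.frame as returned by [read_genotype_counts()]
#' @param path output CSV
#' @return `path`, invisibly
#' @export
write_genotype_counts <- function(df, path) {
  need <- c("group", "insecticide", "n_SS", "n_GS", "n_GG")
  stopifnot(all(need %in% names(df)))
  write.csv(df[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bioassay mortality table
#'
#' CSV with header `insecticide,n_exposed,n_dead`; one row per replicate
#' tube.
#'
#' @param path CSV file
#' @return data.frame
#' @export
read_bioassay_counts <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("insecticide", "n_exposed", "n_dead")
  if (!all(need %in% names(df)))
    stop(sprintf("parse error in '%s': expected columns %s",
                 path, paste(need, collapse = ", ")))
  if (any(df$n_exposed <= 0) || any(df$n_dead < 0) ||
      any(df$n_dead > df$n_exposed))
    stop(sprintf("parse error in '%s': need 0 <= n_dead <= n_exposed, n_exposed > 0",
                 path))
  df[need]
}

#' Write a result table to CSV
#'
#' Thin wrapper used by all report emitters: plain CSV, header row, no row
#' names, no quoting surprises.
#'
#' @param df data.frame
#' @param path output CSV
#' @return `path`, invisibly
#' @export
write_report_csv <- function(df, path) {
  tryCatch(write.csv(df, path, row.names = FALSE),
           error = function(e)
             stop(sprintf("I/O error writing '%s': %s", path,
                          conditionMessage(e)), call. = FALSE))
  invisible(path)
}
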