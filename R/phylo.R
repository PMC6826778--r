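# Tamura 3-parameter distances and neighbor-joining trees: the desk-scale
# stand-in for a full maximum-likelihood search.  Sites with gaps or
# ambiguity codes are deleted pairwise; the GC content entering the model
# is computed per pair, not pooled over the alignment.

#' Tamura 3-parameter distance between two sequences
#'
#' `d = -c * ln(1 - P/c - Q) - (1/2)(1 - c) * ln(1 - 2Q)` with `P` the
#' transition proportion, `Q` the transversion proportion, and
#' `c = 2 * theta * (1 - theta)` where `theta` is the mean G+C content of
#' the pair over comparable sites.  With `theta = 0.5` this reduces exactly
#' to the Kimura 2-parameter distance.
#'
#' @param seq_x,seq_y equal-length nucleotide strings
#' @param labels length-2 labels used in error messages
#' @return the model distance (0 for identical sequences)
#' @export
tamura3_distance <- function(seq_x, seq_y, labels = c("x", "y")) {
  cx <- strsplit(toupper(seq_x), "", fixed = TRUE)[[1]]
  cy <- strsplit(toupper(seq_y), "", fixed = TRUE)[[1]]
  if (length(cx) != length(cy))
    stop("sequences must have equal length")
  comp <- is_unambiguous(cx) & is_unambiguous(cy)
  nc <- sum(comp)
  if (nc == 0) stop("no comparable sites between ",
                    labels[1], " and ", labels[2])
  x <- cx[comp]; y <- cy[comp]
  diff <- x != y
  transition <- diff & ((x %in% c("A", "G") & y %in% c("A", "G")) |
                          (x %in% c("C", "T") & y %in% c("C", "T")))
  P <- sum(transition) / nc
  Q <- sum(diff & !transition) / nc
  theta <- mean(c(x, y) %in% c("G", "C"))
  cc <- 2 * theta * (1 - theta)
  if (Q >= 0.5)
    stop(sprintf("saturation error between %s and %s: 1 - 2Q <= 0",
                 labels[1], labels[2]))
  term2 <- -0.5 * (1 - cc) * log(1 - 2 * Q)
  if (cc == 0) {
    if (P > 0)
      stop(sprintf("saturation error between %s and %s: transitions with c = 0",
                   labels[1], labels[2]))
    return(term2)
  }
  arg <- 1 - P / cc - Q
  if (arg <= 0)
    stop(sprintf("saturation error between %s and %s: log argument <= 0",
                 labels[1], labels[2]))
  -cc * log(arg) + term2
}

#' Tamura 3-parameter distance matrix
#'
#' @param x an `ace1_alignment`, `haplotype_set`, or named character vector
#'   of aligned sequences
#' @return symmetric numeric matrix with zero diagonal
#' @export
tamura3_matrix <- function(x) {
  if (inherits(x, "haplotype_set")) x <- setNames(x$seq, x$haplotype)
  seqs <- as_seq_vector(x)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- tamura3_distance(seqs[[i]], seqs[[j]],
                                           labels = names(seqs)[c(i, j)])
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via [ape::nj]); negative branch
#' lengths are clamped to zero with the deficit moved onto the sibling
#' branch, so leaf-to-leaf path lengths are approximately preserved and all
#' branch lengths are non-negative.
#'
#' @param dm symmetric distance matrix with labels (or `dist` object)
#' @return an unrooted `phylo` tree
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("argument error: need at least 3 labels")
  tr <- ape::nj(as.dist(dm))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]          # negative
    parent <- tr$edge[e, 1]
    sibs <- which(tr$edge[, 1] == parent & seq_len(nrow(tr$edge)) != e)
    tr$edge.length[e] <- 0
    if (length(sibs))
      tr$edge.length[sibs] <- pmax(0, tr$edge.length[sibs] +
                                     deficit / length(sibs))
  }
  tr
}

#' Write a tree in newick format
#' @param tree a `phylo` object
#' @param path output file (terminated by ";")
#' @return `path`, invisibly
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Best-bipartition purity of a tree against a labelling
#'
#' For every internal edge, the induced leaf split is scored by the
#' classification accuracy of its two sides (sum of per-side majority
#' counts over the number of leaves); the maximum over edges is returned.
#' A single-label input scores 1.
#'
#' @param tree a `phylo` object
#' @param labels named character vector (by tip label) of class labels
#' @return purity in `[0, 1]`
#' @export
cluster_purity <- function(tree, labels) {
  stopifnot(inherits(tree, "phylo"))
  labels <- labels[tree$tip.label]
  if (anyNA(labels)) stop("every tip needs a label")
  if (length(unique(labels)) <= 1) return(1)
  n <- length(tree$tip.label)
  maj <- function(lab) if (length(lab) == 0) 0 else max(table(lab))
  # leaf sets under each node via one postorder pass
  ntot <- n + tree$Nnode
  desc <- vector("list", ntot)
  for (i in seq_len(n)) desc[[i]] <- i
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  best <- 0
  for (e in seq_len(nrow(edge))) {
    tips <- desc[[edge[e, 2]]]
    if (length(tips) == 0 || length(tips) == n) next
    acc <- (maj(labels[tips]) + maj(labels[-tips])) / n
    best <- max(best, acc)
  }
  best
}
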