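# Statistical-parsimony haplotype networks in the spirit of the TCS
# program: haplotypes are joined by single-mutation edges, longer joins
# insert latent intermediate nodes, and joins beyond a probabilistically
# justified connection limit are refused.

#' Pairwise Hamming distance matrix
#'
#' Number of comparable sites (both bases unambiguous) at which each pair of
#' equal-length sequences differs.
#'
#' @param x an `ace1_alignment`, `haplotype_set`, or character vector of
#'   aligned sequences
#' @return symmetric integer matrix with zero diagonal, labelled by names
#' @export
hamming_matrix <- function(x) {
  if (inherits(x, "haplotype_set")) x <- setNames(x$seq, x$haplotype)
  seqs <- as_seq_vector(x)
  m <- seq_char_matrix(seqs)
  ok <- matrix(is_unambiguous(m), nrow = nrow(m))
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    comp <- ok[i, ] & ok[j, ]
    d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp])
  }
  d
}

#' Statistical-parsimony connection limit
#'
#' Largest number of mutational steps `j` for which the probability that
#' `j` observed differences between two sequences of length `L` arose
#' without any superimposed (homoplasious) change is at least `confidence`.
#'
#' The probability model is the pair coalescent with Jukes-Cantor
#' substitution: given coalescence time the per-site mutation count is
#' geometric, so the per-site probability of an observed difference is
#' `3p/(3+p)` (with `p` the geometric parameter), matched to the observed
#' divergence `q = j/L`; the probability that a differing site carries
#' exactly one mutation is then `(1-p)(3+p)/3`, and the parsimony
#' probability for `j` differences is that quantity to the power `j`.
#' Deterministic in `(L, confidence)` and non-decreasing in `L`.
#'
#' @param L alignment length in sites (> 0)
#' @param confidence required parsimony probability, in (0, 1); 0.95 is the
#'   conventional choice
#' @return integer connection limit (>= 1)
#' @export
parsimony_connection_limit <- function(L, confidence = 0.95) {
  stopifnot(L > 0)
  if (confidence <= 0 || confidence >= 1)
    stop("argument error: confidence must lie in (0, 1)")
  j <- 0L
  repeat {
    j_next <- j + 1L
    q <- j_next / L
    if (q >= 1) break
    p <- 3 * q / (3 - q)
    if (p >= 1) break
    p_single <- (1 - p) * (3 + p) / 3
    if (p_single^j_next < confidence) break
    j <- j_next
  }
  max(j, 1L)
}

#' Build a statistical-parsimony haplotype network
#'
#' Haplotype pairs are processed in non-decreasing Hamming distance order
#' (ties broken lexicographically by label).  A pair in different components
#' at distance `d <= limit` is joined; a `d`-step join inserts `d - 1`
#' latent intermediate nodes, resolving the differing sites in ascending
#' column order (an arbitrary but deterministic placement).  Joins beyond
#' the limit are refused, possibly leaving several components.  Pairs whose
#' components become connected by another equal-distance join in the same
#' distance class are recorded as `ambiguous_alternatives`, not drawn as
#' edges, so each component stays a tree.
#'
#' @param x haplotypes: a `haplotype_set` from [collapse_haplotypes()], or a
#'   named character vector of distinct aligned sequences
#' @param limit connection limit in mutational steps; default computed by
#'   [parsimony_connection_limit()] from the sequence length
#' @param confidence used for the default limit
#' @param frequencies observed counts per haplotype (taken from the
#'   `haplotype_set` when available; default 1)
#' @param codon_column optional diagnostic column; when given, nodes carry a
#'   resistance state
#' @return object of class `parsimony_network`: data.frames `nodes` (label,
#'   seq, frequency, latent, resistance, component) and `edges` (from, to),
#'   data.frame `ambiguous_alternatives`, and the `limit` used
#' @export
build_network <- function(x, limit = NULL, confidence = 0.95,
                          frequencies = NULL, codon_column = NULL) {
  if (inherits(x, "haplotype_set")) {
    if (is.null(frequencies)) frequencies <- x$frequency
    x <- setNames(x$seq, x$haplotype)
  }
  seqs <- as_seq_vector(x)
  if (anyDuplicated(unname(seqs)))
    stop("haplotypes must be distinct; collapse first")
  if (is.null(frequencies)) frequencies <- rep(1L, length(seqs))
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("haplotypes must have equal length")
  if (is.null(limit)) limit <- parsimony_connection_limit(L, confidence)

  labels <- names(seqs)
  node_seq <- unname(seqs)
  node_lab <- labels
  node_freq <- as.integer(frequencies)
  node_latent <- rep(FALSE, length(seqs))
  edges_from <- character(0); edges_to <- character(0)
  amb <- list()
  n_latent <- 0L

  # union-find over observed haplotypes (drives merge decisions)
  parent <- seq_along(labels)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  # union-find over all node labels (keeps each component a tree even when
  # a latent path runs through an already-placed node)
  uf <- new.env(parent = emptyenv())
  uf_find <- function(lab) {
    p <- get0(lab, envir = uf, ifnotfound = lab)
    if (identical(p, lab)) lab else {
      r <- uf_find(p); assign(lab, r, envir = uf); r
    }
  }

  d <- hamming_matrix(seqs)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[pairs], labels[pairs[, 1]], labels[pairs[, 2]],
               method = "radix")
  pairs <- pairs[ord, , drop = FALSE]
  dist_sorted <- d[pairs]

  add_node <- function(seq_str) {
    # reuse an existing node carrying the same sequence, else create latent
    hit <- match(seq_str, node_seq)
    if (!is.na(hit)) return(node_lab[hit])
    n_latent <<- n_latent + 1L
    lab <- paste0("int", n_latent)
    node_seq <<- c(node_seq, seq_str)
    node_lab <<- c(node_lab, lab)
    node_freq <<- c(node_freq, 0L)
    node_latent <<- c(node_latent, TRUE)
    lab
  }
  add_edge <- function(a, b) {
    ra <- uf_find(a); rb <- uf_find(b)
    if (identical(ra, rb)) return(invisible(FALSE))  # would close a cycle
    assign(ra, rb, envir = uf)
    edges_from <<- c(edges_from, a); edges_to <<- c(edges_to, b)
    invisible(TRUE)
  }

  for (dv in unique(dist_sorted)) {
    if (dv == 0 || dv > limit) next
    in_class <- which(dist_sorted == dv)
    snapshot <- vapply(seq_along(labels), find, integer(1))
    for (k in in_class) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      ri <- find(i); rj <- find(j)
      if (ri == rj) {
        if (snapshot[i] != snapshot[j])  # joined within this distance class
          amb[[length(amb) + 1L]] <-
            data.frame(from = labels[i], to = labels[j], steps = dv)
        next
      }
      parent[ri] <- rj
      # lay a path of single-mutation steps from i to j
      ci <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
      cj <- strsplit(seqs[[j]], "", fixed = TRUE)[[1]]
      diff_cols <- which(ci != cj & ci %in% DNA_BASES & cj %in% DNA_BASES)
      prev_lab <- labels[i]
      cur <- ci
      for (s in seq_along(diff_cols)) {
        cur[diff_cols[s]] <- cj[diff_cols[s]]
        nxt_lab <- if (s == length(diff_cols)) labels[j] else
          add_node(paste(cur, collapse = ""))
        if (nxt_lab != prev_lab) add_edge(prev_lab, nxt_lab)
        prev_lab <- nxt_lab
      }
    }
  }

  roots <- vapply(seq_along(labels), find, integer(1))
  comp_id <- match(roots, unique(roots))
  # latent nodes inherit the component of the observed node they attach to
  comp <- setNames(rep(NA_integer_, length(node_lab)), node_lab)
  comp[labels] <- comp_id
  changed <- TRUE
  while (changed && anyNA(comp)) {
    changed <- FALSE
    for (e in seq_along(edges_from)) {
      a <- edges_from[e]; b <- edges_to[e]
      if (is.na(comp[a]) && !is.na(comp[b])) { comp[a] <- comp[b]; changed <- TRUE }
      if (is.na(comp[b]) && !is.na(comp[a])) { comp[b] <- comp[a]; changed <- TRUE }
    }
  }

  resistance <- rep(NA_character_, length(node_lab))
  if (!is.null(codon_column)) {
    base <- substr(node_seq, codon_column, codon_column)
    resistance <- ifelse(base == "A", "resistant",
                         ifelse(base == "G", "susceptible", "undetermined"))
  }

  structure(list(
    nodes = data.frame(label = node_lab, seq = node_seq,
                       frequency = node_freq, latent = node_latent,
                       resistance = resistance,
                       component = unname(comp[node_lab]),
                       stringsAsFactors = FALSE),
    edges = data.frame(from = edges_from, to = edges_to,
                       stringsAsFactors = FALSE),
    ambiguous_alternatives = if (length(amb)) do.call(rbind, amb) else
      data.frame(from = character(0), to = character(0),
                 steps = integer(0)),
    limit = limit),
    class = "parsimony_network")
}

#' @export
print.parsimony_network <- function(x, ...) {
  cat(sprintf(
    "parsimony_network: %d observed + %d latent nodes, %d edges, %d component(s), limit %d\n",
    sum(!x$nodes$latent), sum(x$nodes$latent), nrow(x$edges),
    length(unique(stats::na.omit(x$nodes$component))), x$limit))
  if (nrow(x$ambiguous_alternatives))
    cat(sprintf("  %d ambiguous equal-cost alternative connection(s)\n",
                nrow(x$ambiguous_alternatives)))
  invisible(x)
}

#' Group-sharing summary over haplotypes
#'
#' Classifies each haplotype of a [collapse_haplotypes()] result by the set
#' of phenotype groups it occurs in, and counts group-specific versus
#' shared haplotypes.  Counts are conserved: group-specific plus shared
#' equals the total haplotype number.
#'
#' @param haps a `haplotype_set` built with group information
#' @return list with data.frame `table` (haplotype, groups_present, shared)
#'   and named vector `counts` (per group-combination totals)
#' @export
shared_haplotype_table <- function(haps) {
  stopifnot(inherits(haps, "haplotype_set"))
  glev <- attr(haps, "group_levels")
  if (is.null(glev))
    stop("haplotype set was built without group information")
  present <- vapply(seq_len(nrow(haps)), function(i) {
    g <- glev[vapply(glev, function(g) haps[[g]][i] > 0, logical(1))]
    paste(g, collapse = "+")
  }, character(1))
  tab <- data.frame(haplotype = haps$haplotype,
                    groups_present = present,
                    shared = grepl("+", present, fixed = TRUE),
                    stringsAsFactors = FALSE)
  list(table = tab, counts = c(table(present)))
}

#' Best two-block purity of a parsimony network
#'
#' How well the network separates resistant from susceptible haplotypes:
#' over candidate bipartitions of the observed nodes (every single-edge cut
#' of a component, and every whole component against the rest), the maximal
#' classification accuracy `(majority(side1) + majority(side2)) / n`.
#' Latent nodes carry no label and are ignored.
#'
#' @param net a `parsimony_network`
#' @param labels named character vector (by node label) of class labels,
#'   e.g. resistance states; defaults to the network's `resistance` column
#' @return purity in `[0, 1]`
#' @export
network_cluster_purity <- function(net, labels = NULL) {
  stopifnot(inherits(net, "parsimony_network"))
  obs <- net$nodes[!net$nodes$latent, ]
  if (is.null(labels))
    labels <- setNames(obs$resistance, obs$label)
  labels <- labels[obs$label]
  if (anyNA(labels)) stop("every observed node needs a label")
  n <- nrow(obs)
  if (length(unique(labels)) <= 1) return(1)
  maj <- function(lab) if (length(lab) == 0) 0 else max(table(lab))
  # adjacency over all nodes
  adj <- split(c(net$edges$to, net$edges$from),
               c(net$edges$from, net$edges$to))
  side_of_cut <- function(drop_a, drop_b) {
    # nodes reachable from drop_b without crossing edge (drop_a, drop_b)
    seen <- drop_b; queue <- drop_b
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in adj[[cur]] %||% character(0)) {
        if (nb == drop_a && cur == drop_b) next
        if (!nb %in% seen) { seen <- c(seen, nb); queue <- c(queue, nb) }
      }
    }
    seen
  }
  best <- 0
  comps <- unique(obs$component)
  if (length(comps) > 1) {
    for (cp in comps) {
      s1 <- obs$label[obs$component == cp]
      acc <- (maj(labels[s1]) + maj(labels[setdiff(obs$label, s1)])) / n
      best <- max(best, acc)
    }
  }
  for (e in seq_len(nrow(net$edges))) {
    # both orientations: with several components the complement side also
    # absorbs the other components, so the two splits differ
    for (side in list(c(net$edges$from[e], net$edges$to[e]),
                      c(net$edges$to[e], net$edges$from[e]))) {
      s_all <- side_of_cut(side[1], side[2])
      s1 <- intersect(s_all, obs$label)
      acc <- (maj(labels[s1]) + maj(labels[setdiff(obs$label, s1)])) / n
      best <- max(best, acc)
    }
  }
  best
}

#' Write a network as Graphviz DOT
#'
#' Observed nodes are sized by frequency and coloured by resistance state;
#' latent intermediates are drawn as points.
#'
#' @param net a `parsimony_network`
#' @param path output `.dot` file
#' @return `path`, invisibly
#' @export
write_dot <- function(net, path) {
  stopifnot(inherits(net, "parsimony_network"))
  col <- c(resistant = "firebrick", susceptible = "steelblue",
           undetermined = "grey70")
  lines <- c("graph haplotype_network {",
             "  node [style=filled, fillcolor=white];")
  for (i in seq_len(nrow(net$nodes))) {
    nd <- net$nodes[i, ]
    attrs <- if (nd$latent)
      "shape=point, width=0.08, label=\"\"" else
      sprintf("shape=circle, width=%.2f, label=\"%s (%d)\"%s",
              0.3 + 0.15 * sqrt(nd$frequency), nd$label, nd$frequency,
              if (!is.na(nd$resistance))
                sprintf(", fillcolor=%s", col[[nd$resistance]]) else "")
    lines <- c(lines, sprintf("  \"%s\" [%s];", nd$label, attrs))
  }
  for (e in seq_len(nrow(net$edges)))
    lines <- c(lines, sprintf("  \"%s\" -- \"%s\";",
                              net$edges$from[e], net$edges$to[e]))
  lines <- c(lines, "}")
  tryCatch(writeLines(lines, path),
           error = function(e)
             stop(sprintf("I/O error writing '%s': %s", path,
                          conditionMessage(e)), call. = FALSE))
  invisible(path)
}
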