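# Alignment-level diagnostics. Alignments are plain uppercase character
# matrices (rows = taxa); IUPAC ambiguity codes and gaps are treated as
# missing for distances and base counts.

#' Coerce to an alignment matrix
#'
#' Accepts a character matrix, an `ape` `DNAbin`, a `phangorn` `phyDat`, or
#' a named character vector of equal-length sequence strings. Returns an
#' uppercase character matrix with taxa as rownames.
#'
#' @param x Object to coerce.
#' @export
as_alignment <- function(x) {
  if (inherits(x, "phyDat")) x <- as.character(x)
  if (inherits(x, "DNAbin")) x <- as.character(as.matrix(x))
  if (is.character(x) && is.null(dim(x))) {
    if (length(unique(nchar(x))) != 1L)
      stop("sequences differ in length")
    labels <- names(x)
    x <- do.call(rbind, strsplit(x, "", fixed = TRUE))
    rownames(x) <- labels
  }
  if (!is.matrix(x)) stop("cannot coerce to alignment")
  x <- toupper(x)
  if (is.null(rownames(x)))
    rownames(x) <- paste0("seq", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x))) stop("duplicate taxon labels")
  x
}

#' Read a FASTA alignment
#' @param file Path to a FASTA file of aligned sequences.
#' @return Character matrix alignment.
#' @export
read_fasta_alignment <- function(file) {
  as_alignment(ape::read.FASTA(file))
}

valid_base <- function(aln) {
  aln == "A" | aln == "C" | aln == "G" | aln == "T"
}

#' Parse a site mask from `start-end` lines
#'
#' One 1-based inclusive column range per line (e.g. `"90-102"`), matching
#' the conventional notation for excluded alignment positions.
#'
#' @param x Character vector of range lines, or a path to a file of them.
#' @return Two-column integer matrix (`start`, `end`).
#' @export
parse_site_mask <- function(x) {
  if (length(x) == 1L && file.exists(x)) x <- readLines(x)
  x <- trimws(x)
  x <- x[nzchar(x)]
  parts <- strsplit(x, "\\s*[-–]\\s*")
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("unparseable mask range(s): ",
                     paste(x[bad], collapse = ", "))
  m <- do.call(rbind, lapply(parts, as.integer))
  colnames(m) <- c("start", "end")
  if (any(is.na(m)) || any(m[, 1L] > m[, 2L]))
    stop("invalid mask range bounds")
  m
}

#' Remove masked columns from an alignment
#'
#' Ranges are 1-based inclusive and may overlap; the union of columns is
#' removed from every sequence.
#'
#' @param aln Alignment (anything [as_alignment()] accepts).
#' @param mask Two-column matrix of ranges, or input for
#'   [parse_site_mask()].
#' @return List with `alignment` (masked) and `removed` (column count).
#' @export
apply_site_mask <- function(aln, mask) {
  aln <- as_alignment(aln)
  if (!is.matrix(mask) || is.character(mask)) mask <- parse_site_mask(mask)
  if (any(mask < 1L) || any(mask > ncol(aln)))
    stop("mask range outside alignment columns 1-", ncol(aln))
  cols <- sort(unique(unlist(Map(seq.int, mask[, 1L], mask[, 2L]))))
  out <- if (length(cols)) aln[, -cols, drop = FALSE] else aln
  list(alignment = out, removed = length(cols))
}

#' Uncorrected-p distances
#'
#' Proportion of differing sites over sites where both sequences have an
#' unambiguous A/C/G/T (`pairwise` deletion), or over the global
#' intersection of unambiguous columns (`complete` deletion). Pairs with no
#' effective sites get `NA` distances and are flagged, never 0.
#'
#' @param aln Alignment.
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return List with symmetric `distance` matrix, `effective_sites` count
#'   matrix, and `undefined_pairs` (data frame of flagged pairs).
#' @export
pdistance <- function(aln, deletion = c("pairwise", "complete")) {
  aln <- as_alignment(aln)
  deletion <- match.arg(deletion)
  if (nrow(aln) < 2L) stop("need at least 2 sequences")
  ok <- valid_base(aln)
  if (deletion == "complete") {
    keep <- colSums(!ok) == 0L
    aln <- aln[, keep, drop = FALSE]
    ok <- ok[, keep, drop = FALSE]
  }
  n <- nrow(aln)
  D <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  Eff <- matrix(ncol(aln), n, n, dimnames = dimnames(D))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    both <- ok[i, ] & ok[j, ]
    eff <- sum(both)
    Eff[i, j] <- Eff[j, i] <- eff
    D[i, j] <- D[j, i] <- if (eff > 0)
      sum(aln[i, both] != aln[j, both]) / eff else NA_real_
  }
  und <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
  undefined <- data.frame(taxon1 = rownames(aln)[und[, 1L]],
                          taxon2 = rownames(aln)[und[, 2L]],
                          stringsAsFactors = FALSE)
  list(distance = D, effective_sites = Eff, undefined_pairs = undefined,
       deletion = deletion)
}

#' Mean pairwise distances within and between groups
#'
#' @param dm Result of [pdistance()] (or a symmetric distance matrix).
#' @param groups Named character vector mapping every taxon to a group.
#' @return Symmetric matrix of group mean distances; within-group means on
#'   the diagonal (`NA` for singleton groups).
#' @export
group_mean_distance <- function(dm, groups) {
  D <- if (is.list(dm)) dm$distance else dm
  taxa <- rownames(D)
  miss <- setdiff(taxa, names(groups))
  if (length(miss))
    stop("ungrouped taxa: ", paste(miss, collapse = ", "))
  gs <- sort(unique(groups[taxa]))
  M <- matrix(NA_real_, length(gs), length(gs), dimnames = list(gs, gs))
  for (a in seq_along(gs)) for (b in a:length(gs)) {
    ia <- taxa[groups[taxa] == gs[a]]
    ib <- taxa[groups[taxa] == gs[b]]
    vals <- if (a == b) {
      if (length(ia) < 2L) NA_real_ else D[ia, ia][upper.tri(D[ia, ia])]
    } else as.vector(D[ia, ib, drop = FALSE])
    M[a, b] <- M[b, a] <- mean(vals, na.rm = TRUE)
  }
  M
}

#' Pairwise saturation table
#'
#' For every sequence pair: overall percent divergence, raw substitution
#' count at mutually unambiguous sites, and the substitution count at third
#' codon positions. Intended for plotting divergence against substitutions
#' to assess saturation visually; no asymptote test is performed.
#'
#' @param aln Alignment.
#' @param codon_pos Integer vector (1/2/3 per column) annotating codon
#'   positions; required unless `third_position = FALSE`.
#' @param third_position Include the third-position column (default
#'   `TRUE`).
#' @return Data frame with one row per pair.
#' @export
saturation_table <- function(aln, codon_pos = NULL, third_position = TRUE) {
  aln <- as_alignment(aln)
  if (third_position) {
    if (is.null(codon_pos)) codon_pos <- attr(aln, "codon_pos")
    if (is.null(codon_pos))
      stop("codon position annotation required for third-position counts")
    if (length(codon_pos) != ncol(aln))
      stop("codon_pos length must match alignment columns")
  }
  ok <- valid_base(aln)
  n <- nrow(aln)
  rows <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    both <- ok[i, ] & ok[j, ]
    diffs <- aln[i, ] != aln[j, ] & both
    eff <- sum(both)
    rows[[length(rows) + 1L]] <- data.frame(
      taxon1 = rownames(aln)[i], taxon2 = rownames(aln)[j],
      percent_divergence = if (eff > 0) 100 * sum(diffs) / eff else NA_real_,
      substitutions = sum(diffs),
      third_pos_substitutions = if (third_position)
        sum(diffs & codon_pos == 3L) else NA_integer_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Base-composition heterogeneity test
#'
#' Per-taxon A/C/G/T counts over unambiguous sites are tested against the
#' pooled composition with a contingency chi-square
#' (df = (taxa - 1) x 3). Taxa with no unambiguous sites are dropped with a
#' warning.
#'
#' @param aln Alignment.
#' @return List with per-taxon `frequencies`, `mean_frequencies`,
#'   `statistic`, `df`, `p_value`.
#' @export
base_composition_test <- function(aln) {
  aln <- as_alignment(aln)
  if (nrow(aln) < 2L) stop("need at least 2 sequences")
  bases <- c("A", "C", "G", "T")
  counts <- t(apply(aln, 1L, function(s)
    vapply(bases, function(b) sum(s == b), 0L)))
  empty <- rowSums(counts) == 0L
  if (any(empty)) {
    warning("excluding taxa with no unambiguous sites: ",
            paste(rownames(aln)[empty], collapse = ", "))
    counts <- counts[!empty, , drop = FALSE]
  }
  freqs <- counts / rowSums(counts)
  use <- counts[, colSums(counts) > 0, drop = FALSE]
  if (all(use == use[rep(1L, nrow(use)), , drop = FALSE]) || ncol(use) < 2L) {
    stat <- 0
  } else {
    stat <- unname(suppressWarnings(
      chisq.test(use, correct = FALSE)$statistic))
  }
  df <- (nrow(counts) - 1L) * 3L
  p <- pchisq(stat, df, lower.tail = FALSE)
  list(frequencies = freqs, mean_frequencies = colMeans(freqs),
       statistic = stat, df = df, p_value = p)
}

#' Count parsimony-informative sites
#'
#' A column is informative when at least two bases each occur in at least
#' two sequences; gaps and ambiguity codes are ignored.
#'
#' @param aln Alignment.
#' @return Integer count.
#' @export
count_informative_sites <- function(aln) {
  aln <- as_alignment(aln)
  ok <- valid_base(aln)
  sum(vapply(seq_len(ncol(aln)), function(k) {
    tab <- table(aln[ok[, k], k])
    sum(tab >= 2L) >= 2L
  }, TRUE))
}

#' Parsimony tree-length skewness (g1) test of phylogenetic signal
#'
#' Samples random labelled bifurcating topologies uniformly (random
#' sequential addition), computes the Fitch parsimony length of each, and
#' reports the moment skewness `g1 = m3 / m2^1.5` of the length
#' distribution. Strongly negative g1 indicates phylogenetic structure.
#' Because published critical-value tables are not reproduced here, an
#' optional column-shuffle null gives an empirical percentile: each
#' replicate permutes every column across taxa (destroying covariation)
#' and recomputes g1.
#'
#' @param aln Alignment (>= 4 taxa).
#' @param n_trees Number of random topologies (default 10000).
#' @param seed Optional integer seed.
#' @param null_replicates Column-shuffle null replicates (default 0 =
#'   skip).
#' @return List of class `g1_result` with `g1`, `n_trees`, `tree_lengths`
#'   summary, and when requested `null_g1` and `null_percentile` (fraction
#'   of null g1 values at or below the observed).
#' @export
g1_statistic <- function(aln, n_trees = 10000, seed = NULL,
                         null_replicates = 0) {
  aln <- as_alignment(aln)
  if (nrow(aln) < 4L) stop("need at least 4 taxa")
  if (!is.null(seed)) set.seed(seed)
  dat <- phangorn::phyDat(aln, type = "DNA")
  lens <- random_tree_lengths(dat, rownames(aln), n_trees)
  g1 <- moment_skewness(lens)
  res <- list(g1 = g1, n_trees = n_trees,
              tree_lengths = summary(lens), seed = seed)
  if (null_replicates > 0) {
    null_g1 <- vapply(seq_len(null_replicates), function(i) {
      shuf <- apply(aln, 2L, sample)
      rownames(shuf) <- rownames(aln)
      moment_skewness(random_tree_lengths(
        phangorn::phyDat(shuf, type = "DNA"), rownames(aln), n_trees))
    }, 0)
    res$null_g1 <- null_g1
    res$null_percentile <- mean(null_g1 <= g1)
  }
  class(res) <- "g1_result"
  res
}

random_tree_lengths <- function(dat, labels, n_trees) {
  vapply(seq_len(n_trees), function(i) {
    tr <- ape::rtopology(length(labels), rooted = FALSE,
                         tip.label = sample(labels))
    phangorn::parsimony(tr, dat, method = "fitch")
  }, 0)
}

moment_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

#' Fitch parsimony length of a tree
#'
#' @param phy A `phylo` tree whose tips match the alignment taxa.
#' @param aln Alignment.
#' @return Integer parsimony length.
#' @export
fitch_length <- function(phy, aln) {
  aln <- as_alignment(aln)
  phangorn::parsimony(phy, phangorn::phyDat(aln, type = "DNA"),
                      method = "fitch")
}
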