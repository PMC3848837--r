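#' Parse a Newick string into a time tree
#'
#' Thin, validating wrapper around [ape::read.tree()]. The returned object is
#' an `ape` `phylo` tree; node ages in Ma before present are recovered with
#' [node_ages()], taking the deepest tip as the present (age 0).
#'
#' @param text A single Newick string with branch lengths in Ma.
#' @return A `phylo` object.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0) || depth[length(depth)] != 0L)
    stop("unbalanced parentheses in Newick string near position ",
         if (any(depth < 0)) which(depth < 0)[1L] else length(chars))
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("Newick parse error: ",
                                           conditionMessage(e)))
  if (is.null(phy)) stop("Newick parse error: no tree found")
  if (is.null(phy$edge.length) ||
      length(phy$edge.length) != nrow(phy$edge) ||
      anyNA(phy$edge.length))
    stop("missing branch lengths in Newick string")
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup))
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  phy
}

#' Write a tree as Newick
#'
#' Branch lengths are always written, with 9 significant digits.
#'
#' @param phy A `phylo` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @export
write_newick <- function(phy, file = NULL) {
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  txt <- ape::write.tree(phy, digits = 9)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Node ages in Ma before present
#'
#' Ages are cumulative root-to-node path lengths rebased so that the deepest
#' tip sits at age 0 (the present). For an ultrametric tree all tips have
#' age 0.
#'
#' @param phy A `phylo` object with branch lengths.
#' @return Numeric vector of length `Ntip + Nnode`, indexed like `phy$edge`.
#' @export
node_ages <- function(phy) {
  depths <- ape::node.depth.edgelength(phy)
  ntip <- ape::Ntip(phy)
  max(depths[seq_len(ntip)]) - depths
}

#' Check that a time tree is ultrametric
#'
#' Reports the maximum tip-age deviation from 0 and whether it passes the
#' tolerance. The default tolerance scales with tree depth
#' (`1e-6 * root age`).
#'
#' @param phy A `phylo` object.
#' @param tol Absolute tolerance in Ma.
#' @return A list with `ultrametric` (logical), `max_deviation`, and `tol`.
#' @export
check_ultrametric <- function(phy, tol = NULL) {
  ages <- node_ages(phy)
  ntip <- ape::Ntip(phy)
  root_age <- ages[ntip + 1L]
  if (is.null(tol)) tol <- 1e-6 * max(root_age, .Machine$double.eps)
  dev <- max(abs(ages[seq_len(ntip)]))
  list(ultrametric = dev <= tol, max_deviation = dev, tol = tol)
}

#' Prune a time tree to a set of tips
#'
#' Returns the induced subtree on `keep`: unary nodes are suppressed with
#' branch lengths summed, so retained nodes keep their original ages and all
#' patristic distances among retained tips are preserved.
#'
#' @param phy A `phylo` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @export
prune_to_taxa <- function(phy, keep) {
  unknown <- setdiff(keep, phy$tip.label)
  if (length(unknown))
    stop("unknown tip labels: ", paste(unknown, collapse = ", "))
  if (length(keep) < 2L) stop("need at least 2 tips to keep")
  ape::keep.tip(phy, keep)
}

#' Stem and crown ages of a clade
#'
#' The crown age is the age of the clade's most recent common ancestor; the
#' stem age is the age of that node's parent. The stem age of the root clade
#' is reported as `NA`.
#'
#' @param phy A `phylo` object.
#' @param clade Character vector of tip labels; must be monophyletic.
#' @return A list with `stem_age` and `crown_age` in Ma.
#' @export
clade_ages <- function(phy, clade) {
  unknown <- setdiff(clade, phy$tip.label)
  if (length(unknown))
    stop("unknown tip labels: ", paste(unknown, collapse = ", "))
  ages <- node_ages(phy)
  ntip <- ape::Ntip(phy)
  if (length(clade) == 1L) {
    node <- match(clade, phy$tip.label)
  } else {
    node <- ape::getMRCA(phy, clade)
    desc <- ape::extract.clade(phy, node)$tip.label
    intruders <- setdiff(desc, clade)
    if (length(intruders))
      stop("clade is not monophyletic; intruding tips: ",
           paste(intruders, collapse = ", "))
  }
  crown <- if (length(clade) == 1L) ages[node] else ages[node]
  root <- ntip + 1L
  stem <- if (node == root) NA_real_ else {
    parent <- phy$edge[phy$edge[, 2L] == node, 1L]
    ages[parent]
  }
  list(stem_age = stem, crown_age = crown)
}

#' Read a tip keep-list (one label per line)
#' @param file Path to a plain-text file.
#' @export
read_keep_list <- function(file) {
  x <- trimws(readLines(file))
  x[nzchar(x)]
}
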