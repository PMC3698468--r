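#' Read a rooted phylogeny from a Newick string or file
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned tree is an
#' `ape` `"phylo"` object, the container used throughout the package. Trees
#' must have branch lengths on every edge (divergence times on an arbitrary
#' scale), unique tip labels, and at least two tips. Polytomies are allowed
#' and zero-length branches are permitted.
#'
#' @param text a Newick string (mutually exclusive with `file`).
#' @param file path to a file containing a single Newick tree.
#' @return an object of class `"phylo"`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  tr <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                 error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("Newick parse error: could not parse tree text")
  validate_phylogeny(tr)
  tr
}

validate_phylogeny <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a 'phylo' object")
  if (length(tr$tip.label) < 2L) stop("tree must have at least 2 tips")
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup))
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "))
  if (is.null(tr$edge.length))
    stop("tree has no branch lengths; they are required")
  if (anyNA(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge))
    stop("missing branch length on one or more edges")
  if (any(tr$edge.length < 0))
    stop("negative branch length(s) found")
  invisible(tr)
}

#' Test whether a tree is ultrametric
#'
#' All root-to-tip distances equal within a relative tolerance on the
#' max/min depth ratio.
#'
#' @param tree a `"phylo"` object.
#' @param tol relative tolerance (default `1e-6`).
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  d <- tip_depths(tree)
  if (any(d <= 0)) return(FALSE)
  (max(d) / min(d) - 1) <= tol
}

# root-to-tip path lengths, in tip.label order; a root edge (stem retained
# by pruning) counts as shared history below the original root
tip_depths <- function(tree) {
  nd <- ape::node.depth.edgelength(tree)
  nd[seq_along(tree$tip.label)] +
    if (is.null(tree$root.edge)) 0 else tree$root.edge
}

#' Prune a phylogeny to a set of tips
#'
#' Keeps the induced subtree on `keep`, collapsing degree-2 internal nodes
#' (their branch lengths are summed), so root-to-tip distances among the kept
#' tips are preserved: if the kept tips' most recent common ancestor lies
#' below the original root, the intervening path is retained as the pruned
#' tree's root edge (it is shared history of every kept tip).
#'
#' @param tree a `"phylo"` object.
#' @param keep character vector of tip labels to retain (at least 2).
#' @return the pruned `"phylo"` object.
#' @export
prune_phylogeny <- function(tree, keep) {
  validate_phylogeny(tree)
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop(paste(unknown, collapse = ", "), " not a tip")
  if (length(keep) < 2L) stop("need at least 2 tips to keep")
  pr <- ape::keep.tip(tree, keep)
  # ape drops the stem above the kept MRCA; restore it so depths are preserved
  d_old <- tip_depths(tree)[match(keep[1], tree$tip.label)]
  d_new <- tip_depths(pr)[match(keep[1], pr$tip.label)]
  stem <- d_old - d_new
  if (stem > 1e-12)
    pr$root.edge <- (if (is.null(pr$root.edge)) 0 else pr$root.edge) + stem
  pr
}

#' Brownian-motion correlation matrix of a phylogeny
#'
#' Under Brownian trait evolution the covariance between two tips is the
#' shared root-to-MRCA path length; standardizing to unit diagonal gives the
#' correlation matrix \eqn{C} with \eqn{c_{ij} = cov_{ij} / \sqrt{cov_{ii}
#' cov_{jj}}}. For an ultrametric tree this is MRCA depth over tree depth.
#' The matrix is symmetric positive semi-definite with entries in `[0, 1]`
#' and is invariant to rescaling all branch lengths by a positive constant.
#'
#' Non-ultrametric trees are accepted — the correlation standardization keeps
#' the diagonal at 1 either way — but a warning is emitted because the
#' `[0, 1]` range guarantee of downstream evenness indices is stated for the
#' ultrametric/star standardization.
#'
#' @param tree a `"phylo"` object with at least 2 tips.
#' @return a symmetric numeric matrix with tip labels as dimnames.
#' @examples
#' brownian_correlation(read_newick("((A:1,B:1):1,C:2);"))
#' @export
brownian_correlation <- function(tree) {
  validate_phylogeny(tree)
  d <- tip_depths(tree)
  if (any(d <= 0))
    stop("degenerate tree: tip(s) at zero distance from the root: ",
         paste(tree$tip.label[d <= 0], collapse = ", "))
  if (!is_ultrametric(tree))
    warning("tree is not ultrametric; correlation standardization applied to a non-constant diagonal")
  V <- ape::vcv(tree)
  if (!is.null(tree$root.edge) && tree$root.edge > 0)
    V <- V + tree$root.edge          # stem time is shared by every pair
  C <- stats::cov2cor(V)
  # clean tiny negative rounding noise
  C[C < 0 & C > -1e-12] <- 0
  C
}

#' Write a labeled correlation matrix as TSV
#' @param C square matrix with dimnames.
#' @param file output path.
#' @export
write_correlation_tsv <- function(C, file) {
  df <- data.frame(species = rownames(C), C, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
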