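#' Phylogenetic Species Variability (PSV)
#'
#' The expected variance of a neutral trait evolving by Brownian motion over
#' the community phylogeny, standardized by its expectation on a star
#' phylogeny. With a unit-diagonal correlation matrix `C` for the `n`
#' community members,
#' \deqn{PSV = \frac{n\,\mathrm{tr}(C) - \sum_{ij} c_{ij}}{n(n-1)}
#'       = 1 - \bar{c}_{off},}
#' one minus the mean off-diagonal correlation. PSV is 1 on a star phylogeny
#' and 0 when all species are phylogenetically identical.
#'
#' @param C correlation (or covariance) submatrix for the species present;
#'   at least 2 x 2.
#' @return a single numeric value.
#' @export
psv <- function(C) {
  C <- as.matrix(C)
  n <- nrow(C)
  if (n < 2L) stop("PSV undefined for fewer than 2 species")
  (n * sum(diag(C)) - sum(C)) / (n * (n - 1))
}

#' Phylogenetic Species Evenness (PSE)
#'
#' Abundance-weighted phylogenetic diversity: conceptually, each species is
#' expanded into `m_i` individuals joined by zero-length branches and the
#' Brownian trait variance is computed over individuals, standardized so that
#' the maximum of 1 is reached only on a star phylogeny with even abundances.
#' With total abundance \eqn{N = \sum m_i} and mean abundance per present
#' species \eqn{\bar m = N/n},
#' \deqn{PSE = \frac{N \sum_i m_i c_{ii} - m' C m}{N^2 - N \bar m}.}
#' PSE reduces exactly to [psv()] when all present abundances are equal, and
#' lies in `[0, 1]` for ultrametric (correlation-standardized) trees.
#'
#' Species with abundance 0 are dropped before the computation: the index is
#' a property of the realized community.
#'
#' @param C full correlation matrix with species dimnames (or already the
#'   submatrix matching `m` if unnamed).
#' @param m non-negative integer abundance vector, named by species when `C`
#'   is named.
#' @return a single numeric value.
#' @examples
#' C <- brownian_correlation(read_newick("((A:1,B:1):1,C:2);"))
#' pse(C, c(A = 3, B = 1, C = 2))
#' @export
pse <- function(C, m) {
  C <- as.matrix(C)
  if (!is.null(names(m)) && !is.null(rownames(C))) {
    missing_sp <- setdiff(names(m), rownames(C))
    if (length(missing_sp))
      stop("species not in correlation matrix: ", paste(missing_sp, collapse = ", "))
    m <- m[rownames(C)[rownames(C) %in% names(m)]]
    C <- C[names(m), names(m), drop = FALSE]
  }
  if (length(m) != nrow(C)) stop("abundance vector does not match matrix dimension")
  if (any(m < 0) || any(m != round(m))) stop("abundances must be non-negative integers")
  pres <- m > 0
  if (sum(pres) < 2L) stop("PSE undefined: fewer than 2 species present")
  m <- as.numeric(m[pres])
  C <- C[pres, pres, drop = FALSE]
  N <- sum(m)
  mbar <- mean(m)
  denom <- N^2 - N * mbar
  if (denom <= 0) stop("degenerate abundances: non-positive denominator")
  as.numeric((N * sum(m * diag(C)) - drop(crossprod(m, C %*% m))) / denom)
}

#' Per-plot phylogenetic diversity table
#'
#' Computes SR (number of species present), PSV, PSE, and total abundance for
#' every plot of a long-format composition table, against one shared
#' Brownian correlation matrix derived from `tree` (pruned to the surveyed
#' species). Plots with fewer than 2 species present get `NA` diversity
#' values with a warning; they cannot enter the damage model.
#'
#' @param tree a `"phylo"` object containing every species in `composition`.
#' @param composition data frame with columns `plot`, `species`, `abundance`
#'   (the 0-4 quadrat coding; rows with abundance 0 are ignored).
#' @return data frame with columns `plot`, `SR`, `PSV`, `PSE`, `N`.
#' @export
plot_diversity <- function(tree, composition) {
  composition <- validate_composition(composition)
  sp <- sort(unique(composition$species[composition$abundance > 0]))
  unknown <- setdiff(sp, tree$tip.label)
  if (length(unknown))
    stop("species missing from tree: ", paste(unknown, collapse = ", "))
  sub <- if (length(sp) < length(tree$tip.label) && length(sp) >= 2)
    prune_phylogeny(tree, sp) else tree
  C <- brownian_correlation(sub)
  plots <- unique(composition$plot)
  res <- lapply(plots, function(pl) {
    rows <- composition[composition$plot == pl & composition$abundance > 0, ]
    m <- setNames(rows$abundance, rows$species)
    n_pres <- length(m)
    if (n_pres < 2L) {
      warning("plot '", pl, "' has fewer than 2 species present; diversity set to NA")
      return(data.frame(plot = pl, SR = n_pres, PSV = NA_real_, PSE = NA_real_,
                        N = sum(m)))
    }
    Csub <- C[names(m), names(m)]
    data.frame(plot = pl, SR = n_pres, PSV = psv(Csub), PSE = pse(Csub, m),
               N = sum(m))
  })
  do.call(rbind, res)
}

#' Write the per-plot diversity table as TSV
#' @param div output of [plot_diversity()].
#' @param file output path.
#' @export
write_diversity_tsv <- function(div, file) {
  write.table(div, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
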