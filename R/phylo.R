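.taxonomy_ranks <- c("phylum", "class", "order", "family", "genus",
                     "species_name")

#' Phylogenetic correlation from a ranked taxonomy
#'
#' Builds the correlation implied by the taxonomic tree with one node per
#' distinct rank value and unit branch lengths on every edge (the surrogate
#' used when a true phylogeny is unavailable): every tip sits six edges below
#' the root, and the correlation between two species is the fraction of the
#' root-to-tip path they share, `C_jk = shared edges / 6`. Nested rank values
#' are distinguished by their full lineage, so a genus name reused in two
#' families would not be conflated.
#'
#' @param taxonomy `data.frame` with columns `species` plus the six ranks
#'   `phylum, class, order, family, genus, species_name` (coarse to fine).
#' @return species x species correlation matrix (unit diagonal, entries in
#'   `[0, 1]`, positive semi-definite).
#' @export
taxonomy_to_correlation <- function(taxonomy) {
  need <- c("species", .taxonomy_ranks)
  missing <- setdiff(need, names(taxonomy))
  if (length(missing))
    stop("taxonomy is missing columns: ", paste(missing, collapse = ", "))
  if (anyNA(taxonomy[need]) || any(taxonomy[need] == ""))
    stop("taxonomy contains missing ranks")
  if (anyDuplicated(taxonomy$species))
    stop("duplicate species identifiers in taxonomy")
  n <- nrow(taxonomy)
  # lineage path at each depth: phylum, phylum/class, ..., down to species
  paths <- Reduce(function(a, b) paste(a, b, sep = "/"),
                  lapply(.taxonomy_ranks, function(r) as.character(taxonomy[[r]])),
                  accumulate = TRUE)
  paths <- do.call(cbind, paths)              # n x 6
  if (anyDuplicated(paths[, 6]))
    stop("species with identical full taxonomy but different identifiers: ",
         "zero-length distinction is not representable")
  depth <- length(.taxonomy_ranks)
  C <- diag(1, n)
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    shared <- sum(cumprod(paths[j, ] == paths[k, ]))
    C[j, k] <- C[k, j] <- shared / depth
  }
  dimnames(C) <- list(taxonomy$species, taxonomy$species)
  C
}

#' Phylogenetic correlation from a tree
#'
#' Converts a phylogeny (an `ape` `phylo` object or a Newick file/string)
#' into the species correlation used in the niche prior: the shared
#' branch-length covariance, normalized to unit diagonal.
#'
#' @param tree an `ape::phylo` object, or a path to / string of Newick.
#' @param species optional character vector giving the species order wanted.
#' @return correlation matrix with unit diagonal.
#' @export
phylo_correlation <- function(tree, species = NULL) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree) else ape::read.tree(text = tree)
    if (is.null(tree)) stop("could not parse Newick tree")
  }
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object or Newick")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  V <- ape::vcv(tree)
  C <- stats::cov2cor(V)
  if (!is.null(species)) {
    missing <- setdiff(species, rownames(C))
    if (length(missing))
      stop("species absent from tree: ", paste(missing, collapse = ", "))
    C <- C[species, species, drop = FALSE]
  }
  C
}

# Symmetrize + verify positive semi-definiteness (tolerance on the smallest
# eigenvalue); used on user-supplied correlation matrices.
.check_psd <- function(C, what = "correlation matrix", tol = 1e-8) {
  if (max(abs(C - t(C))) > 1e-10) stop(what, " is not symmetric")
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) stop(what, " is not positive semi-definite")
  invisible(C)
}
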