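#' Patristic distance matrix from a phylogeny
#'
#' Sums branch lengths along the path between every pair of tips. The
#' trees consumed here are expected to be ultrametric (equal root-to-tip
#' depths); departures beyond a 1e-6 relative tolerance raise a warning,
#' not an error, since time calibration happens upstream.
#'
#' @param tree an \pkg{ape} \code{phylo} object with branch lengths, or a
#'   path to a Newick file.
#' @return symmetric patristic distance matrix with tip-name dimnames.
#' @export
patristic_matrix <- function(tree) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object or Newick file")
  if (is.null(tree$edge.length)) stop("tree has missing branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip names in tree")
  if (!ape::is.ultrametric(tree, tol = 1e-6, option = 2))
    warning("tree is not ultrametric (relative tolerance 1e-6)")
  as.matrix(stats::cophenetic(tree))
}

#' Standardised effect size of mean pairwise phylogenetic distance
#'
#' Observed MPD (mean pairwise patristic distance among a community's
#' members) compared against richness-matched random communities drawn
#' from the tree's tip pool — the same null engine used for color
#' disparity, applied to the patristic matrix, so trait and phylogenetic
#' dispersion are measured on one common footing.
#'
#' @param members character vector of community members (tree tips).
#' @param tree phylogeny (see [patristic_matrix()]) or a precomputed
#'   patristic matrix.
#' @param n_iter number of null communities (default 10000).
#' @param seed optional integer seed.
#' @return a \code{"null_summary"} (see [null_disparity()]) whose
#'   \code{observed} is the community MPD.
#' @export
ses_mpd <- function(members, tree, n_iter = 10000, seed = NULL) {
  d <- if (is.matrix(tree)) tree else patristic_matrix(tree)
  obs <- mean_pairwise_disparity(members, d)
  null_disparity(length(unique(members)), d, n_iter = n_iter, seed = seed,
                 observed = obs)
}

#' Per-community MPD dispersion table
#'
#' Runs [ses_mpd()] for every community in a membership table, with
#' deterministic per-seep substreams from the master seed.
#'
#' @param communities data.frame with columns \code{seep_id}, \code{species}.
#' @inheritParams ses_mpd
#' @return data.frame with columns \code{seep_id}, \code{richness},
#'   \code{observed_mpd}, \code{null_mean}, \code{null_sd}, \code{ci_lo},
#'   \code{ci_hi}, \code{z}.
#' @export
mpd_dispersion <- function(communities, tree, n_iter = 10000, seed = NULL) {
  d <- if (is.matrix(tree)) tree else patristic_matrix(tree)
  out <- community_dispersion(communities, d, n_iter = n_iter, seed = seed)
  names(out)[names(out) == "observed_mean"] <- "observed_mpd"
  names(out)[names(out) == "null_grand_mean"] <- "null_mean"
  out
}
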