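# Tree simulation: Yule (pure-birth) topologies with rescaled branch
# lengths, reproducible for a fixed seed.

#' Simulate a pure-birth tree
#'
#' Yule topology with unit birth rate via [ape::rphylo()]; branch lengths
#' are rescaled so that their mean equals `branch_length_scale` (expected
#' substitutions per site on an average edge).
#'
#' @param n_taxa number of leaves (at least 3).
#' @param seed integer RNG seed; fixed seed gives a bit-identical tree.
#' @param branch_length_scale positive mean edge length after rescaling.
#' @param labels optional leaf labels; default `t01, t02, ...`.
#' @return A rooted, fully bifurcating `phylo` tree with strictly positive
#'   branch lengths.
#' @export
simulate_tree <- function(n_taxa, seed = 1L, branch_length_scale = 0.1,
                          labels = NULL) {
  if (n_taxa < 3L) stop("n_taxa must be at least 3")
  if (branch_length_scale <= 0) stop("branch_length_scale must be positive")
  set.seed(as.integer(seed))
  tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tr$edge.length <- pmax(tr$edge.length, 1e-6)
  tr$edge.length <- tr$edge.length * branch_length_scale /
    mean(tr$edge.length)
  tr$tip.label <- if (is.null(labels)) {
    sprintf("t%0*d", nchar(as.character(n_taxa)), seq_len(n_taxa))
  } else {
    stopifnot(length(labels) == n_taxa)
    labels
  }
  tr
}
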