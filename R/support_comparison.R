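# Cross-analysis node-support comparison: threshold fractions over a clade,
# the missing-data-artifact check, and side-by-side support tables.

#' Support profile of one analysis
#'
#' Bundles an analysis label, its best (reference) tree and the bipartition
#' support map, optionally restricted to a clade of interest (e.g. the
#' ingroup).
#'
#' @param label analysis label (e.g. `"nt123_19genes"`).
#' @param tree the analysis's best `phylo` tree.
#' @param support named numeric vector of percent support per split key
#'   (as from [bootstrap_support()]`$frequencies`), or `NULL` to read
#'   `tree$node.label`.
#' @param clade_taxa optional taxon labels spanning the clade of interest.
#' @return Object of class `support_profile`.
#' @export
support_profile <- function(label, tree, support = NULL,
                            clade_taxa = NULL) {
  if (is.null(support)) {
    ntip <- length(tree$tip.label)
    nodes <- ntip + seq_len(tree$Nnode)
    keys <- .node_splits(tree, nodes, sort(tree$tip.label))
    val <- suppressWarnings(as.numeric(tree$node.label))
    keep <- nzchar(keys) & !is.na(val)
    support <- val[keep]
    names(support) <- keys[keep]
  }
  if (length(support) && (any(support < 0) || any(support > 100))) {
    stop("support values must lie in [0, 100]")
  }
  structure(list(label = label, tree = tree, support = support,
                 clade_taxa = clade_taxa),
            class = "support_profile")
}

#' Internal-node count of a rooted clade
#'
#' Number of internal nodes of the rooted subtree spanned by `clade_taxa`
#' (the subtree root included); for a fully bifurcating rooted subtree with
#' n leaves this is n - 1. Polytomies are counted as they stand, with a
#' warning.
#'
#' @param tree a `phylo` tree.
#' @param clade_taxa leaf labels of the clade; defaults to all leaves.
#' @return Integer internal-node count.
#' @export
count_internal_nodes <- function(tree, clade_taxa = NULL) {
  if (is.null(clade_taxa) || setequal(clade_taxa, tree$tip.label)) {
    sub <- tree
  } else {
    node <- ape::getMRCA(tree, clade_taxa)
    sub <- ape::extract.clade(tree, node)
  }
  n <- sub$Nnode
  if (n != length(sub$tip.label) - 1L) {
    warning("subtree is not fully bifurcating; counting ", n,
            " internal nodes as-is")
  }
  n
}

#' Fractions of clade nodes meeting support thresholds
#'
#' For each threshold t, the fraction of the clade's internal nodes whose
#' bipartition support is at least t, reported as a whole-number percent.
#' By the usual convention, 70-79% is read as moderate and >= 80% as strong
#' support; fractions are necessarily non-increasing in the threshold.
#'
#' @param profile a [support_profile()].
#' @param thresholds numeric thresholds in percent.
#' @return List of class `threshold_report`: `thresholds`,
#'   `fraction_percent` (rounded), `n_nodes`, `n_meeting`.
#' @export
threshold_fractions <- function(profile, thresholds = c(70, 80, 90)) {
  tree <- profile$tree
  clade <- profile$clade_taxa
  if (is.null(clade)) clade <- tree$tip.label
  if (setequal(clade, tree$tip.label)) {
    sub <- tree
  } else {
    sub <- ape::extract.clade(tree, ape::getMRCA(tree, clade))
  }
  ntip <- length(sub$tip.label)
  nodes <- ntip + seq_len(sub$Nnode)
  # node support = support of the split separating the node's clade,
  # measured on the full taxon set; the subtree root's split is the clade
  # itself versus the rest
  keys <- .node_splits(sub, nodes, sort(tree$tip.label))
  supp <- profile$support[keys]
  supp[is.na(supp)] <- 0
  n <- length(nodes)
  meet <- vapply(thresholds, function(t) sum(supp >= t), 0L)
  structure(list(thresholds = thresholds,
                 fraction_percent = round(100 * meet / n),
                 n_nodes = n, n_meeting = meet),
            class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf(">=%g%%: %d/%d nodes (%g%%)\n", x$thresholds, x$n_meeting,
              x$n_nodes, x$fraction_percent), sep = "")
  invisible(x)
}

#' Missing-data artifact check
#'
#' If large blocks of deliberately missing data created artifactual
#' groupings, the expanded-but-incomplete matrix would strongly support
#' groups that do not occur in trees from the complete (reduced-gene)
#' matrix. This returns every bipartition with support at or above
#' `strong_threshold` in `full` that is absent from the `reduced` best
#' tree; an empty result is the no-artifact outcome.
#'
#' @param full [support_profile()] of the deliberately incomplete matrix
#'   analysis (bootstrap supports required).
#' @param reduced [support_profile()] of the complete-matrix analysis.
#' @param strong_threshold percent support counted as strong (default 80).
#' @return Named numeric vector (possibly empty) of offending splits and
#'   their supports.
#' @export
detect_missing_data_artifacts <- function(full, reduced,
                                          strong_threshold = 80) {
  if (!setequal(full$tree$tip.label, reduced$tree$tip.label)) {
    stop("profiles must share one taxon set")
  }
  strong <- full$support[full$support >= strong_threshold]
  strong[setdiff(names(strong), tree_splits(reduced$tree))]
}

#' Side-by-side support table across analyses
#'
#' One row per internal node of the first profile's (reference) tree; one
#' column per analysis holding its percent support for that node's
#' bipartition, or the marker `"-"` when the bipartition is absent from
#' that analysis's best tree.
#'
#' @param profiles list of [support_profile()] objects over one taxon set.
#' @return Data frame with a `split` column and one column per analysis,
#'   in input order.
#' @export
compare_codings <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  ref <- profiles[[1]]$tree
  taxa <- sort(ref$tip.label)
  for (p in profiles[-1]) {
    if (!setequal(p$tree$tip.label, ref$tip.label)) {
      stop("profiles must share one taxon set")
    }
  }
  splits <- tree_splits(ref)
  out <- data.frame(split = splits, stringsAsFactors = FALSE)
  for (p in profiles) {
    present <- tree_splits(p$tree)
    col <- vapply(splits, function(k) {
      if (!k %in% present) return("-")
      v <- p$support[k]
      if (is.na(v)) "0" else format(round(v))
    }, "")
    out[[p$label]] <- unname(col)
  }
  out
}
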