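# Bipartition (split) utilities: canonical label-set keys, so comparisons
# are invariant to leaf ordering, tree rotation and rooting.

# canonical key for one side of a split: the side NOT containing the
# alphabetically first taxon, labels sorted and joined
split_key <- function(side, all_taxa) {
  anchor <- min(all_taxa)
  if (anchor %in% side) side <- setdiff(all_taxa, side)
  paste(sort(side), collapse = "|")
}

#' Non-trivial bipartitions of a tree
#'
#' Every internal edge of the unrooted tree induces a split of the leaf
#' set; trivial splits (single leaf or its complement) are dropped. Splits
#' are returned as canonical keys (sorted labels of the side not holding
#' the alphabetically first taxon, joined by `|`).
#'
#' @param tree a `phylo` tree.
#' @param taxa optional taxon set to restrict the splits to (labels not in
#'   `taxa` are dropped before canonicalization).
#' @return Character vector of split keys (may contain duplicates only if
#'   restriction collapses distinct edges; duplicates are removed).
#' @export
tree_splits <- function(tree, taxa = NULL) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  desc <- vector("list", nnode)
  desc[seq_len(ntip)] <- as.list(tr$tip.label)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  all_taxa <- if (is.null(taxa)) tr$tip.label else intersect(tr$tip.label,
                                                            taxa)
  keys <- character(0)
  for (e in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[e, 2]
    if (ch <= ntip) next
    side <- intersect(desc[[ch]], all_taxa)
    if (length(side) < 2L || length(side) > length(all_taxa) - 2L) next
    keys <- c(keys, split_key(side, all_taxa))
  }
  unique(keys)
}

# splits for every internal node of a *rooted* subtree view: named by node
# id, value = canonical split key over all_taxa (used for node-support maps)
.node_splits <- function(tree, nodes, all_taxa) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  desc <- vector("list", ntip + tr$Nnode)
  desc[seq_len(ntip)] <- as.list(tr$tip.label)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  out <- vapply(nodes, function(nd)
    split_key(intersect(desc[[nd]], all_taxa), all_taxa), "")
  names(out) <- as.character(nodes)
  out
}
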