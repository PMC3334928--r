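# Nonparametric bootstrap: resample alignment columns with replacement
# within each partition, re-search per pseudo-replicate, tabulate
# bipartition frequencies.

#' Nonparametric bootstrap over site columns
#'
#' Each pseudo-replicate resamples nucleotide columns with replacement
#' within every partition (preserving partition sizes), then runs
#' [search_tree()] with `searches_per_rep` random-addition starts. Model
#' parameters are held fixed at the supplied values during replicates (the
#' desk-scale analogue of estimating them once on the original matrix).
#'
#' @param matrix a `supermatrix` or [codon_alignment()].
#' @param models single [subst_model()] or list per partition.
#' @param scheme optional `partition_scheme`.
#' @param n_replicates number of pseudo-replicates.
#' @param seed integer seed; replicate `r` uses `seed + r`.
#' @param searches_per_rep stepwise-addition starts per replicate.
#' @param optimize_bl whether each replicate search ends with a full
#'   branch-length pass (off by default for speed; NNI still interleaves
#'   coarse passes).
#' @param start_tree optional reference tree handed to [search_tree()] as
#'   the start of every replicate (skipping stepwise addition); the
#'   rapid-bootstrap-style option for large matrices.
#' @return Object of class `bootstrap_result`: `n_replicates`,
#'   `frequencies` (named percent per split key), `taxa` and `trees`
#'   (the per-replicate best trees).
#' @export
bootstrap_support <- function(matrix, models, scheme = NULL,
                              n_replicates = 100L, seed = 1L,
                              searches_per_rep = 1L, optimize_bl = FALSE,
                              start_tree = NULL) {
  n_replicates <- as.integer(n_replicates)
  stopifnot(n_replicates >= 1L)
  if (inherits(matrix, "codon_alignment")) {
    matrix <- concatenate_genes(list(matrix))
  }
  sets <- if (is.null(scheme)) list(all = seq_len(ncol(matrix$mat)))
          else unclass(scheme)
  counts <- new.env(parent = emptyenv())
  trees <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(as.integer(seed) + r)
    cols <- unlist(lapply(sets, function(s)
      if (length(s)) sample(s, length(s), replace = TRUE) else integer(0)))
    reps <- matrix   # resampled pseudo-matrix, same partition geometry
    reps$mat <- matrix$mat[, cols, drop = FALSE]
    scheme_r <- if (is.null(scheme)) NULL else {
      lens <- vapply(sets, length, 1L)
      out <- split(seq_len(sum(lens)), rep(seq_along(sets), lens))
      names(out) <- names(sets)
      class(out) <- "partition_scheme"
      out
    }
    tr <- search_tree(reps, models, scheme_r, n_starts = searches_per_rep,
                      seed = as.integer(seed) + 7919L * r,
                      optimize_bl = optimize_bl, start_tree = start_tree)
    trees[[r]] <- tr
    for (k in tree_splits(tr)) {
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
    }
  }
  keys <- ls(counts)
  freq <- vapply(keys, function(k) 100 * counts[[k]] / n_replicates, 0)
  structure(list(n_replicates = n_replicates, frequencies = freq,
                 taxa = matrix$taxa, trees = trees),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap_result: %d replicates, %d non-trivial splits seen\n",
              x$n_replicates, length(x$frequencies)))
  invisible(x)
}

#' Annotate a tree's internal edges with bootstrap support
#'
#' Each internal edge's bipartition is looked up in the bootstrap
#' frequencies; splits never seen in any replicate get 0. Supported splits
#' absent from the tree itself (the "node not present on best tree" case)
#' are reported in the attribute `absent_splits`.
#'
#' @param tree a `phylo` tree.
#' @param result a [bootstrap_support()] result over the same taxon set.
#' @return The tree with `node.label` support values (percent; root label
#'   empty) and attribute `absent_splits`.
#' @export
annotate_support <- function(tree, result) {
  if (!setequal(tree$tip.label, result$taxa)) {
    stop("tree leaves do not match the bootstrap taxon set")
  }
  ntip <- length(tree$tip.label)
  nodes <- ntip + seq_len(tree$Nnode)
  keys <- .node_splits(tree, nodes, sort(tree$tip.label))
  lab <- character(tree$Nnode)
  for (i in seq_along(nodes)) {
    side_size <- lengths(regmatches(keys[i], gregexpr("\\|", keys[i]))) + 1L
    trivial <- !nzchar(keys[i]) || side_size < 2L ||
      side_size > ntip - 2L
    lab[i] <- if (trivial) "" else {
      f <- result$frequencies[keys[i]]
      format(round(ifelse(is.na(f), 0, f), 1))
    }
  }
  tree$node.label <- lab
  own <- tree_splits(tree)
  attr(tree, "absent_splits") <-
    result$frequencies[setdiff(names(result$frequencies), own)]
  tree
}
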