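# Tree search: random stepwise-addition starting trees with best-insertion
# by log-likelihood, then NNI hill climbing. Desk-scale replacement for
# cluster-scale stochastic searches; search effort is configuration.

# unrooted 3-taxon star with default branch lengths
.three_taxon_tree <- function(labels, bl = 0.1) {
  structure(list(edge = matrix(c(4L, 4L, 4L, 1L, 2L, 3L), ncol = 2),
                 edge.length = rep(bl, 3),
                 tip.label = labels, Nnode = 1L),
            class = "phylo")
}

# insert a new tip on edge e (index into tree$edge): the edge is split in
# half and a pendant edge attached
.insert_tip <- function(tree, e, label, pendant = 0.1) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  el <- tree$edge.length
  # renumber: tips unchanged except new tip = ntip+1; internal nodes shift by 1
  edge[edge > ntip] <- edge[edge > ntip] + 1L
  new_tip <- ntip + 1L
  new_int <- ntip + 1L + tree$Nnode + 1L
  par <- edge[e, 1]; ch <- edge[e, 2]
  half <- el[e] / 2
  edge[e, ] <- c(par, new_int)
  el[e] <- max(half, .BL_MIN)
  edge <- rbind(edge, c(new_int, ch), c(new_int, new_tip))
  el <- c(el, max(half, .BL_MIN), pendant)
  out <- structure(list(edge = edge, edge.length = el,
                        tip.label = c(tree$tip.label, label),
                        Nnode = tree$Nnode + 1L),
                   class = "phylo")
  attr(out, "order") <- NULL
  out
}

# the two NNI rearrangements around internal edge (u, v); v's children a, b
# are exchanged in turn with one other neighbor c of u
.nni_neighbors <- function(tree) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  out <- list()
  internal <- which(edge[, 2] > ntip)
  for (e in internal) {
    u <- edge[e, 1]; v <- edge[e, 2]
    rows_a <- which(edge[, 1] == v)
    row_c <- setdiff(which(edge[, 1] == u), e)[1]
    if (is.na(row_c)) next
    for (ra in rows_a) {
      t2 <- tree
      t2$edge[ra, 2] <- edge[row_c, 2]
      t2$edge[row_c, 2] <- edge[ra, 2]
      tmp <- t2$edge.length[ra]
      t2$edge.length[ra] <- t2$edge.length[row_c]
      t2$edge.length[row_c] <- tmp
      attr(t2, "order") <- NULL # edge order no longer postorder
      out[[length(out) + 1L]] <- list(tree = t2, edge = e)
    }
  }
  out
}

# hill climb: accept the best improving NNI neighbor until none improves
.nni_search <- function(tree, data, models, bl_pass_every = 3L,
                        max_rounds = 50L) {
  best_ll <- .loglik(tree, data, models)
  accepts <- 0L
  for (round in seq_len(max_rounds)) {
    nbrs <- .nni_neighbors(tree)
    if (!length(nbrs)) break
    lls <- vapply(nbrs, function(n) .loglik(n$tree, data, models), 0)
    if (max(lls) <= best_ll + 1e-9) break
    k <- which.max(lls)
    tree <- nbrs[[k]]$tree
    best_ll <- lls[k]
    accepts <- accepts + 1L
    if (accepts %% bl_pass_every == 0L) {
      tree <- .optimize_branch_lengths(tree, data, models)
      best_ll <- .loglik(tree, data, models)
    }
  }
  list(tree = tree, loglik = best_ll)
}

# single stepwise-addition build over a given taxon order
.stepwise_tree <- function(order, data, models, pendant = 0.1) {
  tree <- .three_taxon_tree(order[1:3], bl = pendant)
  for (k in 4:length(order)) {
    best <- NULL; best_ll <- -Inf
    for (e in seq_len(nrow(tree$edge))) {
      cand <- .insert_tip(tree, e, order[k], pendant)
      ll <- .loglik(cand, data, models)
      if (ll > best_ll + 1e-12) { best <- cand; best_ll <- ll }
    }
    tree <- best
  }
  tree
}

#' Maximum-likelihood tree search
#'
#' For each start, taxa are added in random order by best-scoring stepwise
#' insertion, branch lengths are optimized, and the tree is refined by NNI
#' hill climbing (interleaved with branch-length passes) to a local
#' optimum. The highest-likelihood tree over all starts is returned; ties
#' in insertion score are broken by the first (smallest-index) edge, and
#' the whole procedure is deterministic given `seed`.
#'
#' @param matrix a `supermatrix` or [codon_alignment()].
#' @param models single [subst_model()] or list per partition.
#' @param scheme optional `partition_scheme`.
#' @param n_starts number of random-addition starts.
#' @param seed integer seed.
#' @param optimize_bl if `TRUE` (default) finish with a full
#'   branch-length pass.
#' @param data optional precomputed [likelihood_data()] (for callers that
#'   re-search on resampled data).
#' @param start_tree optional starting `phylo` tree; when supplied, the
#'   stepwise-addition phase is skipped and every start refines this tree
#'   by NNI hill climbing (the rapid-bootstrap-style shortcut for large
#'   replicate analyses).
#' @return The best `phylo` tree found, with its log-likelihood in
#'   attribute `loglik`.
#' @export
search_tree <- function(matrix, models, scheme = NULL, n_starts = 1L,
                        seed = 1L, optimize_bl = TRUE, data = NULL,
                        start_tree = NULL) {
  if (is.null(data)) data <- likelihood_data(matrix, scheme)
  if (length(data$taxa) < 4L) stop("need at least 4 taxa to search")
  models <- .match_models(models, data)
  set.seed(as.integer(seed))
  best <- NULL; best_ll <- -Inf
  for (s in seq_len(n_starts)) {
    if (is.null(start_tree)) {
      order <- sample(sort(data$taxa))
      tree <- .stepwise_tree(order, data, models)
      tree <- .optimize_branch_lengths(tree, data, models)
    } else {
      tree <- start_tree
    }
    fit <- .nni_search(tree, data, models)
    tree <- fit$tree; ll <- fit$loglik
    if (optimize_bl) {
      tree <- .optimize_branch_lengths(tree, data, models)
      ll <- .loglik(tree, data, models)
    }
    if (ll > best_ll) { best <- tree; best_ll <- ll }
  }
  # normalize node numbering to ape's canonical layout
  best <- ape::read.tree(text = ape::write.tree(best))
  attr(best, "loglik") <- best_ll
  best
}
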