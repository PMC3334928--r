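# Partitioned log-likelihood of a tree given a supermatrix, via the
# pruning algorithm (compiled kernel) on compressed site patterns.
# IUPAC-coded matrices (e.g. degen1-recoded data) are handled by summing
# over compatible states; '?' and '-' are fully ambiguous.

# 0/1 partial-likelihood column for one alignment symbol
.symbol_partial <- function(ch) {
  v <- numeric(4)
  v[match(expand_iupac(ch), NUC)] <- 1
  v
}

# compress alignment columns (character matrix rows = taxa) into patterns
.compress_patterns <- function(mat) {
  if (ncol(mat) == 0L) {
    return(list(cols = mat, weights = numeric(0), index = integer(0)))
  }
  key <- apply(mat, 2L, paste, collapse = "")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  list(cols = mat[, first, drop = FALSE],
       weights = as.numeric(tabulate(idx, sum(first))),
       index = idx)
}

# site data for one partition: tip partials in a fixed taxon order
.partition_data <- function(mat) {
  pat <- .compress_patterns(mat)
  ntip <- nrow(mat)
  npat <- length(pat$weights)
  tp <- matrix(0, nrow = 4, ncol = ntip * npat)
  if (npat > 0L) {
    syms <- unique(as.vector(pat$cols))
    lut <- vapply(syms, .symbol_partial, numeric(4))
    colnames(lut) <- syms
    # tip t occupies columns (t-1)*npat + 1:npat
    for (t in seq_len(ntip)) {
      tp[, (t - 1L) * npat + seq_len(npat)] <- lut[, pat$cols[t, ]]
    }
  }
  list(tip_partials = tp, weights = pat$weights, npat = npat, ntip = ntip)
}

#' Precompute likelihood site data for a supermatrix
#'
#' Splits the matrix by partition (or keeps it whole), compresses site
#' patterns and builds tip partial-likelihood tables once, so that repeated
#' likelihood evaluations during optimization and search only pay for the
#' pruning pass.
#'
#' @param matrix a `supermatrix`, a [codon_alignment()] (treated as a
#'   single-gene matrix), or a raw character matrix with taxon rownames
#'   (any number of columns; useful for partition slices).
#' @param scheme optional `partition_scheme`; `NULL` means unpartitioned.
#' @return An object of class `likelihood_data`.
#' @export
likelihood_data <- function(matrix, scheme = NULL) {
  if (is.matrix(matrix) && is.character(matrix)) {
    matrix <- list(taxa = rownames(matrix), mat = matrix)
  } else if (inherits(matrix, "codon_alignment")) {
    matrix <- concatenate_genes(list(matrix))
  }
  sets <- if (is.null(scheme)) list(all = seq_len(ncol(matrix$mat)))
          else unclass(scheme)
  parts <- lapply(sets, function(s)
    .partition_data(matrix$mat[, s, drop = FALSE]))
  structure(list(parts = parts, taxa = matrix$taxa), class = "likelihood_data")
}

# match models argument to partitions: a single subst_model is recycled
.match_models <- function(models, data) {
  if (inherits(models, "subst_model")) {
    models <- rep(list(models), length(data$parts))
    names(models) <- names(data$parts)
  }
  if (length(models) != length(data$parts)) {
    stop("need one model per partition")
  }
  models
}

# pruning log-likelihood given precomputed data; tree tip labels must match
# data$taxa as a set
.loglik <- function(tree, data, models) {
  models <- .match_models(models, data)
  tr <- ape::reorder.phylo(tree, "postorder")
  perm <- match(tr$tip.label, data$taxa)
  if (anyNA(perm)) stop("tree leaves do not match matrix taxa")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  el <- pmax(tr$edge.length, 1e-8)
  total <- 0
  for (i in seq_along(data$parts)) {
    p <- data$parts[[i]]
    if (p$npat == 0L) next
    m <- models[[i]]
    eig <- gtr_eigen(m)
    mix <- gamma_invariant_mixture(m)
    # reorder tip blocks to the tree's tip numbering
    tp <- p$tip_partials[, as.vector(outer(seq_len(p$npat), (perm - 1L) * p$npat,
                                           `+`)), drop = FALSE]
    ll <- pruning_site_loglik(tr$edge, el, eig$U, eig$Uinv, eig$lambda,
                              mix$rates, mix$weights, m$base_freq,
                              tp, ntip, nnode, p$npat)
    if (any(!is.finite(ll))) {
      stop("numerical error: zero site likelihood (all-zero partials) in ",
           "partition ", names(data$parts)[i])
    }
    total <- total + sum(p$weights * ll)
  }
  total
}

#' Log-likelihood of a tree under (partitioned) GTR+gamma+I
#'
#' Sum over sites of the log of the gamma+I mixture likelihood computed by
#' the pruning algorithm, with per-node scaling for numerical stability.
#' Gap and missing symbols are fully ambiguous; IUPAC codes sum over their
#' compatible states, so degen1-recoded matrices are handled natively.
#'
#' @param tree a `phylo` tree whose leaves are the matrix taxa.
#' @param matrix a `supermatrix` or [codon_alignment()].
#' @param models a single [subst_model()] (recycled over partitions) or a
#'   list with one model per partition.
#' @param scheme optional `partition_scheme`.
#' @return The log-likelihood (a single number).
#' @export
log_likelihood <- function(tree, matrix, models, scheme = NULL) {
  .loglik(tree, likelihood_data(matrix, scheme), models)
}
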