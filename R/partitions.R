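# Character partitioning: leucine/arginine-aware first-position filtering
# and construction of the non-synonymous nt1+nt2 versus potentially
# synonymous nt1+nt3 partitions.

# Does a codon possibly encode leucine or arginine? Conservative rule: TRUE
# if ANY IUPAC expansion translates to L or R (a site only lacks synonymous
# first-position signal if no species can carry Leu/Arg there). Codons with
# gap/missing symbols never count.
.codon_maybe_LR <- function(codon, code = standard_genetic_code()) {
  ch <- strsplit(codon, "")[[1]]
  if (any(ch %in% c("-", "?"))) return(FALSE)
  any(codon_amino_acids(codon, code) %in% c("L", "R"))
}

#' First-position sites free of leucine and arginine
#'
#' Leucine and arginine are the only amino acids whose codons can vary
#' synonymously at the first position (CTN/TTR and CGN/AGR). First-position
#' sites of codon columns where no taxon's codon is compatible with Leu or
#' Arg therefore carry no synonymous signal; these are the sites pooled with
#' nt2 into the non-synonymous partition.
#'
#' Codons containing IUPAC ambiguity codes count as Leu/Arg-encoding if any
#' expansion translates to Leu or Arg (conservative exclusion); codons with
#' gap or missing symbols never do.
#'
#' @param alignment a [codon_alignment()].
#' @param code genetic code table.
#' @return Integer vector of included nt1 column indices (1-based).
#' @export
find_noLR_nt1_sites <- function(alignment, code = standard_genetic_code()) {
  mat <- alignment$mat
  nc <- ncol(mat) %/% 3L
  if (nc == 0L) return(integer(0))
  codons <- matrix(paste0(mat[, 3 * seq_len(nc) - 2],
                          mat[, 3 * seq_len(nc) - 1],
                          mat[, 3 * seq_len(nc)]),
                   nrow = nrow(mat))
  uniq <- unique(as.vector(codons))
  lr <- vapply(uniq, .codon_maybe_LR, TRUE, code = code)
  col_has_lr <- matrix(lr[codons], nrow = nrow(mat))
  keep <- !apply(col_has_lr, 2L, any)
  3L * which(keep) - 2L
}

#' Build the two-way character partition of a supermatrix
#'
#' Splits all (unmasked) sites of a supermatrix into
#' `nonsyn_nt1_nt2` = (noLR nt1 sites) + (all nt2 sites), reflecting only
#' non-synonymous change, and `potsyn_nt1_nt3` = (Leu/Arg-capable nt1
#' sites) + (all nt3 sites), carrying the potentially synonymous change.
#' The two site sets are disjoint and together cover every column.
#'
#' Partially masked codons are evaluated with `N` at the masked positions,
#' which under the conservative Leu/Arg rule sends their surviving nt1 sites
#' to the potentially synonymous partition.
#'
#' @param matrix a `supermatrix` (apply any exclusion mask first).
#' @param code genetic code table.
#' @return A named list of class `partition_scheme` with integer column
#'   index sets `nonsyn_nt1_nt2` and `potsyn_nt1_nt3`.
#' @export
build_partitions <- function(matrix, code = standard_genetic_code()) {
  ncols <- ncol(matrix$mat)
  if (ncols == 0L) {
    return(structure(list(nonsyn_nt1_nt2 = integer(0),
                          potsyn_nt1_nt3 = integer(0)),
                     class = "partition_scheme"))
  }
  pos <- matrix$codon_pos
  # reconstruct codon columns from surviving sites, padding masked
  # positions with N; codon identity = (gene block, running codon index)
  nt1_cols <- which(pos == 1L)
  noLR <- logical(length(nt1_cols))
  mat <- matrix$mat
  for (i in seq_along(nt1_cols)) {
    c1 <- nt1_cols[i]
    c2 <- if (c1 + 1L <= ncols && pos[c1 + 1L] == 2L) c1 + 1L else NA_integer_
    c3i <- c1 + (!is.na(c2)) + 1L
    c3 <- if (!is.na(c2) && c3i <= ncols && pos[c3i] == 3L) c3i else {
      if (is.na(c2) && c1 + 1L <= ncols && pos[c1 + 1L] == 3L) c1 + 1L
      else NA_integer_
    }
    codons <- paste0(mat[, c1],
                     if (is.na(c2)) "N" else mat[, c2],
                     if (is.na(c3)) "N" else mat[, c3])
    uniq <- unique(codons)
    noLR[i] <- !any(vapply(uniq, .codon_maybe_LR, TRUE, code = code))
  }
  nonsyn <- sort(c(nt1_cols[noLR], which(pos == 2L)))
  potsyn <- sort(c(nt1_cols[!noLR], which(pos == 3L)))
  if (length(intersect(nonsyn, potsyn)) ||
      length(union(nonsyn, potsyn)) != ncols) {
    stop("internal error: partition leak") # nocov
  }
  structure(list(nonsyn_nt1_nt2 = nonsyn, potsyn_nt1_nt3 = potsyn),
            class = "partition_scheme")
}

#' Export a partition scheme as a RAxML-style partition file
#'
#' @param scheme a `partition_scheme`.
#' @param file output path.
#' @param model model tag to prefix each line with.
#' @return `file`, invisibly.
#' @export
write_raxml_partitions <- function(scheme, file, model = "GTR+G+I") {
  writeLines(sprintf("%s, %s = %s", model, names(scheme),
                     vapply(scheme, function(s)
                       gsub(" ", ", ", compact_ranges(s)), "")),
             file)
  invisible(file)
}
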