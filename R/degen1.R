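# degen1 recoding: fully degenerate every codon position capable of
# synonymous change, using IUPAC ambiguity codes, so synonymous differences
# become invisible to downstream inference.

#' The degen1 codon recoding table
#'
#' For each sense codon, its synonymous family (single-nucleotide-step
#' closure, see [synonymous_families()]) is collected and each codon
#' position is replaced by the IUPAC code spanning the family's states at
#' that position. Positions with no synonymous degeneracy are left
#' unchanged: ATG (Met) and TGG (Trp) map to themselves, CAC/CAT (His) both
#' map to CAY, and all six leucine codons map to YTN. Serine's TCN and AGY
#' families are kept distinct (no single-step synonymous path connects
#' them), so TCT maps to TCN and AGT to AGY.
#'
#' @inheritParams translate_codons
#' @param stop_codon value recorded for the three stop codons (policy
#'   entries; the recoder applies its own stop policy before lookup).
#' @return Named character vector over all 64 codons.
#' @export
degen1_table <- function(code = standard_genetic_code(), stop_codon = "NNN") {
  key <- paste0("degen1.", stop_codon)
  if (!is.null(.code_cache[[key]])) return(.code_cache[[key]])
  fams <- synonymous_families(code)
  out <- character(64)
  names(out) <- names(code)
  for (fam in fams) {
    chars <- do.call(rbind, strsplit(fam, ""))
    img <- paste0(iupac_code(chars[, 1]), iupac_code(chars[, 2]),
                  iupac_code(chars[, 3]))
    out[fam] <- img
  }
  out[names(code)[code == "*"]] <- stop_codon
  .code_cache[[key]] <- out
  out
}

# degen1 image of a single, possibly ambiguous codon.
# Gap-/missing-containing codons pass through untouched. A codon with
# ambiguity codes is recoded as the IUPAC union of the degen1 images of its
# sense expansions; stop expansions are dropped under the lenient policy
# (they contribute nothing) and are an error under the strict policy.
.degen1_one <- function(codon, tab, code, strict) {
  ch <- strsplit(codon, "")[[1]]
  if (any(ch %in% c("-", "?"))) return(codon)
  hit <- tab[codon]
  if (!is.na(hit)) {                      # plain codon
    if (code[codon] == "*") {             # in-frame stop
      if (strict) stop("in-frame stop codon: ", codon)
      warning("in-frame stop codon ", codon, " replaced by NNN")
      return("NNN")
    }
    return(unname(hit))
  }
  exps <- codon_expansions(codon)
  aa <- code[exps]
  if (all(aa == "*")) {
    if (strict) stop("codon ", codon, " expands only to stop codons")
    warning("codon ", codon, " expands only to stop codons; replaced by NNN")
    return("NNN")
  }
  if (any(aa == "*") && strict) {
    stop("codon ", codon, " has stop-codon expansions")
  }
  imgs <- tab[exps[aa != "*"]]
  m <- do.call(rbind, strsplit(unname(imgs), ""))
  paste0(
    iupac_code(unlist(lapply(m[, 1], expand_iupac))),
    iupac_code(unlist(lapply(m[, 2], expand_iupac))),
    iupac_code(unlist(lapply(m[, 3], expand_iupac)))
  )
}

#' Recode an in-frame codon alignment with degen1
#'
#' Every codon is replaced by its degen1 representative (see
#' [degen1_table()]). Codons containing gap (`-`) or missing (`?`) symbols
#' pass through unchanged; codons containing IUPAC ambiguity codes are
#' recoded as the positionwise IUPAC union of the images of their sense
#' expansions. In-frame stop codons follow the stop policy: the default
#' lenient policy replaces them with `NNN` and warns (real alignments can
#' contain sequencing artifacts), the strict policy fails.
#'
#' The recoding is idempotent and erases synonymous differences: two sense
#' codons of the same synonymous family always share one image.
#'
#' @param alignment a [codon_alignment()].
#' @param stop_policy `"lenient"` (stop codons become `NNN`, with a warning)
#'   or `"strict"` (error).
#' @param code genetic code table.
#' @return A [codon_alignment()] of identical dimensions.
#' @export
degen1_recode <- function(alignment, stop_policy = c("lenient", "strict"),
                          code = standard_genetic_code()) {
  stop_policy <- match.arg(stop_policy)
  strict <- stop_policy == "strict"
  tab <- degen1_table(code)
  mat <- alignment$mat
  nc <- ncol(mat) / 3L
  codons <- matrix(paste0(mat[, 3 * seq_len(nc) - 2],
                          mat[, 3 * seq_len(nc) - 1],
                          mat[, 3 * seq_len(nc)]),
                   nrow = nrow(mat))
  uniq <- unique(as.vector(codons))
  img <- vapply(uniq, .degen1_one, "", tab = tab, code = code,
                strict = strict)
  rec <- matrix(img[codons], nrow = nrow(mat))
  out <- matrix("", nrow = nrow(mat), ncol = ncol(mat),
                dimnames = dimnames(mat))
  spl <- strsplit(as.vector(rec), "")
  out[, 3 * rep(seq_len(nc), each = 1) - 2] <-
    matrix(vapply(spl, `[`, "", 1L), nrow = nrow(mat))
  out[, 3 * seq_len(nc) - 1] <- matrix(vapply(spl, `[`, "", 2L), nrow = nrow(mat))
  out[, 3 * seq_len(nc)] <- matrix(vapply(spl, `[`, "", 3L), nrow = nrow(mat))
  codon_alignment(out, gene = alignment$gene)
}
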