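# Genetic-code machinery: the standard nuclear code, IUPAC ambiguity algebra,
# and synonymous codon families under single-nucleotide-step closure.

NUC <- c("A", "C", "G", "T")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# reverse map: sorted base set -> IUPAC letter
.IUPAC_BY_KEY <- local({
  keys <- vapply(IUPAC_SETS, function(s) paste(sort(s), collapse = ""), "")
  out <- names(IUPAC_SETS)
  names(out) <- keys
  out
})

#' IUPAC code covering a set of bases
#'
#' @param bases character vector of bases drawn from A, C, G, T.
#' @return The single-letter IUPAC code whose expansion is exactly
#'   `unique(bases)`.
#' @examples
#' iupac_code(c("C", "T")) # "Y"
#' @export
iupac_code <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  code <- .IUPAC_BY_KEY[[key]]
  if (is.null(code)) stop("not a valid base set: ", key)
  code
}

#' Expand an IUPAC symbol to its base set
#'
#' @param x a single IUPAC nucleotide symbol (case-insensitive).
#' @return Character vector of plain bases. Gap (`-`) and missing (`?`)
#'   symbols expand to all four bases, matching their treatment as fully
#'   ambiguous in likelihood computations.
#' @export
expand_iupac <- function(x) {
  x <- toupper(x)
  if (x %in% c("-", "?")) return(NUC)
  s <- IUPAC_SETS[[x]]
  if (is.null(s)) stop("unknown IUPAC symbol: ", x)
  s
}

#' All plain-base expansions of a (possibly ambiguous) codon
#'
#' @param codon a 3-character string over the IUPAC alphabet.
#' @return Character vector of ACGT codons the input is compatible with.
#' @export
codon_expansions <- function(codon) {
  stopifnot(nchar(codon) == 3L)
  ch <- strsplit(codon, "", fixed = TRUE)[[1]]
  sets <- lapply(ch, expand_iupac)
  grid <- expand.grid(sets[[1]], sets[[2]], sets[[3]],
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  paste0(grid[[1]], grid[[2]], grid[[3]])
}

#' The standard nuclear genetic code
#'
#' Loaded from a plain-text table shipped with the package
#' (`extdata/standard_genetic_code.tsv`), so that an alternative code table
#' can be supplied for organisms with non-standard nuclear codes.
#'
#' @param path optional path to a two-column TSV (codon, aa) overriding the
#'   shipped standard table. Stop codons use `*`.
#' @return Named character vector mapping all 64 codons to one-letter amino
#'   acids (`*` = stop).
#' @export
standard_genetic_code <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.code_cache$std)) return(.code_cache$std)
    path <- system.file("extdata", "standard_genetic_code.tsv",
                        package = "phylodegen", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("codon", "aa") %in% names(tab))) {
    stop("genetic code table must have columns 'codon' and 'aa'")
  }
  code <- toupper(tab$aa)
  names(code) <- toupper(tab$codon)
  if (length(code) != 64L || anyDuplicated(names(code))) {
    stop("genetic code table must cover all 64 codons exactly once")
  }
  .code_cache$std <- code
  code
}

.code_cache <- new.env(parent = emptyenv())

#' Translate sense codons
#'
#' @param codons character vector of plain ACGT codons.
#' @param code genetic code, as from [standard_genetic_code()].
#' @return One-letter amino acids (`*` for stops).
#' @export
translate_codons <- function(codons, code = standard_genetic_code()) {
  aa <- code[toupper(codons)]
  if (anyNA(aa)) stop("not plain sense/stop codons: ",
                      paste(codons[is.na(aa)], collapse = ", "))
  unname(aa)
}

#' Amino acids compatible with a possibly ambiguous codon
#'
#' Expands every IUPAC symbol and translates each expansion; stop-codon
#' expansions are reported as `*`.
#'
#' @inheritParams translate_codons
#' @param codon a 3-character codon over the IUPAC alphabet.
#' @return Character vector of distinct one-letter amino acids.
#' @export
codon_amino_acids <- function(codon, code = standard_genetic_code()) {
  unique(unname(code[codon_expansions(codon)]))
}

#' Synonymous codon families under single-step closure
#'
#' Two sense codons belong to the same family when they are connected by a
#' chain of single-nucleotide substitutions that each preserve the amino
#' acid. This splits serine into its TCN and AGY families (no
#' single-nucleotide synonymous path joins them), while the six leucine and
#' six arginine codons each form one family.
#'
#' @inheritParams translate_codons
#' @return Named list: family id (e.g. `"L"`, `"S.1"`, `"S.2"`) to a
#'   character vector of member codons.
#' @export
synonymous_families <- function(code = standard_genetic_code()) {
  sense <- names(code)[code != "*"]
  # union-find over single-step synonymous edges
  parent <- seq_along(sense)
  names(parent) <- sense
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_along(sense)) {
    ca <- sense[a]
    ch <- strsplit(ca, "")[[1]]
    for (pos in 1:3) for (b in NUC) {
      if (b == ch[pos]) next
      cb <- ch; cb[pos] <- b; cb <- paste(cb, collapse = "")
      if (!is.na(code[cb]) && code[cb] == code[ca] && code[cb] != "*") {
        ra <- find(a); rb <- find(match(cb, sense))
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  roots <- vapply(seq_along(sense), find, 1L)
  fams <- split(sense, roots)
  aa <- vapply(fams, function(f) unname(code[f[1]]), "")
  # disambiguate amino acids split into several families (serine)
  ids <- ave(aa, aa, FUN = function(x) {
    if (length(x) == 1L) x else paste0(x, ".", seq_along(x))
  })
  names(fams) <- ids
  fams[order(names(fams))]
}
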