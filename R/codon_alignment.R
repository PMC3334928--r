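# In-frame codon alignment container and file I/O.

#' In-frame codon alignment
#'
#' A light container for one gene region: an aligned matrix of single
#' characters over the DNA + IUPAC + gap/missing alphabet, with unique taxon
#' labels and a length divisible by three (frame assertion).
#'
#' @param x either a character matrix (rows = taxa, one column per site,
#'   rownames = taxon labels) or a named character vector of equal-length
#'   sequence strings.
#' @param gene gene label (single string).
#' @return An object of class `codon_alignment` with fields `taxa`, `mat`
#'   (character matrix) and `gene`.
#' @export
codon_alignment <- function(x, gene = "gene") {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) stop("sequences must be named by taxon")
    n <- unique(nchar(x))
    if (length(n) != 1L) stop("all sequences must have equal length")
    mat <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(mat) <- names(x)
    x <- mat
  }
  if (!is.matrix(x) || !is.character(x)) stop("x must be a character matrix")
  if (is.null(rownames(x))) stop("alignment matrix must have taxon rownames")
  if (anyDuplicated(rownames(x))) stop("taxon labels must be unique")
  if (ncol(x) %% 3L != 0L) stop("alignment length must be divisible by 3")
  bad <- setdiff(unique(as.vector(x)), c(names(IUPAC_SETS), "-", "?"))
  if (length(bad)) stop("invalid alignment symbols: ",
                        paste(bad, collapse = ", "))
  structure(list(taxa = rownames(x), mat = x, gene = as.character(gene)[1]),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment '%s': %d taxa, %d sites (%d codons)\n",
              x$gene, length(x$taxa), ncol(x$mat), ncol(x$mat) %/% 3L))
  invisible(x)
}

#' @export
as.matrix.codon_alignment <- function(x, ...) x$mat

#' Number of alignment columns
#' @param x a `codon_alignment` or `supermatrix`.
#' @return Integer site count.
#' @export
n_sites <- function(x) ncol(x$mat)

#' Sequences as strings
#' @param x a `codon_alignment` or `supermatrix`.
#' @return Named character vector of sequence strings.
#' @export
sequence_strings <- function(x) {
  s <- apply(x$mat, 1L, paste, collapse = "")
  names(s) <- x$taxa
  s
}

#' Read a codon alignment from FASTA
#'
#' @param file path to an (uncompressed) FASTA file.
#' @param gene gene label; defaults to the file name without extension.
#' @return A [codon_alignment()].
#' @export
read_codon_fasta <- function(file, gene = NULL) {
  if (is.null(gene)) gene <- sub("\\.[^.]*$", "", basename(file))
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", file)
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")
  }, "")
  names(seqs) <- sub("^>\\s*", "", lines[hdr])
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  codon_alignment(seqs, gene = gene)
}

#' Write an alignment to FASTA
#'
#' @param x a `codon_alignment` or `supermatrix`.
#' @param file output path.
#' @param missing_as symbol to write for missing data (`?` cells); FASTA
#'   consumers often expect `N`, which is the default here.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(x, file, missing_as = "N") {
  s <- sequence_strings(x)
  if (!identical(missing_as, "?")) s <- gsub("?", missing_as, s, fixed = TRUE)
  out <- character(2L * length(s))
  out[c(TRUE, FALSE)] <- paste0(">", names(s))
  out[c(FALSE, TRUE)] <- s
  writeLines(out, file)
  invisible(file)
}

#' Write an alignment in relaxed PHYLIP format
#'
#' Relaxed sequential PHYLIP: a header line with taxon and site counts, then
#' one `label<whitespace>sequence` line per taxon (labels of any length, no
#' 10-character truncation). Missing cells are written as `?`.
#'
#' @param x a `codon_alignment` or `supermatrix`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_phylip <- function(x, file) {
  s <- sequence_strings(x)
  pad <- max(nchar(names(s))) + 2L
  writeLines(c(sprintf(" %d %d", length(s), n_sites(x)),
               sprintf("%-*s%s", pad, names(s), s)), file)
  invisible(file)
}

#' Read a relaxed PHYLIP alignment
#'
#' @param file path to a sequential relaxed PHYLIP file.
#' @param gene gene label; defaults to the file name without extension.
#' @return A [codon_alignment()].
#' @export
read_phylip <- function(file, gene = NULL) {
  if (is.null(gene)) gene <- sub("\\.[^.]*$", "", basename(file))
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  hd <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  body <- strsplit(trimws(lines[-1]), "\\s+")
  seqs <- vapply(body, function(p) paste(p[-1], collapse = ""), "")
  names(seqs) <- vapply(body, `[`, "", 1L)
  if (length(seqs) != hd[1] || any(nchar(seqs) != hd[2])) {
    stop("PHYLIP header does not match records in ", file)
  }
  codon_alignment(seqs, gene = gene)
}
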