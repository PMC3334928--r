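# Supermatrix assembly: concatenation of gene alignments over a shared taxon
# set, taxon-by-gene presence designs, exclusion masks, matrix statistics.

#' Concatenate gene alignments into a supermatrix
#'
#' Genes are laid end to end in input order. Cells for taxa absent from a
#' gene are filled with the missing symbol `?`; the taxon-by-gene presence
#' matrix distinguishes deliberate whole-gene absence from gappy-but-present
#' sequence. Column codon positions (nt1/nt2/nt3) are tracked so partition
#' construction survives masking.
#'
#' @param alignments list of [codon_alignment()] objects with unique gene
#'   labels.
#' @param taxa optional ordered taxon labels; defaults to the union of the
#'   per-gene taxa in order of first appearance.
#' @return An object of class `supermatrix` with fields `taxa`, `mat`,
#'   `gene_blocks` (named list of `c(start, end)` 1-based inclusive column
#'   ranges), `presence` (logical taxa x genes matrix) and `codon_pos`
#'   (integer vector, the codon position of every column).
#' @export
concatenate_genes <- function(alignments, taxa = NULL) {
  genes <- vapply(alignments, function(a) a$gene, "")
  if (anyDuplicated(genes)) stop("duplicate gene labels")
  if (is.null(taxa)) {
    taxa <- unique(unlist(lapply(alignments, function(a) a$taxa)))
  } else {
    extra <- setdiff(unique(unlist(lapply(alignments, function(a) a$taxa))),
                     taxa)
    if (length(extra)) stop("alignment taxa not in 'taxa': ",
                            paste(extra, collapse = ", "))
  }
  lens <- vapply(alignments, n_sites, 1L)
  total <- sum(lens)
  mat <- matrix("?", nrow = length(taxa), ncol = total,
                dimnames = list(taxa, NULL))
  presence <- matrix(FALSE, nrow = length(taxa), ncol = length(genes),
                     dimnames = list(taxa, genes))
  blocks <- vector("list", length(genes))
  names(blocks) <- genes
  at <- 0L
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    if (lens[i] > 0L) {
      mat[a$taxa, at + seq_len(lens[i])] <- a$mat
    }
    presence[a$taxa, i] <- TRUE
    blocks[[i]] <- c(start = at + 1L, end = at + lens[i])
    at <- at + lens[i]
  }
  new_supermatrix(taxa, mat, blocks, presence)
}

# internal constructor; codon_pos defaults to 1,2,3 tiling per block
new_supermatrix <- function(taxa, mat, blocks, presence, codon_pos = NULL) {
  if (is.null(codon_pos) || length(codon_pos) != ncol(mat)) {
    codon_pos <- integer(ncol(mat))
    for (b in blocks) if (b["end"] >= b["start"]) {
      codon_pos[b["start"]:b["end"]] <- rep_len(1:3, b["end"] - b["start"] + 1L)
    }
  }
  structure(list(taxa = taxa, mat = mat, gene_blocks = blocks,
                 presence = presence, codon_pos = codon_pos),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("supermatrix: %d taxa, %d genes, %d sites\n",
              length(x$taxa), length(x$gene_blocks), ncol(x$mat)))
  invisible(x)
}

#' Restrict a supermatrix to a subset of genes
#'
#' Retains only the requested gene blocks (in matrix order), remapping
#' coordinates; used e.g. to carve the five-gene complete matrix out of the
#' full deliberately incomplete matrix.
#'
#' @param matrix a `supermatrix`.
#' @param genes character vector of gene labels to keep.
#' @return A `supermatrix`.
#' @export
subset_matrix <- function(matrix, genes) {
  unknown <- setdiff(genes, names(matrix$gene_blocks))
  if (length(unknown)) stop("unknown gene labels: ",
                            paste(unknown, collapse = ", "))
  keep <- names(matrix$gene_blocks)[names(matrix$gene_blocks) %in% genes]
  cols <- integer(0)
  blocks <- list()
  at <- 0L
  for (g in keep) {
    b <- matrix$gene_blocks[[g]]
    len <- b[["end"]] - b[["start"]] + 1L
    if (b[["end"]] >= b[["start"]]) cols <- c(cols, b[["start"]]:b[["end"]]) else len <- 0L
    blocks[[g]] <- c(start = at + 1L, end = at + len)
    at <- at + len
  }
  new_supermatrix(matrix$taxa,
                  matrix$mat[, cols, drop = FALSE],
                  blocks,
                  matrix$presence[, keep, drop = FALSE],
                  codon_pos = matrix$codon_pos[cols])
}

#' Exclusion mask over alignment columns
#'
#' @param start,end integer vectors of 1-based inclusive column ranges.
#' @param note provenance note.
#' @return An object of class `exclusion_mask` (a data frame of sorted,
#'   non-overlapping intervals).
#' @export
exclusion_mask <- function(start = integer(0), end = integer(0), note = "") {
  stopifnot(length(start) == length(end))
  m <- data.frame(start = as.integer(start), end = as.integer(end))
  m <- m[order(m$start), , drop = FALSE]
  if (any(m$end < m$start)) stop("mask interval with end < start")
  if (nrow(m) > 1L && any(m$start[-1] <= m$end[-nrow(m)])) {
    stop("mask intervals overlap")
  }
  structure(m, class = c("exclusion_mask", "data.frame"), note = note)
}

#' Read an exclusion mask from plain text or a NEXUS EXSET line
#'
#' Accepts either one `start-end` (or single-column) range per line, or a
#' NEXUS-style `EXSET ... = 12-15 40 100-144;` statement. All coordinates
#' are 1-based inclusive.
#'
#' @param file path to the mask file.
#' @return An [exclusion_mask()].
#' @export
read_mask <- function(file) {
  txt <- paste(readLines(file), collapse = " ")
  if (grepl("exset", txt, ignore.case = TRUE)) {
    txt <- sub(".*=", "", txt)
    txt <- sub(";.*", "", txt)
  }
  toks <- regmatches(txt, gregexpr("[0-9]+(-[0-9]+)?", txt))[[1]]
  if (!length(toks)) return(exclusion_mask())
  parts <- strsplit(toks, "-", fixed = TRUE)
  start <- as.integer(vapply(parts, `[`, "", 1L))
  end <- as.integer(vapply(parts, function(p) p[length(p)], ""))
  exclusion_mask(start, end, note = file)
}

#' Apply an exclusion mask to a supermatrix
#'
#' Masked columns are removed; gene-block coordinates and per-column codon
#' positions are remapped. Masking precedes noLR detection and partition
#' building, so partitions are always built on the analysis matrix.
#'
#' @param matrix a `supermatrix`.
#' @param mask an [exclusion_mask()].
#' @return A list with elements `matrix` (the masked `supermatrix`) and
#'   `stats` (excluded count, total columns, percentage excluded rounded to
#'   one decimal).
#' @export
apply_mask <- function(matrix, mask) {
  total <- ncol(matrix$mat)
  drop <- logical(total)
  for (i in seq_len(nrow(mask))) {
    if (mask$start[i] < 1L || mask$end[i] > total) {
      stop("mask interval out of bounds: ", mask$start[i], "-", mask$end[i])
    }
    drop[mask$start[i]:mask$end[i]] <- TRUE
  }
  keep <- which(!drop)
  blocks <- list()
  at <- 0L
  for (g in names(matrix$gene_blocks)) {
    b <- matrix$gene_blocks[[g]]
    len <- if (b["end"] >= b["start"]) sum(!drop[b["start"]:b["end"]]) else 0L
    blocks[[g]] <- c(start = at + 1L, end = at + len)
    at <- at + len
  }
  sm <- new_supermatrix(matrix$taxa, matrix$mat[, keep, drop = FALSE],
                        blocks, matrix$presence,
                        codon_pos = matrix$codon_pos[keep])
  stats <- list(excluded = sum(drop), total = total,
                percent = round(100 * sum(drop) / max(total, 1L), 1))
  list(matrix = sm, stats = stats)
}

#' Supermatrix tallies
#'
#' @param matrix a `supermatrix`.
#' @return A list: `n_taxa`, `n_genes`, `total_sites`, `sites_per_gene`,
#'   `percent_missing_cells` (taxon-by-gene absences) and
#'   `percent_missing_characters` (`?` cells over taxa x sites).
#' @export
matrix_stats <- function(matrix) {
  lens <- vapply(matrix$gene_blocks,
                 function(b) max(0L, b[["end"]] - b[["start"]] + 1L), 1L)
  ncell <- length(matrix$presence)
  nchar_total <- length(matrix$mat)
  list(
    n_taxa = length(matrix$taxa),
    n_genes = length(matrix$gene_blocks),
    total_sites = ncol(matrix$mat),
    sites_per_gene = lens,
    percent_missing_cells =
      if (ncell) 100 * sum(!matrix$presence) / ncell else 0,
    percent_missing_characters =
      if (nchar_total) 100 * sum(matrix$mat == "?") / nchar_total else 0
  )
}

#' Read/write a taxon-by-gene presence design as TSV
#'
#' The design is a 0/1 table with taxa as rows and genes as columns.
#'
#' @param design logical taxa x genes matrix with dimnames.
#' @param file path.
#' @return `read_presence_design` returns the logical matrix.
#' @export
write_presence_design <- function(design, file) {
  df <- data.frame(taxon = rownames(design),
                   design * 1L, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_presence_design
#' @export
read_presence_design <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE]) == 1
  rownames(m) <- df[[1]]
  validate_presence_design(m)
  m
}

#' Validate a presence design
#'
#' Every taxon must be present for at least one gene and every gene for at
#' least four taxa (the minimum for an informative unrooted quartet).
#'
#' @param design logical taxa x genes matrix.
#' @return The design, invisibly; errors if the invariants fail.
#' @export
validate_presence_design <- function(design) {
  if (any(rowSums(design) < 1L)) {
    stop("presence design: some taxa are present for no gene")
  }
  if (any(colSums(design) < 4L)) {
    stop("presence design: every gene needs at least 4 taxa")
  }
  invisible(design)
}

#' Export a supermatrix as a NEXUS file with charsets
#'
#' Writes a DATA block plus a SETS block holding one `charset` per gene and,
#' when a partition scheme is supplied, one per character partition
#' (coordinates 1-based inclusive, as NEXUS requires).
#'
#' @param matrix a `supermatrix`.
#' @param file output path.
#' @param scheme optional [build_partitions()] result.
#' @return `file`, invisibly.
#' @export
write_nexus <- function(matrix, file, scheme = NULL) {
  s <- sequence_strings(matrix)
  pad <- max(nchar(names(s))) + 2L
  lines <- c(
    "#NEXUS", "",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(s), ncol(matrix$mat)),
    "  FORMAT DATATYPE=DNA MISSING=? GAP=-;",
    "  MATRIX",
    sprintf("    %-*s%s", pad, names(s), s),
    "  ;", "END;", "",
    "BEGIN SETS;"
  )
  for (g in names(matrix$gene_blocks)) {
    b <- matrix$gene_blocks[[g]]
    if (b["end"] >= b["start"]) {
      lines <- c(lines, sprintf("  CHARSET %s = %d-%d;", g,
                                b[["start"]], b[["end"]]))
    }
  }
  if (!is.null(scheme)) {
    for (p in names(scheme)) {
      lines <- c(lines, sprintf("  CHARSET %s = %s;", p,
                                compact_ranges(scheme[[p]])))
    }
  }
  lines <- c(lines, "END;")
  writeLines(lines, file)
  invisible(file)
}

# collapse a sorted integer vector into NEXUS-style "a-b c d-e" ranges
compact_ranges <- function(idx) {
  if (!length(idx)) return("")
  idx <- sort(idx)
  brk <- c(0L, which(diff(idx) != 1L), length(idx))
  paste(vapply(seq_len(length(brk) - 1L), function(i) {
    a <- idx[brk[i] + 1L]; b <- idx[brk[i + 1L]]
    if (a == b) as.character(a) else paste0(a, "-", b)
  }, ""), collapse = " ")
}
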