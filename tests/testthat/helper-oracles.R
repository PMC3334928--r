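# Independent brute-force oracles used to verify the implementation paths.

# --- IUPAC machinery, written independently of the package's tables -------

.orc_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

orc_union_code <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  for (nm in names(.orc_iupac)) {
    if (paste(sort(.orc_iupac[[nm]]), collapse = "") == key) return(nm)
  }
  stop("no IUPAC code for ", key)
}

orc_expand_codon <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  sets <- lapply(ch, function(x) .orc_iupac[[x]])
  out <- character(0)
  for (a in sets[[1]]) for (b in sets[[2]]) for (cc in sets[[3]]) {
    out <- c(out, paste0(a, b, cc))
  }
  out
}

# authoritative code table from Biostrings (independent of the package's
# shipped TSV)
orc_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

# --- degen1 oracle: BFS closure over synonymous single-nucleotide steps ---

orc_degen1_table <- function() {
  code <- orc_code()
  sense <- names(code)[code != "*"]
  nucs <- c("A", "C", "G", "T")
  out <- character(0)
  for (cd in sense) {
    # transitive closure of synonymous single-nucleotide changes
    closure <- cd
    frontier <- cd
    while (length(frontier)) {
      nxt <- character(0)
      for (f in frontier) {
        ch <- strsplit(f, "")[[1]]
        for (pos in 1:3) for (b in nucs) {
          cand <- ch
          cand[pos] <- b
          cand <- paste(cand, collapse = "")
          if (cand != f && code[cand] == code[f] && code[cand] != "*" &&
              !(cand %in% closure)) {
            closure <- c(closure, cand)
            nxt <- c(nxt, cand)
          }
        }
      }
      frontier <- nxt
    }
    m <- do.call(rbind, strsplit(closure, ""))
    out[cd] <- paste0(orc_union_code(m[, 1]), orc_union_code(m[, 2]),
                      orc_union_code(m[, 3]))
  }
  out
}

# --- likelihood oracle: exhaustive enumeration of internal-node states ----

orc_loglik <- function(tree, mat, model) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  n_int <- tr$Nnode
  eig <- gtr_eigen(model)
  mix <- gamma_invariant_mixture(model)
  el <- pmax(tr$edge.length, 1e-8)
  root <- tr$edge[nrow(tr$edge), 1]
  perm <- match(tr$tip.label, rownames(mat))
  combos <- as.matrix(expand.grid(rep(list(1:4), n_int)))
  total <- 0
  for (site in seq_len(ncol(mat))) {
    allowed <- lapply(seq_len(ntip), function(t)
      match(.orc_iupac[[mat[perm[t], site]]] %||% c("A", "C", "G", "T"),
            c("A", "C", "G", "T")))
    sitelik <- 0
    for (c in seq_along(mix$rates)) {
      Ps <- lapply(seq_len(nrow(tr$edge)), function(e)
        pmat(eig, el[e] * mix$rates[c]))
      Lc <- 0
      for (k in seq_len(nrow(combos))) {
        states <- integer(ntip + n_int)
        states[ntip + seq_len(n_int)] <- combos[k, ]
        p <- model$base_freq[states[root]]
        for (e in seq_len(nrow(tr$edge))) {
          par <- states[tr$edge[e, 1]]
          ch <- tr$edge[e, 2]
          p <- p * if (ch <= ntip) {
            sum(Ps[[e]][par, allowed[[ch]]])
          } else {
            Ps[[e]][par, states[ch]]
          }
          if (p == 0) break
        }
        Lc <- Lc + p
      }
      sitelik <- sitelik + mix$weights[c] * Lc
    }
    total <- total + log(sitelik)
  }
  total
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- random fixtures -------------------------------------------------------

# random unrooted tree with n leaves (trifurcating root), random lengths
orc_random_tree <- function(n, min_bl = 0.02, max_bl = 0.6) {
  tr <- ape::rtree(n, rooted = FALSE, tip.label = sprintf("t%02d", 1:n))
  tr$edge.length <- stats::runif(nrow(tr$edge), min_bl, max_bl)
  tr
}

orc_random_model <- function() {
  f <- stats::runif(4, 0.1, 1)
  subst_model(rates = stats::runif(6, 0.3, 3), base_freq = f / sum(f),
              alpha = stats::runif(1, 0.3, 3),
              p_inv = stats::runif(1, 0, 0.4), k = 4L)
}

# random character matrix over an alphabet, rows named by taxa
orc_random_matrix <- function(taxa, n_sites,
                              alphabet = c("A", "C", "G", "T")) {
  matrix(sample(alphabet, length(taxa) * n_sites, replace = TRUE),
         nrow = length(taxa), dimnames = list(taxa, NULL))
}

# random in-frame alignment of sense codons
orc_random_codon_alignment <- function(n_taxa, n_codons, gene = "g") {
  code <- orc_code()
  sense <- names(code)[code != "*"]
  taxa <- sprintf("t%02d", seq_len(n_taxa))
  seqs <- vapply(taxa, function(t)
    paste(sample(sense, n_codons, replace = TRUE), collapse = ""), "")
  codon_alignment(seqs, gene = gene)
}
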