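# Codon-alignment simulation: a two-layer process (a slow amino-acid chain
# plus a fast within-family synonymous chain) that concentrates
# base-compositional heterogeneity at synonymously variable sites, the
# signal structure the degen1/partitioning machinery is designed to handle.

#' Simulation configuration
#'
#' @param n_codons_per_gene integer vector, codons per gene.
#' @param tree_shape_seed,sequence_seed integer seeds for the tree and
#'   sequence layers.
#' @param branch_length_scale positive mean edge length (codon-change events
#'   per codon site).
#' @param gamma_shape shape of the discrete gamma distribution of
#'   among-site rate multipliers (4 categories, category means).
#' @param p_invariant proportion of invariant sites, in `[0, 1)`.
#' @param gtr_exchangeabilities six positive GTR exchangeabilities (used by
#'   the site-level GTR simulator, [simulate_gtr_sites()]).
#' @param base_frequencies four frequencies (sum 1): the stationary
#'   composition of the synonymous chain on ordinary lineages.
#' @param synonymous_rate_multiplier rate of synonymous codon change
#'   relative to amino-acid change (0 switches the synonymous layer off).
#' @param composition_shift_taxa taxon labels whose lineages use the
#'   alternative synonymous-site composition.
#' @param composition_shift_frequencies four frequencies (sum 1) for the
#'   shifted lineages.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_codons_per_gene = c(200L),
                              tree_shape_seed = 1L,
                              sequence_seed = 2L,
                              branch_length_scale = 0.1,
                              gamma_shape = 0.8,
                              p_invariant = 0.2,
                              gtr_exchangeabilities = c(1, 4, 1, 1, 4, 1),
                              base_frequencies = rep(0.25, 4),
                              synonymous_rate_multiplier = 5,
                              composition_shift_taxa = character(0),
                              composition_shift_frequencies = rep(0.25, 4)) {
  stopifnot(all(n_codons_per_gene >= 1L),
            branch_length_scale > 0,
            gamma_shape > 0,
            p_invariant >= 0, p_invariant < 1,
            all(gtr_exchangeabilities > 0),
            length(gtr_exchangeabilities) == 6L,
            length(base_frequencies) == 4L,
            length(composition_shift_frequencies) == 4L,
            synonymous_rate_multiplier >= 0)
  if (abs(sum(base_frequencies) - 1) > 1e-9 ||
      abs(sum(composition_shift_frequencies) - 1) > 1e-9) {
    stop("frequencies must sum to 1")
  }
  structure(list(
    n_codons_per_gene = as.integer(n_codons_per_gene),
    tree_shape_seed = as.integer(tree_shape_seed),
    sequence_seed = as.integer(sequence_seed),
    branch_length_scale = branch_length_scale,
    gamma_shape = gamma_shape,
    p_invariant = p_invariant,
    gtr_exchangeabilities = gtr_exchangeabilities,
    base_frequencies = base_frequencies,
    synonymous_rate_multiplier = synonymous_rate_multiplier,
    composition_shift_taxa = as.character(composition_shift_taxa),
    composition_shift_frequencies = composition_shift_frequencies
  ), class = "simulation_config")
}

# discrete gamma (category means) + invariant-site mass; returns per-site
# rate multipliers for n sites
.draw_site_rates <- function(n, shape, p_inv, k = 4L) {
  rates <- discrete_gamma_rates(shape, k)
  cat <- sample.int(k, n, replace = TRUE)
  r <- rates[cat]
  r[stats::runif(n) < p_inv] <- 0
  r
}

# per-family bookkeeping for the two-layer codon process
.codon_machine <- function(code = standard_genetic_code()) {
  fams <- synonymous_families(code)
  sense <- names(code)[code != "*"]
  fam_of <- integer(length(sense)); names(fam_of) <- sense
  for (i in seq_along(fams)) fam_of[fams[[i]]] <- i
  canonical <- vapply(fams, function(f) sort(f)[1], "")
  list(fams = fams, sense = sense, fam_of = fam_of, canonical = canonical,
       members = lapply(fams, function(f) match(f, sense)))
}

# within-family codon weights under a base composition (product over the
# codon's three positions)
.family_weights <- function(machine, freqs) {
  names(freqs) <- NUC
  lapply(machine$fams, function(f) {
    ch <- do.call(rbind, strsplit(f, ""))
    w <- freqs[ch[, 1]] * freqs[ch[, 2]] * freqs[ch[, 3]]
    w / sum(w)
  })
}

#' Simulate an in-frame codon alignment on a tree
#'
#' Codon sites evolve by a two-layer Markov process. The amino-acid layer
#' jumps between the 21 synonymous codon families (serine contributes two)
#' at relative rate 1; arrival is at the family's canonical (alphabetically
#' first) codon. The synonymous layer resamples the codon within the
#' current family at relative rate `synonymous_rate_multiplier`, with
#' stationary weights given by the lineage's base composition - the normal
#' `base_frequencies`, or `composition_shift_frequencies` on every edge
#' whose descendant leaves all belong to `composition_shift_taxa`. Per-site
#' rate multipliers come from a 4-category discrete gamma (category means)
#' with an invariant-site mass `p_invariant`. Stop codons are unreachable by
#' construction.
#'
#' @param tree a `phylo` tree whose tip labels name the taxa.
#' @param config a [simulation_config()].
#' @param gene_index which entry of `n_codons_per_gene` to simulate; the
#'   sequence seed is offset by the gene index so genes are independent but
#'   jointly reproducible.
#' @return A [codon_alignment()] with `3 * n_codons` columns; the root
#'   codon sequence is attached as attribute `root_codons`.
#' @export
simulate_codon_alignment <- function(tree, config, gene_index = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (gene_index < 1L || gene_index > length(config$n_codons_per_gene)) {
    stop("gene_index out of range")
  }
  extra <- setdiff(config$composition_shift_taxa, tree$tip.label)
  if (length(extra)) {
    stop("composition_shift_taxa not in tree: ", paste(extra, collapse = ", "))
  }
  n_cod <- config$n_codons_per_gene[gene_index]
  set.seed(config$sequence_seed + 1000L * (gene_index - 1L))

  machine <- .codon_machine()
  w_base <- .family_weights(machine, config$base_frequencies)
  w_shift <- .family_weights(machine, config$composition_shift_frequencies)
  n_fam <- length(machine$fams)
  canon_idx <- match(machine$canonical, machine$sense)

  m <- config$synonymous_rate_multiplier
  p_syn <- m / (1 + m)

  rates <- .draw_site_rates(n_cod, config$gamma_shape, config$p_invariant)

  # root: uniform family, canonical codon
  root <- canon_idx[sample.int(n_fam, n_cod, replace = TRUE)]

  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  # which edges sit inside an all-shifted clade
  is_shift_tip <- tr$tip.label %in% config$composition_shift_taxa
  all_shifted <- rep(TRUE, nnode)
  all_shifted[seq_len(ntip)] <- is_shift_tip
  for (e in seq_len(nrow(tr$edge))) { # postorder: children first
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    all_shifted[p] <- all_shifted[p] && all_shifted[ch]
  }
  states <- matrix(NA_integer_, nrow = nnode, ncol = n_cod)
  rootnode <- ntip + 1L
  states[rootnode, ] <- root

  evolve_site <- function(st, n_ev, weights) {
    for (k in seq_len(n_ev)) {
      if (stats::runif(1) < p_syn) {
        fam <- machine$fam_of[[st]]
        mem <- machine$members[[fam]]
        if (length(mem) > 1L) {
          st <- mem[sample.int(length(mem), 1L, prob = weights[[fam]])]
        }
      } else {
        fam <- machine$fam_of[[st]]
        newfam <- sample.int(n_fam - 1L, 1L)
        if (newfam >= fam) newfam <- newfam + 1L
        st <- canon_idx[newfam]
      }
    }
    st
  }

  for (e in rev(seq_len(nrow(tr$edge)))) { # preorder: parents first
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    t_e <- tr$edge.length[e]
    st <- states[p, ]
    n_ev <- stats::rpois(n_cod, t_e * rates)
    hit <- which(n_ev > 0L)
    if (length(hit)) {
      w <- if (all_shifted[ch]) w_shift else w_base
      for (i in hit) st[i] <- evolve_site(st[i], n_ev[i], w)
    }
    states[ch, ] <- st
  }

  codons <- machine$sense[t(states[seq_len(ntip), , drop = FALSE])]
  seqs <- vapply(seq_len(ntip), function(i) {
    paste(codons[(i - 1L) * n_cod + seq_len(n_cod)], collapse = "")
  }, "")
  names(seqs) <- tr$tip.label
  aln <- codon_alignment(seqs[tree$tip.label],
                         gene = paste0("gene", gene_index))
  attr(aln, "root_codons") <- machine$sense[root]
  attr(aln, "site_rates") <- rates
  aln
}

#' Apply a taxon-by-gene presence design to per-gene alignments
#'
#' For every absent taxon-by-gene cell, the taxon's whole row in that gene
#' is replaced by the missing symbol `?`; present cells are untouched.
#'
#' @param alignments list of [codon_alignment()] objects.
#' @param design logical taxa x genes matrix (see
#'   [validate_presence_design()]).
#' @return List of [codon_alignment()] objects.
#' @export
apply_presence_design <- function(alignments, design) {
  validate_presence_design(design)
  lapply(alignments, function(a) {
    if (!a$gene %in% colnames(design)) {
      stop("gene ", a$gene, " not in design")
    }
    missing_taxa <- setdiff(a$taxa, rownames(design))
    if (length(missing_taxa)) {
      stop("taxa not in design: ", paste(missing_taxa, collapse = ", "))
    }
    absent <- a$taxa[!design[a$taxa, a$gene]]
    if (length(absent)) a$mat[absent, ] <- "?"
    a
  })
}

#' Block-missing presence design
#'
#' The deliberately incomplete sampling pattern: the first `n_full` taxa are
#' present for every gene, the remaining taxa only for the core genes.
#'
#' @param taxa,genes ordered labels.
#' @param n_full number of taxa sequenced for the full gene set.
#' @param core_genes labels of the genes sequenced in all taxa.
#' @return Logical taxa x genes matrix.
#' @export
block_presence_design <- function(taxa, genes, n_full,
                                  core_genes = genes[1:5]) {
  stopifnot(n_full >= 0L, n_full <= length(taxa),
            all(core_genes %in% genes))
  m <- matrix(FALSE, length(taxa), length(genes),
              dimnames = list(taxa, genes))
  m[, core_genes] <- TRUE
  if (n_full > 0L) m[seq_len(n_full), ] <- TRUE
  validate_presence_design(m)
}

#' Simulate nucleotide sites on a tree under GTR+gamma+I
#'
#' Site-level companion to the codon simulator, used for model-recovery and
#' search checks: independent sites evolve under the same GTR+gamma+I
#' process the inference machinery fits.
#'
#' @param tree a `phylo` tree.
#' @param model a [subst_model()].
#' @param n_sites number of sites (a multiple of 3, so the result is a
#'   valid in-frame alignment container).
#' @param seed integer RNG seed.
#' @param gene gene label for the returned alignment.
#' @return A [codon_alignment()].
#' @export
simulate_gtr_sites <- function(tree, model, n_sites, seed = 1L,
                               gene = "gtr_sim") {
  stopifnot(n_sites %% 3L == 0L)
  set.seed(as.integer(seed))
  eig <- gtr_eigen(model)
  mix <- gamma_invariant_mixture(model)
  cat <- sample.int(length(mix$rates), n_sites, replace = TRUE,
                    prob = mix$weights)
  r <- mix$rates[cat]
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  states <- matrix(NA_integer_, nrow = nnode, ncol = n_sites)
  states[ntip + 1L, ] <- sample.int(4L, n_sites, replace = TRUE,
                                    prob = model$base_freq)
  for (e in rev(seq_len(nrow(tr$edge)))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    st <- states[p, ]
    for (cc in unique(cat)) {
      idx <- which(cat == cc)
      rate <- mix$rates[cc]
      if (rate == 0) next
      P <- pmat(eig, tr$edge.length[e] * rate)
      for (s in 1:4) {
        ii <- idx[st[idx] == s]
        if (length(ii)) {
          states[ch, ii] <- sample.int(4L, length(ii), replace = TRUE,
                                       prob = P[s, ]) # vectorized per state
        }
      }
    }
    zero <- which(cat %in% which(mix$rates == 0))
    states[ch, zero] <- st[zero]
  }
  mat <- matrix(NUC[states[seq_len(ntip), , drop = FALSE]], nrow = ntip,
                dimnames = list(tr$tip.label, NULL))
  codon_alignment(mat[tree$tip.label, , drop = FALSE], gene = gene)
}
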