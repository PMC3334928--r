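---
title: "Codon-aware recoding, incomplete supermatrices and desk-scale likelihood phylogenetics"
author: "phylodegen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-aware recoding, incomplete supermatrices and desk-scale likelihood phylogenetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylodegen)
library(ape)
```

## The problem this package addresses

Multi-gene phylogenies of protein-coding nuclear genes face a specific
nuisance: sites that can change synonymously evolve fast and are prone to
among-lineage base-compositional heterogeneity. Lineages that drift toward
different synonymous-site compositions can be drawn together by that
composition rather than by shared ancestry, obscuring or actively
misleading inference. Two complementary remedies are implemented here:

* **Partitioning** the matrix into a set of sites carrying essentially
  only non-synonymous change and a set carrying the potentially synonymous
  change, so the fast heterogeneous component is modelled separately; and
* **degen1 recoding**, which degenerates every codon position capable of
  synonymous change to the IUPAC code spanning its synonymous family, so
  synonymous differences become invisible to inference altogether.

Around these sit the rest of a practical pipeline: supermatrix assembly
under deliberately incomplete taxon-by-gene sampling designs, exclusion
masks, partitioned GTR+Γ+I maximum-likelihood tree search with
nonparametric bootstrap, cross-analysis support comparison including a
missing-data-artifact check, and a diet-breadth (oligophagy/polyphagy)
classifier for host-association record tables. A synthetic-data module
generates every input with known truth, so the whole chain is testable
without any sequence downloads.

## Character recoding and partitioning

### degen1

Two sense codons belong to one *synonymous family* when a chain of
single-nucleotide substitutions connects them without ever changing the
amino acid. Under the standard nuclear code this closure yields 21
families: one per amino acid, except that serine splits into its TCN
(4-fold) and AGY (2-fold) families, which no single-nucleotide synonymous
step connects. The degen1 image of a codon replaces each position with the
IUPAC union of the family's states at that position: CAC and CAT (His)
both become CAY; all six leucine codons become YTN; ATG (Met) and TGG
(Trp) are untouched. Serine's two families keep distinct images (TCN,
AGY), so a Ser1↔Ser2 difference — which necessarily involved a
non-synonymous step — remains visible.

Note a small but deliberate asymmetry: the image is a *positionwise*
union, so for leucine and arginine the expansion of the image (YTN, MGN)
also covers a few codons of other amino acids (YTN contains TTT = Phe).
This is inherent to the published coding scheme; what the recoding
guarantees is that all members of a family share one image, i.e. that
synonymous differences contribute nothing to pairwise sequence
differences. The test suite verifies the full 64-codon table against an
independent brute-force closure oracle, plus idempotence and
amino-acid preservation on random alignments.

Ambiguity codes in input data are recoded as the IUPAC union of the
degen1 images of their sense expansions. In-frame stop codons follow a
configurable policy: the default lenient policy replaces them with `NNN`
and warns (real alignments contain occasional artifacts), the strict
policy fails. Ambiguous codons whose expansions include stops simply drop
the stop expansions from the union; only a codon expanding *exclusively*
to stops triggers the policy. How the original implementations handled
ambiguous codons is not documented anywhere we know of; the rule above is
this package's own, conservative, documented choice.

### The noLR filter and the two-partition scheme

Only leucine and arginine codons can change synonymously at the first
codon position (CTN/TTR and CGN/AGR). First-position sites in codon
columns where *no* taxon carries a codon compatible with Leu or Arg
therefore cannot contain synonymous signal. `find_noLR_nt1_sites()`
treats a codon as Leu/Arg-compatible if *any* IUPAC expansion translates
to Leu or Arg (conservative: a site is only admitted when synonymous
change is undetectable for every species); gap/missing codons never count.

`build_partitions()` then forms

* `nonsyn_nt1_nt2` = (noLR nt1 sites) ∪ (all nt2 sites) — essentially
  non-synonymous change only;
* `potsyn_nt1_nt3` = (remaining nt1 sites) ∪ (all nt3 sites) — the
  potentially synonymous remainder.

The two sets are disjoint and tile all unmasked columns; this is asserted
at construction time and property-tested on random matrices.

Exclusion masks are applied *before* noLR detection and partition
building, so partitions always describe the analysis matrix. Columns
removed from inside a codon leave the survivors evaluated with `N` at the
masked positions, which under the conservative rule sends the codon's
surviving nt1 site to the potentially synonymous partition. Coordinates
are 1-based inclusive throughout (the R convention, and what NEXUS
`charset`/`EXSET` blocks use).

## Supermatrices and deliberately incomplete designs

`concatenate_genes()` lays gene blocks end to end over a shared taxon
list, filling absent taxon-by-gene cells with `?`. Deliberate whole-gene
absence is recorded in a taxon-by-gene presence matrix, distinct from
gappy-but-present sequence: the missing-data-artifact analysis is about
*block* absence by design, not about incidental gaps.
`block_presence_design()` builds the canonical pattern — a subset of taxa
sequenced for every gene, the remainder only for a core gene set — and
`subset_matrix()` carves out the complete-matrix counterpart (e.g. the
five core genes over all taxa). Matrix statistics (`matrix_stats()`)
report sizes and the two missingness percentages (cells and characters).

## Likelihood machinery

`log_likelihood()` computes the Felsenstein pruning likelihood under
GTR+Γ+I, partition by partition, on compressed site patterns. The hot
loop is compiled (Rcpp) with per-node scaling, so matrices of tens of
taxa and thousands of sites evaluate in milliseconds. Gamma rate
variation uses 4 discrete categories represented by their category
*means* (equal-probability slices of a mean-1 gamma), and the
invariant-site class is an extra zero-rate category with weight
$p_{inv}$; gamma rates are rescaled by $1/(1-p_{inv})$ so the mixture
mean stays 1. IUPAC symbols are handled natively by summing over
compatible states — degen1-recoded matrices feed straight into the same
kernel — and `-`/`?` are fully ambiguous.

Numerical choices: branch lengths are bounded below at $10^{-8}$;
the gamma shape is bounded to $[0.02, 100]$ and $p_{inv}$ to $[0, 0.95]$
during optimization to limit ridge behaviour in the joint
$\alpha$/$p_{inv}$ profile; eigendecomposition of the reversible rate
matrix goes through the symmetrized form for stability. An all-zero
partial (impossible site) raises an explicit numerical error rather than
returning `-Inf` silently.

`optimize_parameters()` is plain coordinate ascent — Brent per branch,
Nelder-Mead (or Brent for a single parameter) over transformed model
parameters per partition, partitions sharing branch lengths with
per-partition rate multipliers — accepting only improvements, so the
likelihood trace is non-decreasing by construction.

### Tree search and bootstrap

`search_tree()` uses random-order stepwise addition (each placement
scored by full log-likelihood, ties broken by the first edge index) and
NNI hill climbing with interleaved branch-length passes. This is a
deliberate desk-scale replacement for cluster-scale stochastic searches:
the aim is correctness and reproducibility (everything is seed-driven)
on problems of tens of taxa, with search effort (`n_starts`,
`searches_per_rep`) exposed as configuration. On four taxa the search
provably returns the best of the three unrooted topologies (tested
against exhaustive evaluation); on strong-signal simulations it recovers
the generating topology.

`bootstrap_support()` resamples nucleotide columns with replacement
*within* each partition (preserving partition sizes — the standard
nonparametric bootstrap on the character matrix the model sees, not a
codon-level resample), re-searches per pseudo-replicate with model
parameters held at the values estimated once on the original matrix, and
tabulates bipartition frequencies as percents. For large matrices a
rapid-bootstrap-style shortcut is available: `start_tree` seeds every
replicate's search with the reference tree and skips stepwise addition,
leaving NNI to rearrange where the resampled data demand it. The
12-taxon recovery analysis uses full per-replicate searches; the
52-taxon artifact analysis uses the shortcut.

## Support comparison and the artifact check

Bipartitions are compared as unordered leaf-label splits (canonical key:
the side not containing the alphabetically first taxon), which makes all
comparisons invariant to rooting, rotation and input order.
`count_internal_nodes()` counts internal nodes of the rooted subtree
spanned by a clade, subtree root included — a rooted binary clade with
$n$ leaves has $n-1$ — and `threshold_fractions()` reports the fraction
of those nodes with support at or above each cutoff (70/80/90 by
default, following the convention that 70–79% is "moderate" and ≥80%
"strong" support), rounded to whole percent.

`detect_missing_data_artifacts()` operationalizes the artifact test for
deliberately incomplete designs: any split supported at or above the
strong threshold by the incomplete-matrix analysis but absent from the
complete-matrix best tree is flagged; an empty result is the no-artifact
outcome. Note the operational definition counts *absence*, not just
conflict, so it is stricter than eyeballing incompatible groups — a
reduced-matrix search too weak to resolve a true clade would be flagged.
The acceptance simulation therefore runs in a strong-signal regime where
the complete matrix is decisive on its own.

## Host-range classification

Host-association tables are entry-level: one row per (tortricid species,
plant species) association, possibly repeated across regions. Entries
(not distinct plant species) are the scoring unit — this matters because
repeated entries shift modal fractions, and it mirrors how observational
host databases are structured. The procedure is:

1. resolve plant orders from a lookup (species key, genus fallback);
   unresolved rows are flagged and excluded;
2. drop species with a single entry (a lone observation cannot attest
   oligophagy);
3. score each remaining species: modal plant order fraction ≥ 0.8
   (inclusive, so 8 of 10 entries is oligophagous) → oligophagous, else
   polyphagous;
4. summarize per tribe as `n_poly/n_scorable = p%`.

Diet breadth is defined at the plant *order* rank here; the rank is a
`classify_species()` threshold away from being family-level if a user
prefers, but order-level is the definition this package follows. Ties
for the modal order share one modal fraction, so the label is
tie-break-independent.

## The synthetic-data module

The simulators are first-class, tested code; their defaults define the
study conditions the acceptance checks run under.

* **Trees**: Yule (pure-birth, unit rate) topologies via `ape::rphylo`,
  branch lengths rescaled so the mean edge equals `branch_length_scale`.
  For strong-signal analyses the edge lengths are drawn uniformly on
  [0.1, 0.3] substitutions/site — the "long internal branches" regime in
  which search and bootstrap recovery are meaningful claims.
* **Codon alignments**: a two-layer process instead of a full 61×61
  codon model. The amino-acid layer jumps among the 21 synonymous
  families at relative rate 1, landing on the family's canonical
  (alphabetically first) codon; the synonymous layer resamples the codon
  within the current family at relative rate
  `synonymous_rate_multiplier`, with stationary weights given by the
  lineage's base composition. Edges whose descendant leaves all belong
  to `composition_shift_taxa` use the alternative composition — this
  concentrates compositional heterogeneity exactly at synonymously
  variable sites, which is the signal structure degen1 and the
  two-partition scheme exist to handle. Branch lengths are expected
  codon-change events per codon site; per-site rate multipliers come
  from the same 4-category discrete gamma + invariant-sites mixture the
  inference side fits. Stop codons are unreachable by construction (the
  chain moves within and between sense-codon families only), and the
  deterministic arrival codon makes the no-synonymous-layer regime
  exactly checkable (one amino acid ⇔ one codon). What this simulator
  does *not* emulate: indels (alignments are gap-free unless a design
  introduces missing rows), selection heterogeneity along the gene,
  codon-usage correlation between sites, or the branch lengths of any
  real data set — so passing tests demonstrate algorithmic correctness
  under the model, not robustness to everything real data do.
* **Host tables**: hidden truth labels with well-separated regimes —
  oligophagous species draw ≥ 95% of entries from a modal order
  (off-modal count capped at 3%, rounded down), polyphagous species
  spread entries over 2–3 orders with every order capped at 70%. The
  separation band (70–95%) is what makes ≥ 95% label recovery a fair
  expectation for the 80% rule; the magnitude of real-world noise is not
  calibrated to any particular database.

The compositional-heterogeneity magnitude is likewise a free parameter:
no published value quantifies it for the motivating data, so the
defaults are chosen to make the effect clearly measurable (shifted
third-position GC differing by several points) rather than to match any
empirical estimate.

## Problem sizes used by the tests and acceptance script

Chosen as comfortable desk-scale sizes: the likelihood oracle compares
pruning with exhaustive enumeration on ≤ 5-leaf trees (100 randomized
cases in the tests); search/bootstrap recovery uses 12 taxa × 1200 sites
with 100 replicates; the artifact analysis uses 52 taxa × 19 genes
(5 core genes of 40 codons, 14 further genes of 10 codons) under the
29-full/23-core design with 20 reference-start replicates; host-range
recovery uses 250 species with ≥ 10 entries each. Gamma-shape recovery
(±30%) uses 12 taxa × 6000 sites.

## Known limitations

* NNI-only rearrangements can in principle be trapped by local optima
  that SPR/TBR would escape; multiple random-addition starts are the
  provided mitigation.
* Partitioned models share branch lengths across partitions up to a
  scalar rate multiplier; fully unlinked branch lengths are out of scope.
* The bootstrap's fixed-model approximation (parameters estimated once)
  is standard practice at this scale but slightly narrows replicate
  variance relative to full re-estimation.
* The artifact check compares against a single best reduced-matrix tree;
  with weak reduced-matrix signal it flags unresolved true clades (see
  above), by design.
* No codon-model likelihoods, no RY-coding variant, no Bayesian
  inference, no model selection: the model family is fixed at GTR+Γ+I.
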