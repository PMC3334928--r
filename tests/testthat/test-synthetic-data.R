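test_that("simulated trees are binary, labelled and reproducible", {
  tr <- simulate_tree(3, seed = 1)
  expect_identical(length(tr$tip.label), 3L)
  expect_identical(tr$Nnode, 2L)  # rooted binary: n - 1 internal nodes
  expect_error(simulate_tree(2), "at least 3")
  t1 <- simulate_tree(8, seed = 7)
  t2 <- simulate_tree(8, seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(simulate_tree(20, seed = 3)$edge.length > 0))
})

test_that("a 52-leaf rooted binary tree has 51 internal nodes", {
  tr <- simulate_tree(52, seed = 11)
  expect_identical(tr$Nnode, 51L)
  expect_identical(count_internal_nodes(tr), 51L)
})

test_that("codon simulation produces sense codons only, reproducibly", {
  tr <- simulate_tree(6, seed = 2, branch_length_scale = 0.3)
  cfg <- simulation_config(n_codons_per_gene = 80L, sequence_seed = 5)
  a1 <- simulate_codon_alignment(tr, cfg)
  a2 <- simulate_codon_alignment(tr, cfg)
  expect_identical(a1$mat, a2$mat)
  code <- orc_code()
  for (t in seq_len(6)) {
    cods <- substring(sequence_strings(a1)[t], seq(1, 240, 3), seq(3, 240, 3))
    expect_true(all(code[cods] != "*"))  # no stop codons anywhere
  }
})

test_that("zero branch lengths reproduce the root sequence everywhere", {
  tr <- simulate_tree(5, seed = 3)
  tr$edge.length[] <- 0
  cfg <- simulation_config(n_codons_per_gene = 40L, sequence_seed = 9)
  a <- simulate_codon_alignment(tr, cfg)
  root <- paste(attr(a, "root_codons"), collapse = "")
  for (s in sequence_strings(a)) expect_identical(s, root)
})

test_that("without the synonymous layer, one amino acid means one codon", {
  tr <- simulate_tree(8, seed = 4, branch_length_scale = 0.4)
  cfg <- simulation_config(n_codons_per_gene = 60L, sequence_seed = 13,
                           synonymous_rate_multiplier = 0)
  a <- simulate_codon_alignment(tr, cfg)
  # with no synonymous layer the codon is a deterministic function of the
  # synonymous family: every codon is its family's canonical representative
  canon <- vapply(synonymous_families(), function(f) sort(f)[1], "")
  for (j in seq_len(60)) {
    cods <- apply(a$mat[, (3 * j - 2):(3 * j)], 1, paste, collapse = "")
    expect_true(all(cods %in% canon))
  }
})

test_that("composition shift moves third-position GC in the imposed direction", {
  tr <- ape::read.tree(text = "((a:0.6,b:0.6):0.4,(c:0.6,d:0.6):0.4,(e:0.6,f:0.6):0.4);")
  cfg <- simulation_config(
    n_codons_per_gene = 2000L, sequence_seed = 17,
    synonymous_rate_multiplier = 20,
    base_frequencies = c(0.35, 0.15, 0.15, 0.35),              # AT-rich
    composition_shift_taxa = c("a", "b"),
    composition_shift_frequencies = c(0.1, 0.4, 0.4, 0.1),     # GC-rich
    p_invariant = 0, gamma_shape = Inf)
  a <- simulate_codon_alignment(tr, cfg)
  nt3 <- a$mat[, seq(3, ncol(a$mat), 3)]
  gc <- rowMeans(nt3 == "G" | nt3 == "C")
  expect_gt(mean(gc[c("a", "b")]), mean(gc[c("c", "d", "e", "f")]))
  # shifted taxa third positions lean toward the imposed composition
  expect_gt(mean(gc[c("a", "b")]) - mean(gc[c("c", "d", "e", "f")]), 0.05)
})

test_that("degen1 erases a purely synonymous history", {
  tr <- simulate_tree(6, seed = 6, branch_length_scale = 0.3)
  cfg <- simulation_config(n_codons_per_gene = 100L, sequence_seed = 19,
                           synonymous_rate_multiplier = 1e7)
  a <- simulate_codon_alignment(tr, cfg)
  rec <- degen1_recode(a)
  for (j in seq_len(ncol(rec$mat))) {
    expect_length(unique(rec$mat[, j]), 1L)
  }
})

test_that("presence designs blank whole taxon-gene rows", {
  set.seed(21)
  tr <- simulate_tree(6, seed = 2)
  cfg <- simulation_config(n_codons_per_gene = c(10L, 8L), sequence_seed = 3)
  alns <- lapply(1:2, function(g) simulate_codon_alignment(tr, cfg, g))
  genes <- vapply(alns, function(a) a$gene, "")
  d <- block_presence_design(tr$tip.label, genes, 4, core_genes = genes[1])
  out <- apply_presence_design(alns, d)
  expect_identical(out[[1]]$mat, alns[[1]]$mat)  # core gene untouched
  absent <- tr$tip.label[5:6]
  expect_true(all(out[[2]]$mat[absent, ] == "?"))
  expect_identical(out[[2]]$mat[tr$tip.label[1:4], ],
                   alns[[2]]$mat[tr$tip.label[1:4], ])
  # all-true design is the identity
  d_all <- matrix(TRUE, 6, 2, dimnames = list(tr$tip.label, genes))
  out2 <- apply_presence_design(alns, d_all)
  expect_identical(out2[[2]]$mat, alns[[2]]$mat)
})

test_that("the deliberately incomplete design yields the expected fraction", {
  taxa <- sprintf("t%02d", 1:52)
  genes <- sprintf("g%02d", 1:19)
  d <- block_presence_design(taxa, genes, 29, core_genes = genes[1:5])
  full <- sum(rowSums(d) == 19L)
  expect_identical(full, 29L)
  expect_identical(round(100 * full / length(taxa)), 56)
})

test_that("host-record simulation is reproducible with valid structure", {
  r1 <- simulate_host_records(40, p_polyphagous = 0.4, seed = 31)
  r2 <- simulate_host_records(40, p_polyphagous = 0.4, seed = 31)
  expect_identical(r1$table, r2$table)
  expect_identical(r1$truth, r2$truth)
  expect_setequal(unique(r1$table$tortricid_species), r1$truth$species)
  # p = 0 means every hidden label is oligophagous
  r0 <- simulate_host_records(30, p_polyphagous = 0, seed = 32)
  expect_true(all(r0$truth$label == "oligophagous"))
  # generated proportions respect the regime separation
  tab <- r1$table
  for (s in unique(tab$tortricid_species)) {
    sub <- tab[tab$tortricid_species == s, ]
    if (nrow(sub) < 2) next
    frac <- max(table(sub$plant_order)) / nrow(sub)
    lab <- r1$truth$label[r1$truth$species == s]
    if (lab == "oligophagous") expect_gte(frac, 0.95)
    else expect_lte(frac, 0.7 + 1e-9)
  }
})
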