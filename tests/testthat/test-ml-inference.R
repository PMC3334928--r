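two_taxon_tree <- function(t) {
  structure(list(edge = matrix(c(3L, 3L, 1L, 2L), ncol = 2),
                 edge.length = c(t / 2, t / 2),
                 tip.label = c("a", "b"), Nnode = 1L),
            class = "phylo")
}

test_that("two-taxon likelihood matches the JC closed form to 1e-10", {
  m <- jc_model(alpha = Inf, p_inv = 0, k = 1)
  # zero branch length, identical sequences: n * log(1/4)
  ll0 <- log_likelihood(two_taxon_tree(0), codon_alignment(c(a = "ACGTGA",
                                                             b = "ACGTGA")), m)
  expect_equal(ll0, 6 * log(0.25), tolerance = 1e-6)
  for (t in c(0.05, 0.3, 1.2)) {
    p_match <- 0.25 * (0.25 + 0.75 * exp(-4 * t / 3))
    p_mis <- 0.25 * (0.25 - 0.25 * exp(-4 * t / 3))
    llm <- log_likelihood(two_taxon_tree(t),
                          codon_alignment(c(a = "AAA", b = "AAA")), m)
    llx <- log_likelihood(two_taxon_tree(t),
                          codon_alignment(c(a = "AAA", b = "CCC")), m)
    expect_equal(llm, 3 * log(p_match), tolerance = 1e-10)
    expect_equal(llx, 3 * log(p_mis), tolerance = 1e-10)
  }
})

test_that("plain GTR (one category, no invariants) equals the mixture path", {
  set.seed(41)
  m1 <- orc_random_model()
  m1$alpha <- Inf; m1$p_inv <- 0
  m4 <- m1; m4$k <- 1L
  tr <- orc_random_tree(4)
  mat <- orc_random_matrix(tr$tip.label, 30)
  aln <- codon_alignment(mat)
  expect_equal(log_likelihood(tr, aln, m1), log_likelihood(tr, aln, m4),
               tolerance = 1e-10)
})

test_that("pruning equals exhaustive enumeration on random small trees", {
  set.seed(42)
  for (case in 1:100) {
    n <- sample(3:5, 1)
    tr <- orc_random_tree(n)
    model <- orc_random_model()
    alphabet <- if (case %% 3 == 0) {
      c("A", "C", "G", "T", "Y", "R", "N", "-", "?")
    } else {
      c("A", "C", "G", "T")
    }
    mat <- orc_random_matrix(tr$tip.label, 15, alphabet)
    aln <- codon_alignment(mat)
    expect_equal(log_likelihood(tr, aln, model),
                 orc_loglik(tr, mat, model), tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to rerooting and taxon order", {
  set.seed(43)
  tr <- orc_random_tree(7)
  model <- orc_random_model()
  mat <- orc_random_matrix(tr$tip.label, 60)
  aln <- codon_alignment(mat)
  ll <- log_likelihood(tr, aln, model)
  rerooted <- ape::unroot(ape::root(tr, outgroup = "t05",
                                    resolve.root = TRUE))
  expect_equal(log_likelihood(rerooted, aln, model), ll, tolerance = 1e-8)
  perm <- sample(tr$tip.label)
  aln2 <- codon_alignment(mat[perm, ])
  expect_equal(log_likelihood(tr, aln2, model), ll, tolerance = 1e-8)
})

test_that("IUPAC columns equal the sum over their explicit expansions", {
  # a Y tip must behave as (likelihood with C) + (likelihood with T)
  m <- orc_random_model()
  tr <- orc_random_tree(3)
  matY <- matrix(c("Y", "A", "G"), ncol = 1,
                 dimnames = list(tr$tip.label, NULL))
  matC <- matY; matC[1, 1] <- "C"
  matT <- matY; matT[1, 1] <- "T"
  lY <- exp(orc_loglik(tr, matY, m))
  expect_equal(exp(log_likelihood(tr, matY, m)), lY, tolerance = 1e-10)
  expect_equal(lY,
               exp(log_likelihood(tr, matC, m)) +
                 exp(log_likelihood(tr, matT, m)),
               tolerance = 1e-10)
})

test_that("partitioned likelihood is the sum of its partition terms", {
  set.seed(44)
  aln <- orc_random_codon_alignment(5, 30)
  sm <- concatenate_genes(list(aln))
  scheme <- build_partitions(sm)
  tr <- orc_random_tree(5)
  tr$tip.label <- aln$taxa
  m1 <- orc_random_model(); m2 <- orc_random_model()
  ll <- log_likelihood(tr, sm, list(nonsyn_nt1_nt2 = m1,
                                    potsyn_nt1_nt3 = m2), scheme)
  ll1 <- log_likelihood(tr, sm$mat[, scheme$nonsyn_nt1_nt2,
                                   drop = FALSE], m1)
  ll2 <- log_likelihood(tr, sm$mat[, scheme$potsyn_nt1_nt3,
                                   drop = FALSE], m2)
  expect_equal(ll, ll1 + ll2, tolerance = 1e-8)
})

test_that("optimization never decreases the likelihood and refits stably", {
  set.seed(45)
  tr <- orc_random_tree(6)
  model <- subst_model(rates = c(1, 2, 1, 1, 2, 1),
                       base_freq = c(0.3, 0.2, 0.2, 0.3),
                       alpha = 0.7, p_inv = 0.1)
  aln <- simulate_gtr_sites(tr, model, 600, seed = 46)
  fit <- suppressWarnings(
    optimize_parameters(tr, aln, model, what = c("alpha", "p_inv"),
                        max_iter = 3))
  expect_true(all(diff(fit$trace) > -1e-6))  # monotone trace
  # refitting at the optimum moves the likelihood by less than tol
  fit2 <- suppressWarnings(
    optimize_parameters(fit$tree, aln, fit$models,
                        what = c("alpha", "p_inv"), max_iter = 1))
  expect_lt(abs(fit2$loglik - fit$loglik), 0.5)
})

test_that("gamma shape is recovered within 30% on simulated data", {
  tr <- simulate_tree(12, seed = 47)
  set.seed(48)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 0.3)
  truth <- subst_model(rates = c(1, 4, 1, 1, 4, 1),
                       base_freq = c(0.3, 0.2, 0.2, 0.3), alpha = 0.5,
                       p_inv = 0)
  aln <- simulate_gtr_sites(tr, truth, 6000, seed = 49)
  start <- truth; start$alpha <- 2
  fit <- suppressWarnings(
    optimize_parameters(ape::unroot(tr), aln, start, what = "alpha",
                        max_iter = 2))
  expect_lt(abs(fit$models[[1]]$alpha - 0.5) / 0.5, 0.3)
})

test_that("search recovers the generating topology and is deterministic", {
  mod <- subst_model(rates = c(1, 3, 1, 1, 3, 1),
                     base_freq = c(0.3, 0.2, 0.2, 0.3), alpha = 0.8,
                     p_inv = 0.1)
  tr6 <- simulate_tree(6, seed = 3)
  set.seed(4); tr6$edge.length <- stats::runif(nrow(tr6$edge), 0.1, 0.3)
  aln <- simulate_gtr_sites(tr6, mod, 600, seed = 11)
  best <- search_tree(aln, mod, n_starts = 2, seed = 5)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr6), best)), 0)
  best2 <- search_tree(aln, mod, n_starts = 2, seed = 5)
  expect_identical(ape::write.tree(best), ape::write.tree(best2))
  expect_equal(attr(best, "loglik"), attr(best2, "loglik"))
  expect_error(search_tree(codon_alignment(c(a = "AAA", b = "AAA", c = "AAA")),
                           mod), "at least 4")
})

test_that("four-taxon search matches exhaustive topology evaluation", {
  set.seed(51)
  mod <- subst_model(rates = c(1, 3, 1, 1, 3, 1),
                     base_freq = c(0.3, 0.2, 0.2, 0.3), alpha = 1,
                     p_inv = 0)
  for (case in 1:3) {
    tr4 <- orc_random_tree(4, min_bl = 0.1, max_bl = 0.4)
    aln <- simulate_gtr_sites(tr4, mod, 300, seed = 52 + case)
    best <- search_tree(aln, mod, n_starts = 2, seed = 6)
    # exhaustive: the three unrooted quartet topologies
    quartets <- c("((t01,t02),t03,t04);", "((t01,t03),t02,t04);",
                  "((t01,t04),t02,t03);")
    lls <- vapply(quartets, function(q) {
      t0 <- ape::read.tree(text = q)
      t0$edge.length <- rep(0.2, nrow(t0$edge))
      f <- suppressWarnings(
        optimize_parameters(t0, aln, mod, what = character(0),
                            max_iter = 2))
      f$loglik
    }, 0)
    top <- ape::read.tree(text = names(which.max(lls)))
    expect_equal(as.numeric(ape::dist.topo(best, ape::unroot(top))), 0)
  }
})

test_that("likelihood on degen1-recoded data accepts ambiguity codes", {
  set.seed(53)
  aln <- orc_random_codon_alignment(5, 20)
  rec <- degen1_recode(aln)
  tr <- orc_random_tree(5)
  tr$tip.label <- aln$taxa
  m <- orc_random_model()
  ll <- log_likelihood(tr, rec, m)
  expect_true(is.finite(ll))
  expect_equal(ll, orc_loglik(tr, rec$mat, m), tolerance = 1e-8)
})
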