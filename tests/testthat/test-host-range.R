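tiny_table <- function() {
  host_record_table(
    tortricid_species = c(rep("sp1", 10), rep("sp2", 10), "sp3",
                          rep("sp4", 2)),
    tribe = c(rep("Archipini", 20), "Tortricini", rep("Cochylini", 2)),
    plant_species = sprintf("Plant_%02d", 1:23),
    plant_order = c(rep("Rosales", 8), rep("Fabales", 2),     # sp1: 8/10
                    rep("Rosales", 7), rep("Poales", 3),      # sp2: 7/10
                    "Fagales",                                # sp3: single
                    rep("Ericales", 2))                       # sp4: 2/2
  )
}

test_that("plant-order lookup fills, flags and is idempotent", {
  tab <- host_record_table(c("s1", "s1", "s2", "s2"), rep("Archipini", 4),
                           c("Rosa canina", "Quercus robur",
                             "Rosa rugosa", "Mystery plant"))
  lookup <- c("Rosa canina" = "Rosales", "Quercus robur" = "Fagales",
              "Rosa" = "Rosales")
  expect_message(m1 <- map_plant_orders(tab, lookup), "1 record")
  expect_identical(m1$plant_order[1:3], c("Rosales", "Fagales", "Rosales"))
  expect_true(m1$unresolved[4])
  m2 <- suppressMessages(map_plant_orders(m1, lookup))
  expect_identical(m2$plant_order, m1$plant_order)
  # fully resolvable table has zero unresolved rows
  m3 <- map_plant_orders(tab[1:3, ], lookup)
  expect_false(any(m3$unresolved))
})

test_that("single-entry species are excluded from scoring", {
  tab <- tiny_table()
  f <- filter_single_entry_species(tab)
  expect_false("sp3" %in% f$tortricid_species)
  expect_true("sp4" %in% f$tortricid_species)  # two entries: retained
  expect_identical(attr(f, "n_removed"), 1L)
  empty <- tab[0, ]
  f0 <- filter_single_entry_species(empty)
  expect_identical(nrow(f0), 0L)
})

test_that("the 80% modal-order rule is inclusive at the boundary", {
  sc <- classify_species(filter_single_entry_species(tiny_table()))
  sc <- sc[order(sc$species), ]
  expect_identical(sc$label[sc$species == "sp1"], "oligophagous")  # 8/10
  expect_identical(sc$label[sc$species == "sp2"], "polyphagous")   # 7/10
  expect_identical(sc$label[sc$species == "sp4"], "oligophagous")  # 2/2
  expect_equal(sc$modal_fraction[sc$species == "sp1"], 0.8)
})

test_that("unscorable, oligophagous and polyphagous counts conserve species", {
  set.seed(91)
  sim <- simulate_host_records(60, p_polyphagous = 0.4,
                               entries_per_species = function(n)
                                 sample(1:8, n, replace = TRUE), seed = 92)
  sc <- classify_species(sim$table)
  expect_identical(nrow(sc), length(unique(sim$table$tortricid_species)))
  expect_identical(sum(sc$label == "unscorable"),
                   sum(base::table(sim$table$tortricid_species) == 1L))
})

test_that("adding modal-order entries never flips oligophagous to polyphagous", {
  set.seed(93)
  sim <- simulate_host_records(30, p_polyphagous = 0.5, seed = 94)
  sc <- classify_species(sim$table)
  oligo <- sc$species[sc$label == "oligophagous"]
  tab <- sim$table
  for (s in oligo) {
    modal <- sc$modal_order[sc$species == s]
    extra <- tab[tab$tortricid_species == s, ][1:3, ]
    extra$plant_order <- modal
    tab <- rbind(tab, extra)
  }
  sc2 <- classify_species(tab)
  expect_true(all(sc2$label[sc2$species %in% oligo] == "oligophagous"))
})

test_that("classifier recovers hidden labels on well-separated tables", {
  sim <- simulate_host_records(250, p_polyphagous = 0.5,
                               entries_per_species = function(n)
                                 10L + stats::rpois(n, 4), seed = 95)
  sc <- classify_species(sim$table)
  truth <- stats::setNames(sim$truth$label, sim$truth$species)
  scored <- sc[sc$n_entries >= 5L & sc$label != "unscorable", ]
  recovery <- mean(scored$label == truth[scored$species])
  expect_gte(recovery, 0.95)
  # the all-polyphagous regime is recovered too
  sim1 <- simulate_host_records(200, p_polyphagous = 1,
                                entries_per_species = 12L, seed = 96)
  sc1 <- classify_species(sim1$table)
  expect_gte(mean(sc1$label == "polyphagous"), 0.95)
})

test_that("tribe summaries count polyphagous over scorable species", {
  sc <- data.frame(
    species = sprintf("s%d", 1:6),
    tribe = c(rep("Archipini", 4), "Cochylini", "Cochylini"),
    n_entries = rep(5L, 6), modal_order = "Rosales",
    modal_fraction = 1,
    label = c("polyphagous", "polyphagous", "oligophagous", "oligophagous",
              "oligophagous", "unscorable"),
    stringsAsFactors = FALSE)
  ts <- summarize_tribes(sc)
  arch <- ts[ts$tribe == "Archipini", ]
  expect_identical(arch$summary, "2/4 = 50%")
  coch <- ts[ts$tribe == "Cochylini", ]
  expect_identical(coch$percent_polyphagous, 0)
  expect_identical(sum(ts$n_scorable), sum(sc$label != "unscorable"))
})

test_that("the shipped synthetic lookup resolves simulated tables fully", {
  lookup_file <- system.file("extdata", "plant_order_lookup_synthetic.tsv",
                             package = "phylodegen")
  lookup <- utils::read.delim(lookup_file)
  sim <- simulate_host_records(20, seed = 97)
  tab <- sim$table
  tab$plant_order <- NA_character_
  res <- map_plant_orders(host_record_table(tab$tortricid_species, tab$tribe,
                                            tab$plant_species), lookup)
  expect_false(any(res$unresolved))
  expect_identical(res$plant_order, sim$table$plant_order)
})
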