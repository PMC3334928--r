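# Host-record table simulation with known diet-breadth truth labels.

.PLANT_ORDERS <- c("Fabales", "Rosales", "Malpighiales", "Asterales",
                   "Poales", "Lamiales", "Sapindales", "Myrtales",
                   "Ericales", "Gentianales", "Fagales", "Pinales")

.TRIBES <- c("Archipini", "Olethreutini", "Grapholitini", "Eucosmini",
             "Cochylini", "Sparganothini", "Tortricini", "Enarmoniini")

#' Simulate a host-association record table with hidden diet labels
#'
#' Each synthetic species carries a hidden true label. Oligophagous species
#' draw at least 95% of their entries from one modal plant order (the
#' off-modal count is capped at 3% of entries, rounded down); polyphagous
#' species draw entries from two or three orders with no order exceeding
#' 70%. Rows are entry-level associations (species, tribe, plant species,
#' plant order), mirroring the structure of observational host-use
#' databases.
#'
#' @param n_species number of tortricid species to simulate.
#' @param p_polyphagous probability that a species is truly polyphagous.
#' @param entries_per_species either a single integer (fixed entry count
#'   per species) or a `function(n)` returning `n` entry counts; counts are
#'   floored at 1 so single-entry species (which the classifier must
#'   discard) can occur when the law produces them.
#' @param seed integer RNG seed.
#' @return A list: `table` (data frame with columns `tortricid_species`,
#'   `tribe`, `plant_species`, `plant_order`) and `truth` (data frame with
#'   `species`, `tribe`, `label`).
#' @export
simulate_host_records <- function(n_species, p_polyphagous = 0.3,
                                  entries_per_species = function(n)
                                    2L + stats::rpois(n, 6),
                                  seed = 1L) {
  stopifnot(p_polyphagous >= 0, p_polyphagous <= 1, n_species >= 1)
  set.seed(as.integer(seed))
  species <- sprintf("Tortricid_sp%04d", seq_len(n_species))
  tribe <- rep_len(.TRIBES, n_species)
  poly <- stats::runif(n_species) < p_polyphagous
  n_entries <- if (is.function(entries_per_species)) {
    pmax(1L, as.integer(entries_per_species(n_species)))
  } else {
    rep_len(pmax(1L, as.integer(entries_per_species)), n_species)
  }
  # a pool of plant species per order
  plant_pool <- lapply(.PLANT_ORDERS, function(o)
    sprintf("%s_plant%02d", o, 1:8))
  names(plant_pool) <- .PLANT_ORDERS

  rows <- vector("list", n_species)
  for (i in seq_len(n_species)) {
    n <- n_entries[i]
    if (poly[i] && n >= 2L) {
      k <- if (n >= 3L) sample(2:3, 1L) else 2L
      ords <- sample(.PLANT_ORDERS, k)
      # counts with every order capped at 70% of entries
      repeat {
        cnt <- as.vector(stats::rmultinom(1L, n, rep(1 / k, k)))
        if (all(cnt >= 1L) && max(cnt) <= floor(0.7 * n)) break
        # small n where no multinomial draw can satisfy the cap:
        if (n < k || floor(0.7 * n) * k < n) { cnt <- rep(n %/% k, k)
          cnt[seq_len(n %% k)] <- cnt[seq_len(n %% k)] + 1L; break }
      }
      order_vec <- rep(ords, cnt)
    } else {
      modal <- sample(.PLANT_ORDERS, 1L)
      n_off <- floor(0.03 * n)
      order_vec <- c(rep(modal, n - n_off),
                     sample(setdiff(.PLANT_ORDERS, modal), n_off,
                            replace = TRUE))
    }
    order_vec <- sample(order_vec)
    plants <- vapply(order_vec, function(o)
      sample(plant_pool[[o]], 1L), "")
    rows[[i]] <- data.frame(tortricid_species = species[i],
                            tribe = tribe[i],
                            plant_species = plants,
                            plant_order = order_vec,
                            stringsAsFactors = FALSE,
                            row.names = NULL)
  }
  truth_label <- ifelse(poly, "polyphagous", "oligophagous")
  list(table = do.call(rbind, rows),
       truth = data.frame(species = species, tribe = tribe,
                          label = truth_label, stringsAsFactors = FALSE))
}
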