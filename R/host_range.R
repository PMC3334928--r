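# Diet-breadth classification from host-association record tables:
# plant-order lookup, single-entry filtering, the >=80% modal-order rule,
# and tribe-level polyphagy summaries.

#' Build a host-record table
#'
#' @param tortricid_species,tribe,plant_species,plant_order character
#'   vectors of equal length; `plant_order` may be `NA` (unresolved,
#'   pending lookup).
#' @return Data frame of class `host_record_table` (entry-level rows).
#' @export
host_record_table <- function(tortricid_species, tribe, plant_species,
                              plant_order = NA_character_) {
  df <- data.frame(tortricid_species = as.character(tortricid_species),
                   tribe = as.character(tribe),
                   plant_species = as.character(plant_species),
                   plant_order = as.character(plant_order),
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[c("tortricid_species", "tribe", "plant_species")])
  if (any(is.na(m) | !nzchar(m))) {
    stop("species/tribe fields must be non-empty")
  }
  class(df) <- c("host_record_table", "data.frame")
  df
}

#' Read a host-record table from TSV
#'
#' @param file TSV with columns `tortricid_species`, `tribe`,
#'   `plant_species` and optionally `plant_order`.
#' @return A [host_record_table()].
#' @export
read_host_records <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (is.null(df$plant_order)) df$plant_order <- NA_character_
  host_record_table(df$tortricid_species, df$tribe, df$plant_species,
                    df$plant_order)
}

#' Fill unresolved plant orders from a lookup
#'
#' Rows with missing `plant_order` are resolved from a plant-species to
#' order map (with a genus-level fallback: the first whitespace- or
#' underscore-separated token). Rows still unresolved are flagged in the
#' logical column `unresolved` and are excluded from scoring downstream;
#' applying the lookup twice changes nothing.
#'
#' @param table a [host_record_table()].
#' @param lookup named character vector (`plant species -> order`) or a
#'   two-column data frame `(plant_species, plant_order)`; genus keys work
#'   as fallback.
#' @return The table with `plant_order` filled and an `unresolved` column.
#' @export
map_plant_orders <- function(table, lookup) {
  if (is.data.frame(lookup)) {
    lk <- lookup[[2]]
    names(lk) <- lookup[[1]]
    lookup <- lk
  }
  miss <- is.na(table$plant_order) | !nzchar(table$plant_order)
  hit <- lookup[table$plant_species[miss]]
  genus <- sub("[ _].*$", "", table$plant_species[miss])
  hit[is.na(hit)] <- lookup[genus[is.na(hit)]]
  table$plant_order[miss] <- unname(hit)
  table$unresolved <- is.na(table$plant_order)
  n_bad <- sum(table$unresolved)
  if (n_bad) {
    message(n_bad, " record(s) with unresolvable plant order; ",
            "excluded from scoring")
  }
  table
}

#' Drop species represented by a single entry
#'
#' Species with exactly one record cannot show polyphagy and would inflate
#' apparent oligophagy, so they are excluded from scoring.
#'
#' @param table a [host_record_table()].
#' @return The table restricted to species with two or more entries; the
#'   number of removed species is attached as attribute `n_removed`.
#' @export
filter_single_entry_species <- function(table) {
  n <- base::table(factor(table$tortricid_species))
  single <- names(n)[n == 1L]
  out <- table[!table$tortricid_species %in% single, , drop = FALSE]
  attr(out, "n_removed") <- length(single)
  out
}

#' Score species as oligophagous or polyphagous
#'
#' Per species, the modal plant order's share of entries is computed; a
#' species with at least 80% of entries in one order (inclusive boundary)
#' is oligophagous, otherwise polyphagous. Species with fewer than two
#' entries are unscorable. Ties for the modal order share the same modal
#' fraction, so the label does not depend on the tie-break.
#'
#' @param table a [host_record_table()] with resolved orders (rows flagged
#'   `unresolved` are dropped first).
#' @param threshold modal-order fraction at or above which a species is
#'   oligophagous (default 0.8).
#' @return Data frame: `species`, `tribe`, `n_entries`, `modal_order`,
#'   `modal_fraction`, `label`.
#' @export
classify_species <- function(table, threshold = 0.8) {
  if (!is.null(table$unresolved)) {
    table <- table[!table$unresolved, , drop = FALSE]
  }
  sp <- unique(table$tortricid_species)
  rows <- lapply(sp, function(s) {
    sub <- table[table$tortricid_species == s, , drop = FALSE]
    tab <- sort(base::table(sub$plant_order), decreasing = TRUE)
    frac <- as.numeric(tab[1]) / nrow(sub)
    label <- if (nrow(sub) < 2L) "unscorable"
             else if (frac >= threshold) "oligophagous" else "polyphagous"
    data.frame(species = s, tribe = sub$tribe[1], n_entries = nrow(sub),
               modal_order = names(tab)[1], modal_fraction = frac,
               label = label, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tribe-level polyphagy synopsis
#'
#' Per tribe: the number of polyphagous species over the number of
#' scorable species (those with two or more entries), as
#' `"n_poly/n_scorable = p%"`.
#'
#' @param scores result of [classify_species()].
#' @param tribe_of optional named character vector `species -> tribe`
#'   overriding the tribes recorded in `scores`.
#' @return Data frame: `tribe`, `n_polyphagous`, `n_scorable`,
#'   `percent_polyphagous`, `summary`; species without a tribe are
#'   collected under attribute `unmapped`.
#' @export
summarize_tribes <- function(scores, tribe_of = NULL) {
  sc <- scores[scores$label != "unscorable", , drop = FALSE]
  tribe <- if (is.null(tribe_of)) sc$tribe else unname(tribe_of[sc$species])
  unmapped <- sc$species[is.na(tribe) | !nzchar(tribe)]
  keep <- !(is.na(tribe) | !nzchar(tribe))
  sc <- sc[keep, , drop = FALSE]
  tribe <- tribe[keep]
  out <- do.call(rbind, lapply(split(sc, tribe), function(g) {
    np <- sum(g$label == "polyphagous")
    ns <- nrow(g)
    pct <- round(100 * np / ns)
    data.frame(tribe = g$tribe[1], n_polyphagous = np, n_scorable = ns,
               percent_polyphagous = pct,
               summary = sprintf("%d/%d = %d%%", np, ns, pct),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "unmapped") <- unmapped
  out
}
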