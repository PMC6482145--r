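#' Benthic survey vocabulary
#'
#' Controlled vocabularies used throughout the package for point-intercept
#' records: benthic categories, coral growth morphologies, radial transect
#' labels and echinoid genera.
#'
#' `benthic_categories()` returns the nine benthic categories a
#' point-intercept observation may take. `coral_morphologies()` returns the
#' recognised coral growth forms plus `"none"`, the value carried by every
#' non-coral observation.
#'
#' @return A character vector of allowed values.
#' @examples
#' benthic_categories()
#' coral_morphologies()
#' @export
benthic_categories <- function() {
  c("live_coral", "dead_coral", "reef_framework", "rubble", "sand",
    "cca", "turf_algae", "macroalgae", "other")
}

#' @rdname benthic_categories
#' @export
coral_morphologies <- function() {
  c("massive", "branching", "tabular", "digitate", "encrusting",
    "free_living", "none")
}

#' @rdname benthic_categories
#' @export
transect_labels <- function() {
  c("SW", "W", "NW", "N", "NE", "E", "SE")
}

#' @rdname benthic_categories
#' @export
echinoid_genera <- function() {
  c("Diadema", "Phyllocanthus")
}

#' Functional category sets
#'
#' Benthic categories grouped by their role in the budget. *Available
#' substrate* is the set open to bioerosion by endolithic borers and
#' grazers: live coral, in-place reef framework, dead coral and rubble.
#' *Carbonate producers* are the categories that contribute gross
#' production: live coral and crustose coralline algae (CCA). Everything
#' else is inert with respect to both terms.
#'
#' These sets are derived groupings, not raw categories; keeping dead
#' coral, reef framework and rubble distinct in the census while mapping
#' all three into available substrate lets the erodible fraction be a
#' configuration of the analysis rather than a constraint of the data
#' format.
#'
#' @return A named list of character vectors with elements
#'   `available_substrate`, `carbonate_producer` and `inert`.
#' @examples
#' category_sets()$available_substrate
#' @export
category_sets <- function() {
  avail <- c("live_coral", "reef_framework", "dead_coral", "rubble")
  prod <- c("live_coral", "cca")
  list(
    available_substrate = avail,
    carbonate_producer = prod,
    inert = setdiff(benthic_categories(), union(avail, prod))
  )
}

#' Positions censused along a 10 m survey line
#'
#' Point-intercept observations are made every 10 cm starting at 10 cm, so
#' a complete line carries the 100 positions 10, 20, ..., 1000 cm.
#'
#' @return Integer vector of the 100 census positions in centimetres.
#' @keywords internal
line_positions <- function() {
  seq.int(10L, 1000L, by = 10L)
}
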