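#' Gross production of a single producer term
#'
#' The census-based production equation for one producer on one line:
#' \deqn{G = R \times (X_i / 100) \times (C_i \times 10000) / 1000}
#' where R is the line's rugosity coefficient, \eqn{X_i} the percent
#' cover of the producer and \eqn{C_i} its calcification rate in
#' g cm\eqn{^{-2}} yr\eqn{^{-1}}. The factor (x10000 cm2 per m2, /1000 g
#' per kg) converts to kg CaCO3 per planar m2 per year and reduces to
#' exactly x10; the function asserts that equivalence on every call.
#'
#' @param R Rugosity coefficient(s), >= 1.
#' @param cover_pct Percent cover \eqn{X_i} (0--100).
#' @param ci Calcification rate \eqn{C_i} in g cm-2 yr-1.
#' @return Production in G (kg CaCO3 m-2 yr-1); vectorised.
#' @examples
#' gross_production_rate(R = 2, cover_pct = 50, ci = 1.0) # 10 G
#' @export
gross_production_rate <- function(R, cover_pct, ci) {
  verbatim <- R * (cover_pct / 100) * ((ci * 10000) / 1000)
  reduced <- R * (cover_pct / 100) * (ci * 10)
  stopifnot(isTRUE(all.equal(verbatim, reduced)))
  reduced
}

#' Gross carbonate production per survey line
#'
#' Applies the production equation to every producer censused on each
#' line: live coral split by (taxon, morphology) with rates resolved via
#' [lookup_ci()], and CCA as a secondary producer with its own rate. One
#' rugosity coefficient — the line's own — scales all producers on that
#' line; covers are never pooled across lines before the equation is
#' applied. Non-producing categories (sand, rubble, dead coral, turf and
#' macroalgae) contribute zero by construction; setting `halimeda_ci` in
#' the rate table additionally counts *Halimeda* macroalgae points as
#' producers.
#'
#' @param observations Validated observations data frame.
#' @param rugosity Rugosity data frame ([read_rugosity()]) covering every
#'   line in `observations`.
#' @param rates A [rate_table()].
#' @return A list with two data frames: `lines` (`line_id`,
#'   `transect_id`, `zone_id`, `rugosity`, `gross_G`) and `terms`
#'   (`line_id`, `taxon`, `morphology`, `cover_pct`, `ci_g_cm2_yr`,
#'   `contribution_G`), with `gross_G` the exact sum of the line's term
#'   contributions.
#' @examples
#' reef <- generate_reef(default_mahutigala_scenario(), seed = 1)
#' gp <- gross_production(reef$observations, reef$rugosity,
#'                        default_rate_table())
#' head(gp$lines)
#' @export
gross_production <- function(observations, rugosity, rates) {
  stopifnot(inherits(rates, "rate_table"))
  check_complete_lines(observations)
  rug <- line_rugosity(rugosity)
  meta <- unique(observations[c("line_id", "transect_id", "zone_id")])
  missing_rug <- setdiff(meta$line_id, rug$line_id)
  if (length(missing_rug) > 0L) {
    stop("no rugosity measurements for line(s): ",
         paste(missing_rug, collapse = ", "), call. = FALSE)
  }

  terms <- producer_cover(observations,
                          include_halimeda = !is.null(rates$halimeda_ci))
  if (nrow(terms) > 0L) {
    hal <- !is.na(terms$taxon) & terms$taxon == "Halimeda" &
      terms$morphology == "none"
    terms$ci_g_cm2_yr <- NA_real_
    terms$ci_g_cm2_yr[hal] <- rates$halimeda_ci
    if (any(!hal)) {
      terms$ci_g_cm2_yr[!hal] <- lookup_ci(rates, terms$taxon[!hal],
                                           terms$morphology[!hal])
    }
    Rl <- rug$rugosity[match(terms$line_id, rug$line_id)]
    terms$contribution_G <- gross_production_rate(Rl, terms$cover_pct,
                                                  terms$ci_g_cm2_yr)
  } else {
    terms$ci_g_cm2_yr <- numeric(0)
    terms$contribution_G <- numeric(0)
  }

  gross <- vapply(meta$line_id, function(ln) {
    sum(terms$contribution_G[terms$line_id == ln])
  }, numeric(1))
  lines <- data.frame(
    line_id = meta$line_id,
    transect_id = meta$transect_id,
    zone_id = meta$zone_id,
    rugosity = rug$rugosity[match(meta$line_id, rug$line_id)],
    gross_G = unname(gross),
    stringsAsFactors = FALSE
  )
  lines <- lines[order(lines$line_id), ]
  rownames(lines) <- NULL
  list(lines = lines, terms = terms)
}

#' Share of gross production by coral growth morphology
#'
#' Sums the per-line production terms over growth morphologies (CCA
#' appears under `"none"`) and normalises to shares of the total. A
#' dataset with zero total production returns an empty result rather
#' than an error: there is nothing to apportion.
#'
#' @param terms The `terms` data frame from [gross_production()].
#' @return Data frame `morphology`, `production_G`, `share` with shares
#'   summing to 1 over morphologies with nonzero production; zero rows
#'   when total production is zero.
#' @export
production_by_morphology <- function(terms) {
  empty <- data.frame(morphology = character(0), production_G = numeric(0),
                      share = numeric(0), stringsAsFactors = FALSE)
  if (nrow(terms) == 0L) return(empty)
  agg <- stats::aggregate(list(production_G = terms$contribution_G),
                          by = list(morphology = terms$morphology),
                          FUN = sum)
  agg <- agg[agg$production_G > 0, ]
  total <- sum(agg$production_G)
  if (total <= 0) return(empty)
  agg$share <- agg$production_G / total
  agg <- agg[order(-agg$production_G), ]
  rownames(agg) <- NULL
  agg
}
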