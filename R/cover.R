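#' Percent cover from point-intercept censuses
#'
#' Converts the 100-point census of each survey line into percent cover.
#' With `by = "category"` every benthic category is reported (zeros
#' included) and the values sum to exactly 100 for each line. With
#' `by = "morphology"` or `by = "taxon"` the breakdown is restricted to
#' live-coral points and renormalised to the live-coral total, the
#' convention used when reporting coral community composition; lines
#' without live coral report no rows for these groupings.
#'
#' @param observations Validated observations data frame (see
#'   [read_observations()]); may hold any number of complete lines.
#' @param by Grouping: `"category"`, `"morphology"` or `"taxon"`.
#' @return Data frame with columns `line_id`, the grouping column, and
#'   `percent`.
#' @examples
#' reef <- generate_reef(default_mahutigala_scenario(), seed = 1)
#' head(percent_cover(reef$observations))
#' @export
percent_cover <- function(observations,
                          by = c("category", "morphology", "taxon")) {
  by <- match.arg(by)
  check_complete_lines(observations)
  lines <- unique(observations$line_id)
  out <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    sub <- observations[observations$line_id == lines[k], ]
    if (by == "category") {
      counts <- table(factor(sub$category, levels = benthic_categories()))
      res <- data.frame(line_id = lines[k],
                        category = names(counts),
                        percent = as.numeric(counts),
                        stringsAsFactors = FALSE)
    } else {
      live <- sub[sub$category == "live_coral", ]
      if (nrow(live) == 0L) {
        res <- NULL
      } else {
        key <- if (by == "morphology") live$morphology else
          ifelse(is.na(live$taxon), "unidentified", live$taxon)
        counts <- table(key)
        res <- data.frame(line_id = lines[k],
                          key = names(counts),
                          percent = 100 * as.numeric(counts) / nrow(live),
                          stringsAsFactors = FALSE)
        names(res)[2L] <- by
      }
    }
    out[[k]] <- res
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(line_id = character(0), key = character(0),
                      percent = numeric(0), stringsAsFactors = FALSE)
    names(res)[2L] <- by
  }
  rownames(res) <- NULL
  res
}

#' Producer cover per line
#'
#' Percent cover (out of the 100 census points) of each carbonate
#' producer on each line: live coral split by (taxon, morphology), plus
#' CCA as the producer keyed `("CCA", "none")`. These are the cover terms
#' that enter the gross-production equation.
#'
#' @inheritParams percent_cover
#' @param include_halimeda Also treat `macroalgae` points recorded as
#'   taxon `"Halimeda"` as producers (keyed `("Halimeda", "none")`).
#'   Off by default: budgets conventionally count corals and CCA only.
#' @return Data frame `line_id`, `taxon`, `morphology`, `cover_pct`.
#' @export
producer_cover <- function(observations, include_halimeda = FALSE) {
  check_complete_lines(observations)
  obs <- observations
  keep <- obs$category %in% category_sets()$carbonate_producer
  if (include_halimeda) {
    keep <- keep | (obs$category == "macroalgae" &
                      !is.na(obs$taxon) & obs$taxon == "Halimeda")
  }
  prod <- obs[keep, ]
  if (nrow(prod) == 0L) {
    return(data.frame(line_id = character(0), taxon = character(0),
                      morphology = character(0), cover_pct = numeric(0),
                      stringsAsFactors = FALSE))
  }
  taxon <- ifelse(prod$category == "cca", "CCA", prod$taxon)
  morph <- ifelse(prod$category == "cca", "none", prod$morphology)
  agg <- stats::aggregate(
    list(n = rep(1L, nrow(prod))),
    by = list(line_id = prod$line_id,
              taxon = ifelse(is.na(taxon), "<unidentified>", taxon),
              morphology = morph),
    FUN = sum)
  agg$taxon[agg$taxon == "<unidentified>"] <- NA_character_
  agg$cover_pct <- as.numeric(agg$n)
  agg$n <- NULL
  agg <- agg[order(agg$line_id, agg$morphology,
                   ifelse(is.na(agg$taxon), "", agg$taxon)), ]
  rownames(agg) <- NULL
  agg
}

#' Fraction of available (erodible) substrate per line
#'
#' The fraction of census points falling in the available-substrate set
#' (live coral, reef framework, dead coral, rubble; see
#' [category_sets()]), the quantity bioerosion rates are applied to.
#'
#' @inheritParams percent_cover
#' @return Data frame `line_id`, `f_avail` (0--1).
#' @export
available_substrate_fraction <- function(observations) {
  check_complete_lines(observations)
  avail <- category_sets()$available_substrate
  lines <- unique(observations$line_id)
  f <- vapply(lines, function(ln) {
    sub <- observations[observations$line_id == ln, ]
    mean(sub$category %in% avail)
  }, numeric(1))
  data.frame(line_id = lines, f_avail = unname(f), stringsAsFactors = FALSE)
}

#' Rugosity coefficient of a survey line
#'
#' The rugosity coefficient R of a 10 m line is the arithmetic mean of
#' its three 1 m chain sections (each expressed as surface length over
#' linear length). R = 1 is a perfectly flat substrate; reef flats
#' typically fall between ~1.5 and 3.
#'
#' @param sections Numeric vector of exactly 3 chain ratios, each >= 1.
#' @return The dimensionless coefficient R (>= 1).
#' @examples
#' rugosity_coefficient(c(2.0, 2.5, 3.0))
#' @export
rugosity_coefficient <- function(sections) {
  if (length(sections) != 3L) {
    stop(sprintf("exactly 3 rugosity sections required, got %d",
                 length(sections)), call. = FALSE)
  }
  if (anyNA(sections) || any(sections < 1)) {
    stop("every rugosity section must be a ratio >= 1", call. = FALSE)
  }
  mean(sections)
}

#' Per-line rugosity coefficients from chain measurements
#'
#' @param rugosity Data frame from [read_rugosity()].
#' @return Data frame `line_id`, `rugosity`.
#' @export
line_rugosity <- function(rugosity) {
  rugosity <- validate_rugosity(rugosity)
  lines <- unique(rugosity$line_id)
  r <- vapply(lines, function(ln) {
    rugosity_coefficient(rugosity$chain_ratio[rugosity$line_id == ln])
  }, numeric(1))
  data.frame(line_id = lines, rugosity = unname(r), stringsAsFactors = FALSE)
}

check_complete_lines <- function(observations) {
  counts <- table(observations$line_id)
  if (any(counts != 100L)) {
    ln <- names(counts)[counts != 100L][1L]
    stop(sprintf("incomplete survey line '%s': %d of 100 observations",
                 ln, counts[[ln]]), call. = FALSE)
  }
  invisible(TRUE)
}
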