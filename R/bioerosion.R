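#' Bioerosion rate kernels
#'
#' The three component erosion laws, exposed as vectorised scalar
#' kernels. All results are in G (kg CaCO3 m-2 yr-1).
#'
#' `borer_erosion_rate()` — endolithic macro- and micro-borers erode the
#' rugosity-scaled available substrate at a fixed combined rate:
#' `R * f_avail * (macro + micro)` (defaults 0.052 + 0.053 = 0.105 G).
#'
#' `parrotfish_erosion_rate()` — a published parrotfish grazing rate
#' (default 3.81 G) applied per planar m2 of available substrate:
#' `rate * f_avail`. Belt-survey-derived fish rates are normalised to
#' planar area, so no rugosity multiplier is applied unless `R` is
#' supplied (sensitivity analyses only).
#'
#' `echinoid_erosion_rate()` — the urchin test-size power law
#' `((a * X^b) * e * 365 / 60) / 1000` with X the mean test size in mm
#' and e the urchin density in individuals per m2. The 365/60 factor is
#' part of the published daily-to-annual rate chain and is applied
#' verbatim.
#'
#' @param R Rugosity coefficient(s).
#' @param f_avail Fraction (0--1) of points on available substrate.
#' @param macro,micro Borer rate constants in G.
#' @param rate Parrotfish rate in G per planar m2 of available substrate.
#' @param test_size_mm Mean echinoid test size, mm.
#' @param density_per_m2 Echinoid density, individuals per m2.
#' @param a,b Coefficients of the echinoid power law.
#' @return Erosion in G; vectorised over the inputs.
#' @examples
#' borer_erosion_rate(R = 1, f_avail = 1)           # 0.105
#' parrotfish_erosion_rate(f_avail = 0.5)           # 1.905
#' echinoid_erosion_rate(30, 1, a = 0.0029)         # ~0.005
#' @name erosion_kernels
NULL

#' @rdname erosion_kernels
#' @export
borer_erosion_rate <- function(R, f_avail, macro = 0.052, micro = 0.053) {
  stopifnot(all(f_avail >= 0 & f_avail <= 1), all(R >= 1))
  R * f_avail * (macro + micro)
}

#' @rdname erosion_kernels
#' @export
parrotfish_erosion_rate <- function(f_avail, rate = 3.81, R = NULL) {
  stopifnot(all(f_avail >= 0 & f_avail <= 1))
  scale <- if (is.null(R)) 1 else R
  rate * f_avail * scale
}

#' @rdname erosion_kernels
#' @export
echinoid_erosion_rate <- function(test_size_mm, density_per_m2,
                                  a, b = 1.6624) {
  stopifnot(all(test_size_mm > 0), all(density_per_m2 >= 0))
  (((a * test_size_mm^b) * density_per_m2) * 365 / 60) / 1000
}

#' Borer and parrotfish erosion per survey line
#'
#' Applies the borer and parrotfish kernels to each line's available-
#' substrate fraction (and rugosity for the borer term; see
#' [erosion_kernels] for why the parrotfish term is planar by default).
#'
#' @inheritParams gross_production
#' @return Data frame `line_id`, `f_avail`, `rugosity`, `borer_G`
#'   (respectively `parrotfish_G`).
#' @export
borer_erosion <- function(observations, rugosity, rates) {
  stopifnot(inherits(rates, "rate_table"))
  fa <- available_substrate_fraction(observations)
  rug <- line_rugosity(rugosity)
  fa$rugosity <- rug$rugosity[match(fa$line_id, rug$line_id)]
  if (anyNA(fa$rugosity)) {
    stop("no rugosity measurements for line(s): ",
         paste(fa$line_id[is.na(fa$rugosity)], collapse = ", "),
         call. = FALSE)
  }
  fa$borer_G <- borer_erosion_rate(fa$rugosity, fa$f_avail,
                                   macro = rates$macro_borer_rate,
                                   micro = rates$micro_borer_rate)
  fa
}

#' @rdname borer_erosion
#' @export
parrotfish_erosion <- function(observations, rugosity, rates) {
  stopifnot(inherits(rates, "rate_table"))
  fa <- available_substrate_fraction(observations)
  rug <- line_rugosity(rugosity)
  fa$rugosity <- rug$rugosity[match(fa$line_id, rug$line_id)]
  Rmult <- if (rates$parrotfish_use_rugosity) fa$rugosity else NULL
  fa$parrotfish_G <- parrotfish_erosion_rate(fa$f_avail,
                                             rate = rates$parrotfish_rate,
                                             R = Rmult)
  fa
}

#' Echinoid erosion per belt transect
#'
#' For each belt and genus the erosion law is evaluated at the recorded
#' mean test size and the density `count / area_m2`; genus rates are
#' summed within a belt.
#'
#' @param belts Belt data frame ([read_belts()]).
#' @param rates A [rate_table()] supplying per-genus (a, b) coefficients.
#' @return Data frame `belt_id`, `transect_id`, `zone_id`, `echinoid_G`.
#' @export
echinoid_erosion <- function(belts, rates) {
  stopifnot(inherits(rates, "rate_table"))
  belts <- validate_belts(belts)
  coeffs <- rates$echinoid_coeffs
  miss <- setdiff(unique(belts$genus), coeffs$genus)
  if (length(miss) > 0L) {
    stop("no echinoid coefficients for genus: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  idx <- match(belts$genus, coeffs$genus)
  gr <- echinoid_erosion_rate(belts$test_size_mm,
                              belts$count / belts$area_m2,
                              a = coeffs$a[idx], b = coeffs$b[idx])
  meta <- unique(belts[c("belt_id", "transect_id", "zone_id")])
  meta$echinoid_G <- vapply(meta$belt_id, function(b) {
    sum(gr[belts$belt_id == b])
  }, numeric(1))
  rownames(meta) <- NULL
  meta
}

#' Broadcast belt-scale echinoid erosion to survey lines
#'
#' Belt transects are fewer and coarser than survey lines, so the belt-
#' scale echinoid rate is assigned to each line by the closest available
#' match: the mean over belts sharing the line's transect and zone, else
#' the mean over belts on the same transect, else the reef-wide mean over
#' all belts. With no belts at all the echinoid term is zero, with a
#' warning.
#'
#' @param line_meta Data frame with columns `line_id`, `transect_id`,
#'   `zone_id` (one row per line).
#' @param belts Belt data frame, possibly empty.
#' @param rates A [rate_table()].
#' @return Data frame `line_id`, `echinoid_G`.
#' @export
echinoid_erosion_by_line <- function(line_meta, belts, rates) {
  if (is.null(belts) || nrow(belts) == 0L) {
    warning("no echinoid belt transects supplied; echinoid erosion set to 0",
            call. = FALSE)
    return(data.frame(line_id = line_meta$line_id, echinoid_G = 0,
                      stringsAsFactors = FALSE))
  }
  br <- echinoid_erosion(belts, rates)
  reef_mean <- mean(br$echinoid_G)
  g <- vapply(seq_len(nrow(line_meta)), function(i) {
    same_tz <- br$transect_id == line_meta$transect_id[i] &
      br$zone_id == line_meta$zone_id[i]
    if (any(same_tz)) return(mean(br$echinoid_G[same_tz]))
    same_t <- br$transect_id == line_meta$transect_id[i]
    if (any(same_t)) return(mean(br$echinoid_G[same_t]))
    reef_mean
  }, numeric(1))
  data.frame(line_id = line_meta$line_id, echinoid_G = g,
             stringsAsFactors = FALSE)
}

#' Total bioerosion per survey line
#'
#' Sums the three components per line and reports their percent shares
#' of the dataset-wide total (shares are empty when total erosion is
#' zero).
#'
#' @inheritParams gross_production
#' @param belts Belt data frame, possibly empty (echinoid term 0).
#' @return A list: `lines` (per-line `borer_G`, `parrotfish_G`,
#'   `echinoid_G`, `total_erosion_G`, exact component sum) and `shares`
#'   (component percent shares of the summed total across lines).
#' @export
total_bioerosion <- function(observations, rugosity, belts, rates) {
  b <- borer_erosion(observations, rugosity, rates)
  p <- parrotfish_erosion(observations, rugosity, rates)
  meta <- unique(observations[c("line_id", "transect_id", "zone_id")])
  e <- echinoid_erosion_by_line(meta, belts, rates)
  df <- data.frame(
    line_id = meta$line_id,
    transect_id = meta$transect_id,
    zone_id = meta$zone_id,
    borer_G = b$borer_G[match(meta$line_id, b$line_id)],
    parrotfish_G = p$parrotfish_G[match(meta$line_id, p$line_id)],
    echinoid_G = e$echinoid_G[match(meta$line_id, e$line_id)],
    stringsAsFactors = FALSE
  )
  df$total_erosion_G <- df$borer_G + df$parrotfish_G + df$echinoid_G
  totals <- c(borer = sum(df$borer_G), parrotfish = sum(df$parrotfish_G),
              echinoid = sum(df$echinoid_G))
  shares <- if (sum(totals) > 0) 100 * totals / sum(totals) else
    stats::setNames(numeric(0), character(0))
  df <- df[order(df$line_id), ]
  rownames(df) <- NULL
  list(lines = df, shares = shares)
}
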