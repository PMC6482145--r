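#' Read point-intercept benthic observations
#'
#' Reads an `observations.csv` census file with columns
#' `line_id,transect_id,zone_id,position_cm,category,morphology,taxon`.
#' Each 10 m survey line must carry exactly 100 observations at the
#' positions 10, 20, ..., 1000 cm. Every field is validated against the
#' package vocabularies ([benthic_categories()], [coral_morphologies()],
#' [transect_labels()]) and the structural invariants of the census:
#'
#' * positions unique within a line and drawn from the 10 cm grid;
#' * `morphology != "none"` exactly for live-coral points;
#' * complete lines only — a line with fewer or more than 100 points is
#'   an error naming the line and its count.
#'
#' Zone 1 is the sand moat; live coral or CCA recorded there is
#' ecologically implausible but not impossible, so it raises a warning
#' rather than an error.
#'
#' @param path Path to the CSV file.
#' @return A data frame of validated observations (one row per census
#'   point) ordered by line and position.
#' @seealso [write_observations()], [validate_observations()]
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("line_id", "transect_id", "zone_id", "position_cm",
            "category", "morphology", "taxon")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("observations file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[need]
  zone <- suppressWarnings(as.integer(df$zone_id))
  pos <- suppressWarnings(as.integer(df$position_cm))
  bad <- which(is.na(zone) | is.na(pos) | !nzchar(df$line_id))
  if (length(bad) > 0L) {
    stop(sprintf("malformed observation row %d (data row, excluding header)",
                 bad[1L]), call. = FALSE)
  }
  df$zone_id <- zone
  df$position_cm <- pos
  df$taxon[df$taxon == ""] <- NA_character_
  validate_observations(df)
}

#' Validate a benthic observations data frame
#'
#' Applies the same invariant checks as [read_observations()] to an
#' in-memory data frame (e.g. one produced by [generate_reef()]).
#'
#' @param df Data frame with the observations schema.
#' @return The validated data frame, ordered by line and position.
#' @export
validate_observations <- function(df) {
  bad_cat <- setdiff(unique(df$category), benthic_categories())
  if (length(bad_cat) > 0L) {
    stop("unknown category value(s): ", paste(bad_cat, collapse = ", "),
         "; allowed: ", paste(benthic_categories(), collapse = ", "),
         call. = FALSE)
  }
  bad_morph <- setdiff(unique(df$morphology), coral_morphologies())
  if (length(bad_morph) > 0L) {
    stop("unknown morphology value(s): ", paste(bad_morph, collapse = ", "),
         "; allowed: ", paste(coral_morphologies(), collapse = ", "),
         call. = FALSE)
  }
  bad_tr <- setdiff(unique(df$transect_id), transect_labels())
  if (length(bad_tr) > 0L) {
    stop("unknown transect_id value(s): ", paste(bad_tr, collapse = ", "),
         "; allowed: ", paste(transect_labels(), collapse = ", "),
         call. = FALSE)
  }
  if (any(df$zone_id < 1L | df$zone_id > 5L)) {
    stop("zone_id must be an integer between 1 and 5", call. = FALSE)
  }
  if (any(!df$position_cm %in% line_positions())) {
    stop("position_cm must lie on the 10 cm grid 10, 20, ..., 1000",
         call. = FALSE)
  }

  live <- df$category == "live_coral"
  if (any(live & df$morphology == "none")) {
    ln <- df$line_id[live & df$morphology == "none"][1L]
    stop(sprintf("live coral without a growth morphology on line '%s'", ln),
         call. = FALSE)
  }
  if (any(!live & df$morphology != "none")) {
    ln <- df$line_id[!live & df$morphology != "none"][1L]
    stop(sprintf("non-coral observation with a coral morphology on line '%s'",
                 ln), call. = FALSE)
  }

  for (ln in unique(df$line_id)) {
    sub <- df[df$line_id == ln, ]
    if (anyDuplicated(sub$position_cm)) {
      dup <- sub$position_cm[duplicated(sub$position_cm)][1L]
      stop(sprintf("duplicate position %d cm within line '%s'", dup, ln),
           call. = FALSE)
    }
    if (nrow(sub) != 100L) {
      stop(sprintf("incomplete survey line '%s': %d of 100 observations",
                   ln, nrow(sub)), call. = FALSE)
    }
    if (length(unique(sub$transect_id)) != 1L ||
        length(unique(sub$zone_id)) != 1L) {
      stop(sprintf("line '%s' spans multiple transects or zones", ln),
           call. = FALSE)
    }
  }

  moat <- df$zone_id == 1L & df$category %in% c("live_coral", "cca")
  if (any(moat)) {
    warning(sprintf(
      "zone 1 (sand moat) line '%s' records carbonate producers; check zoning",
      df$line_id[moat][1L]), call. = FALSE)
  }

  df <- df[order(df$line_id, df$position_cm), ]
  rownames(df) <- NULL
  df
}

#' @rdname read_observations
#' @param df A validated observations data frame.
#' @export
write_observations <- function(df, path) {
  out <- df
  out$taxon[is.na(out$taxon)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write rugosity chain measurements
#'
#' `rugosity.csv` has columns `line_id,section_index,chain_ratio`: three
#' randomly placed 1 m chain sections per 10 m line, each recorded as
#' substrate surface length divided by 1 m of linear length. A ratio
#' below 1 is physically impossible (the draped chain cannot be shorter
#' than the straight-line distance) and is rejected.
#'
#' @param path Path to the CSV file.
#' @return A data frame with columns `line_id`, `section_index`,
#'   `chain_ratio`.
#' @export
read_rugosity <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line_id", "section_index", "chain_ratio")
  if (!all(need %in% names(df))) {
    stop("rugosity file must have columns line_id,section_index,chain_ratio",
         call. = FALSE)
  }
  df$chain_ratio <- as.numeric(df$chain_ratio)
  validate_rugosity(df[need])
}

#' @rdname read_rugosity
#' @param df A rugosity data frame.
#' @export
validate_rugosity <- function(df) {
  if (anyNA(df$chain_ratio)) {
    stop("non-numeric chain_ratio in rugosity data", call. = FALSE)
  }
  if (any(df$chain_ratio < 1)) {
    ln <- df$line_id[df$chain_ratio < 1][1L]
    stop(sprintf("chain_ratio < 1 on line '%s': surface length cannot be shorter than linear length",
                 ln), call. = FALSE)
  }
  counts <- table(df$line_id)
  if (any(counts != 3L)) {
    ln <- names(counts)[counts != 3L][1L]
    stop(sprintf("line '%s' has %d rugosity sections; exactly 3 required",
                 ln, counts[[ln]]), call. = FALSE)
  }
  df <- df[order(df$line_id, df$section_index), ]
  rownames(df) <- NULL
  df
}

#' @rdname read_rugosity
#' @export
write_rugosity <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write echinoid belt transects
#'
#' `belts.csv` has one row per (belt, genus) with columns
#' `belt_id,transect_id,zone_id,area_m2,genus,test_size_mm,count`. Belts
#' are 30 m by 2 m swaths surveyed for urchins; `test_size_mm` is the
#' mean skeletal test diameter of the counted individuals of that genus
#' (1--200 mm), and `count` may be zero (the row then records an urchin-
#' free belt).
#'
#' @param path Path to the CSV file.
#' @return A data frame of belt records.
#' @export
read_belts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("belt_id", "transect_id", "zone_id", "area_m2", "genus",
            "test_size_mm", "count")
  if (!all(need %in% names(df))) {
    stop("belts file must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  df <- df[need]
  df$area_m2 <- as.numeric(df$area_m2)
  df$test_size_mm <- as.numeric(df$test_size_mm)
  df$count <- as.integer(df$count)
  df$zone_id <- as.integer(df$zone_id)
  validate_belts(df)
}

#' @rdname read_belts
#' @param df A belts data frame.
#' @export
validate_belts <- function(df) {
  if (any(is.na(df$area_m2) | df$area_m2 <= 0)) {
    stop("belt area_m2 must be a positive number", call. = FALSE)
  }
  if (any(is.na(df$test_size_mm) | df$test_size_mm < 1 |
            df$test_size_mm > 200)) {
    stop("test_size_mm must lie within 1-200 mm", call. = FALSE)
  }
  if (any(is.na(df$count) | df$count < 0)) {
    stop("count must be a non-negative integer", call. = FALSE)
  }
  bad_gen <- setdiff(unique(df$genus), echinoid_genera())
  if (length(bad_gen) > 0L) {
    stop("unknown echinoid genus: ", paste(bad_gen, collapse = ", "),
         "; allowed: ", paste(echinoid_genera(), collapse = ", "),
         call. = FALSE)
  }
  area_per_belt <- tapply(df$area_m2, df$belt_id, function(x) length(unique(x)))
  if (any(area_per_belt != 1L)) {
    stop("inconsistent area_m2 within a belt", call. = FALSE)
  }
  df <- df[order(df$belt_id, df$genus), ]
  rownames(df) <- NULL
  df
}

#' @rdname read_belts
#' @export
write_belts <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
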