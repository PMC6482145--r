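#' Line-scale net carbonate budgets
#'
#' Runs the full budget on each survey line: gross production from cover,
#' rugosity and calcification rates; the three bioerosion components; and
#' net production as their exact difference. This is the atomic result
#' everything else aggregates.
#'
#' @inheritParams gross_production
#' @param belts Echinoid belt data frame (may be empty; the echinoid term
#'   is then zero).
#' @return Data frame with one row per line and columns `scope`
#'   (`"line"`), `line_id`, `transect_id`, `zone_id`, `live_cover_pct`,
#'   `rugosity`, `f_avail`, `gross_G`, `borer_G`, `parrotfish_G`,
#'   `echinoid_G`, `total_erosion_G`, `net_G`. The identities
#'   `net_G = gross_G - total_erosion_G` and
#'   `total_erosion_G = borer_G + parrotfish_G + echinoid_G` hold exactly
#'   on every row.
#' @examples
#' reef <- generate_reef(default_mahutigala_scenario(), seed = 1)
#' lb <- line_budgets(reef$observations, reef$rugosity, reef$belts,
#'                    default_rate_table())
#' head(lb[c("line_id", "gross_G", "total_erosion_G", "net_G")])
#' @seealso [aggregate_budget()], [cover_threshold()]
#' @export
line_budgets <- function(observations, rugosity, belts, rates) {
  gp <- gross_production(observations, rugosity, rates)
  er <- total_bioerosion(observations, rugosity, belts, rates)
  cov <- percent_cover(observations, by = "category")
  live <- cov[cov$category == "live_coral", ]
  fa <- available_substrate_fraction(observations)

  df <- gp$lines
  df$live_cover_pct <- live$percent[match(df$line_id, live$line_id)]
  df$f_avail <- fa$f_avail[match(df$line_id, fa$line_id)]
  idx <- match(df$line_id, er$lines$line_id)
  df$borer_G <- er$lines$borer_G[idx]
  df$parrotfish_G <- er$lines$parrotfish_G[idx]
  df$echinoid_G <- er$lines$echinoid_G[idx]
  df$total_erosion_G <- er$lines$total_erosion_G[idx]
  df$net_G <- df$gross_G - df$total_erosion_G
  df$scope <- "line"
  cols <- c("scope", "line_id", "transect_id", "zone_id", "live_cover_pct",
            "rugosity", "f_avail", "gross_G", "borer_G", "parrotfish_G",
            "echinoid_G", "total_erosion_G", "net_G")
  df <- df[cols]
  rownames(df) <- NULL
  df
}

#' Aggregate line budgets to zone, transect or reef scale
#'
#' Reports the unweighted arithmetic mean and sample (n-1) standard
#' deviation of every budget quantity within each group:
#'
#' * `"zone"` — lines grouped by (transect, zone): the replicate survey
#'   lines of one eco-geomorphic zone crossing of one radial transect;
#' * `"transect"` — all productive-zone lines of a radial transect;
#' * `"reef"` — by default the mean (and SD) of the transect means, the
#'   convention for a reef-wide figure built from radial transects;
#'   `reef_method = "pooled_lines"` averages the lines directly instead.
#'
#' Sand-moat lines (zone 1) carry no carbonate producers and are excluded
#' from every aggregate.
#'
#' Because the mean is linear, the exact accounting identities of
#' [line_budgets()] (net = gross - total erosion; total = sum of
#' components) carry over to the means at every scale.
#'
#' @param lines Line-scope data frame from [line_budgets()].
#' @param level `"zone"`, `"transect"` or `"reef"`.
#' @param reef_method For `level = "reef"`: `"transect_means"` (default)
#'   or `"pooled_lines"`.
#' @return Data frame with one row per group: identifiers, `n_lines`,
#'   and `<quantity>_mean` / `<quantity>_sd` columns for live cover,
#'   rugosity, gross, the three erosion components, total erosion and
#'   net. SDs are `NA` for single-member groups.
#' @export
aggregate_budget <- function(lines,
                             level = c("zone", "transect", "reef"),
                             reef_method = c("transect_means",
                                             "pooled_lines")) {
  level <- match.arg(level)
  reef_method <- match.arg(reef_method)
  lines <- lines[lines$zone_id != 1L, , drop = FALSE]
  if (nrow(lines) == 0L) {
    stop("no productive-zone (zone > 1) lines to aggregate", call. = FALSE)
  }
  vars <- c("live_cover_pct", "rugosity", "gross_G", "borer_G",
            "parrotfish_G", "echinoid_G", "total_erosion_G", "net_G")

  summarise_group <- function(sub, ids) {
    out <- c(ids, list(n_lines = nrow(sub)))
    for (v in vars) {
      out[[paste0(v, "_mean")]] <- mean(sub[[v]])
      out[[paste0(v, "_sd")]] <- if (nrow(sub) > 1L) stats::sd(sub[[v]])
        else NA_real_
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  }

  if (level == "zone") {
    groups <- unique(lines[c("transect_id", "zone_id")])
    res <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
      sub <- lines[lines$transect_id == groups$transect_id[i] &
                     lines$zone_id == groups$zone_id[i], ]
      summarise_group(sub, list(scope = "zone",
                                transect_id = groups$transect_id[i],
                                zone_id = groups$zone_id[i]))
    }))
  } else if (level == "transect") {
    res <- do.call(rbind, lapply(unique(lines$transect_id), function(tr) {
      sub <- lines[lines$transect_id == tr, ]
      summarise_group(sub, list(scope = "transect", transect_id = tr,
                                zone_id = NA_integer_))
    }))
  } else {
    if (reef_method == "pooled_lines") {
      res <- summarise_group(lines, list(scope = "reef",
                                         transect_id = NA_character_,
                                         zone_id = NA_integer_))
    } else {
      tr <- aggregate_budget(lines, level = "transect")
      out <- list(scope = "reef", transect_id = NA_character_,
                  zone_id = NA_integer_, n_lines = sum(tr$n_lines))
      for (v in vars) {
        m <- tr[[paste0(v, "_mean")]]
        out[[paste0(v, "_mean")]] <- mean(m)
        out[[paste0(v, "_sd")]] <- if (length(m) > 1L) stats::sd(m)
          else NA_real_
      }
      res <- as.data.frame(out, stringsAsFactors = FALSE)
    }
  }
  ord <- if (level == "zone") order(res$transect_id, res$zone_id)
    else seq_len(nrow(res))
  res <- res[ord, ]
  rownames(res) <- NULL
  res
}

#' Write a budget table to CSV
#'
#' Writes line- or aggregate-scope budget results in a flat CSV layout.
#'
#' @param budget Data frame from [line_budgets()] or [aggregate_budget()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_budget <- function(budget, path) {
  utils::write.csv(budget, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
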