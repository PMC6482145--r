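#' Define a zone profile for synthetic surveys
#'
#' A zone profile is the generative description of one eco-geomorphic
#' zone: the multinomial distribution of benthic categories under the
#' census points, the (taxon, morphology) mixture of live coral, the
#' rugosity distribution (normal truncated at 1), and the urchin
#' community (density, genus mixture and per-genus test-size means).
#'
#' @param zone_id Integer zone label, 1--5.
#' @param category_probs Named numeric vector over (a subset of)
#'   [benthic_categories()], summing to 1.
#' @param live_coral_mix Data frame `taxon`, `morphology`, `prob`
#'   (probabilities summing to 1). Required when the live-coral
#'   probability is positive.
#' @param rugosity_mean,rugosity_sd Mean and SD of the chain-section
#'   distribution before truncation at 1; `rugosity_mean >= 1`.
#' @param urchin_density_per_m2 Expected urchins per m2 (all genera).
#' @param urchin_genus_mix Named probability vector over
#'   [echinoid_genera()].
#' @param urchin_test_mean_mm Named vector of mean test sizes (mm) per
#'   genus.
#' @return An object of class `zone_profile`.
#' @seealso [default_mahutigala_scenario()], [generate_reef()]
#' @export
zone_profile <- function(zone_id, category_probs, live_coral_mix = NULL,
                         rugosity_mean = 2, rugosity_sd = 0.3,
                         urchin_density_per_m2 = 0,
                         urchin_genus_mix = c(Diadema = 0.5,
                                              Phyllocanthus = 0.5),
                         urchin_test_mean_mm = c(Diadema = 30,
                                                 Phyllocanthus = 90)) {
  bad <- setdiff(names(category_probs), benthic_categories())
  if (length(bad) > 0L) {
    stop("unknown category in category_probs: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(category_probs < 0) ||
      abs(sum(category_probs) - 1) > 1e-8) {
    stop("category_probs must be non-negative and sum to 1", call. = FALSE)
  }
  full <- stats::setNames(numeric(length(benthic_categories())),
                          benthic_categories())
  full[names(category_probs)] <- category_probs
  p_live <- full[["live_coral"]]
  if (p_live > 0) {
    if (is.null(live_coral_mix)) {
      stop("live_coral_mix required when live coral probability > 0",
           call. = FALSE)
    }
    live_coral_mix <- as.data.frame(live_coral_mix,
                                    stringsAsFactors = FALSE)
    if (!all(c("taxon", "morphology", "prob") %in% names(live_coral_mix))) {
      stop("live_coral_mix needs columns taxon, morphology, prob",
           call. = FALSE)
    }
    if (any(live_coral_mix$prob < 0) ||
        abs(sum(live_coral_mix$prob) - 1) > 1e-8) {
      stop("live_coral_mix probabilities must be non-negative and sum to 1",
           call. = FALSE)
    }
    if (any(!live_coral_mix$morphology %in%
              setdiff(coral_morphologies(), "none"))) {
      stop("live_coral_mix morphologies must be coral growth forms",
           call. = FALSE)
    }
  }
  if (rugosity_mean < 1) stop("rugosity_mean must be >= 1", call. = FALSE)
  if (rugosity_sd < 0) stop("rugosity_sd must be >= 0", call. = FALSE)
  if (urchin_density_per_m2 < 0) {
    stop("urchin_density_per_m2 must be >= 0", call. = FALSE)
  }
  if (abs(sum(urchin_genus_mix) - 1) > 1e-8 || any(urchin_genus_mix < 0)) {
    stop("urchin_genus_mix must be non-negative and sum to 1", call. = FALSE)
  }
  structure(
    list(zone_id = as.integer(zone_id), category_probs = full,
         live_coral_mix = live_coral_mix, rugosity_mean = rugosity_mean,
         rugosity_sd = rugosity_sd,
         urchin_density_per_m2 = urchin_density_per_m2,
         urchin_genus_mix = urchin_genus_mix,
         urchin_test_mean_mm = urchin_test_mean_mm),
    class = "zone_profile")
}

#' Define a synthetic reef survey scenario
#'
#' A scenario fixes everything the generator needs: the zone profiles,
#' which zones each radial transect crosses, replication (survey lines
#' per zone crossing, belts per zone crossing), belt geometry, test-size
#' dispersion and truncation classes, within-line patchiness and the
#' random seed. The same scenario and seed always regenerate the same
#' dataset.
#'
#' @param zone_profiles List of [zone_profile()] objects.
#' @param zones_by_transect Named list mapping each transect label to the
#'   integer zones it crosses.
#' @param lines_per_zone Replicate 10 m survey lines per (transect, zone)
#'   crossing (default 3).
#' @param belt_transects Transects carrying echinoid belt surveys.
#' @param belts_per_zone Replicate belts per surveyed (transect, zone)
#'   crossing (default 2).
#' @param belt_length_m,belt_width_m Belt geometry (default 30 m x 2 m).
#' @param test_size_sd_mm SD of individual test sizes around the genus
#'   mean (default 4 mm).
#' @param test_size_range_mm Named list of `c(min, max)` truncation
#'   ranges per genus; sizes are redrawn until inside the class range.
#' @param patchiness Probability (0--1) that a census point repeats the
#'   previous point's category instead of a fresh multinomial draw
#'   (first-order Markov persistence along the tape). Default 0:
#'   independent points.
#' @param seed Default random seed for [generate_reef()].
#' @return An object of class `reef_scenario`.
#' @export
reef_scenario <- function(zone_profiles, zones_by_transect,
                          lines_per_zone = 3,
                          belt_transects = c("SW", "NW", "NE", "SE"),
                          belts_per_zone = 2,
                          belt_length_m = 30, belt_width_m = 2,
                          test_size_sd_mm = 4,
                          test_size_range_mm = list(
                            Diadema = c(21, 40),
                            Phyllocanthus = c(81, 100)),
                          patchiness = 0,
                          seed = 1L) {
  stopifnot(all(vapply(zone_profiles, inherits, logical(1), "zone_profile")))
  ids <- vapply(zone_profiles, `[[`, integer(1), "zone_id")
  names(zone_profiles) <- as.character(ids)
  bad_tr <- setdiff(names(zones_by_transect), transect_labels())
  if (length(bad_tr) > 0L) {
    stop("unknown transect label(s): ", paste(bad_tr, collapse = ", "),
         call. = FALSE)
  }
  used <- unique(unlist(zones_by_transect))
  miss <- setdiff(used, ids)
  if (length(miss) > 0L) {
    stop("zones_by_transect references zone(s) without a profile: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (patchiness < 0 || patchiness >= 1) {
    stop("patchiness must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(zone_profiles = zone_profiles,
         zones_by_transect = zones_by_transect,
         lines_per_zone = as.integer(lines_per_zone),
         belt_transects = belt_transects,
         belts_per_zone = as.integer(belts_per_zone),
         belt_length_m = belt_length_m, belt_width_m = belt_width_m,
         test_size_sd_mm = test_size_sd_mm,
         test_size_range_mm = test_size_range_mm,
         patchiness = patchiness, seed = as.integer(seed)),
    class = "reef_scenario")
}

#' Default lagoonal reef-platform scenario
#'
#' A fully specified scenario emulating a small Maldivian lagoonal reef
#' platform four months after a mass bleaching event: five eco-geomorphic
#' zones (sand moat, patch reef, inner reef flat, two outer reef-flat
#' zones), seven radial transects each crossing three productive zones
#' with three replicate lines per crossing (63 lines, 6300 census
#' points), a massive-dominated live-coral community (massive 66%,
#' branching 13%, *Heliopora* 13%, other growth forms 8%), rugosity
#' around 1.9--2.9, sparse urchins (0.1 ind. per m2; mean test sizes
#' 30 mm *Diadema*, 90 mm *Phyllocanthus*) and belt surveys on four of
#' the seven transects. Zone compositions are set to the midpoints of
#' the cover ranges characteristic of each zone type; they are a
#' synthetic stand-in, not field data.
#'
#' @param lines_per_zone Replicate lines per (transect, zone) crossing;
#'   default 3.
#' @param seed Default seed carried by the scenario.
#' @return A [reef_scenario()].
#' @examples
#' sc <- default_mahutigala_scenario()
#' length(sc$zones_by_transect)  # 7 radial transects
#' @export
default_mahutigala_scenario <- function(lines_per_zone = 3, seed = 1L) {
  mix <- data.frame(
    taxon = c("Porites", "Acropora", "Heliopora",
              "Montipora", "Porites", "Acropora", "Fungia"),
    morphology = c("massive", "branching", "branching",
                   "encrusting", "digitate", "tabular", "free_living"),
    prob = c(0.66, 0.13, 0.13, 0.03, 0.02, 0.02, 0.01),
    stringsAsFactors = FALSE)

  profiles <- list(
    # sand moat: no primary or secondary carbonate producers
    zone_profile(1, c(sand = 0.95, rubble = 0.05),
                 rugosity_mean = 1.1, rugosity_sd = 0.05,
                 urchin_density_per_m2 = 0),
    # patch reef over a sand/rubble plain
    zone_profile(2, c(live_coral = 0.15, dead_coral = 0.10, cca = 0.03,
                      turf_algae = 0.02, sand = 0.40, rubble = 0.30),
                 live_coral_mix = mix,
                 rugosity_mean = 2.2, rugosity_sd = 0.3,
                 urchin_density_per_m2 = 0.1),
    # inner reef flat: open dead-coral framework, massive live coral
    zone_profile(3, c(live_coral = 0.175, dead_coral = 0.30, cca = 0.05,
                      turf_algae = 0.05, sand = 0.375, rubble = 0.05),
                 live_coral_mix = mix,
                 rugosity_mean = 2.6, rugosity_sd = 0.3,
                 urchin_density_per_m2 = 0.1),
    # outer reef flat: dense dead framework under turf/CCA
    zone_profile(4, c(live_coral = 0.20, dead_coral = 0.25,
                      reef_framework = 0.15, cca = 0.07, turf_algae = 0.13,
                      macroalgae = 0.05, sand = 0.10, rubble = 0.05),
                 live_coral_mix = mix,
                 rugosity_mean = 2.8, rugosity_sd = 0.3,
                 urchin_density_per_m2 = 0.1),
    zone_profile(5, c(live_coral = 0.18, dead_coral = 0.30,
                      reef_framework = 0.15, cca = 0.08, turf_algae = 0.12,
                      macroalgae = 0.04, sand = 0.08, rubble = 0.05),
                 live_coral_mix = mix,
                 rugosity_mean = 2.6, rugosity_sd = 0.3,
                 urchin_density_per_m2 = 0.1)
  )
  zones <- list(
    SW = c(2, 3, 4), W = c(2, 3, 4), NW = c(2, 4, 5), N = c(2, 4, 5),
    NE = c(2, 3, 5), E = c(2, 3, 5), SE = c(3, 4, 5)
  )
  reef_scenario(profiles, zones, lines_per_zone = lines_per_zone,
                seed = seed)
}

#' Generate a synthetic reef survey dataset
#'
#' Draws a complete survey dataset from a scenario: for every survey
#' line 100 census points from the zone's category distribution (with
#' optional Markov patchiness along the tape), (taxon, morphology)
#' labels for live-coral points from the zone's coral mixture, three
#' rugosity chain sections from a normal truncated at 1, and for every
#' belt per-genus urchin counts from Poisson(density x area x genus
#' share) with test sizes jittered around the genus mean and truncated
#' to the genus size class. The draw is fully reproducible: the same
#' scenario and seed give identical output.
#'
#' @param scenario A [reef_scenario()].
#' @param seed Integer seed; defaults to the scenario's own.
#' @return A list of class `reef_dataset`: `observations`, `rugosity`
#'   and `belts` data frames (the survey inputs) plus `truth`, a record
#'   of every generative parameter and the per-zone expectations implied
#'   by them, for parameter-recovery checks.
#' @examples
#' reef <- generate_reef(default_mahutigala_scenario(), seed = 7)
#' nrow(reef$observations)  # 63 lines x 100 points
#' @export
generate_reef <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "reef_scenario"))
  set.seed(as.integer(seed))
  cats <- benthic_categories()

  obs_list <- list()
  rug_list <- list()
  for (tr in names(scenario$zones_by_transect)) {
    for (z in scenario$zones_by_transect[[tr]]) {
      prof <- scenario$zone_profiles[[as.character(z)]]
      for (rep in seq_len(scenario$lines_per_zone)) {
        line_id <- sprintf("%s-Z%d-L%d", tr, z, rep)
        category <- draw_line_categories(prof$category_probs,
                                         scenario$patchiness)
        morph <- rep("none", 100L)
        taxon <- rep(NA_character_, 100L)
        live <- which(category == "live_coral")
        if (length(live) > 0L) {
          mix <- prof$live_coral_mix
          pick <- sample.int(nrow(mix), length(live), replace = TRUE,
                             prob = mix$prob)
          morph[live] <- mix$morphology[pick]
          taxon[live] <- mix$taxon[pick]
        }
        obs_list[[line_id]] <- data.frame(
          line_id = line_id, transect_id = tr, zone_id = as.integer(z),
          position_cm = line_positions(), category = category,
          morphology = morph, taxon = taxon, stringsAsFactors = FALSE)
        rug_list[[line_id]] <- data.frame(
          line_id = line_id, section_index = 1:3,
          chain_ratio = rtrunc_norm(3L, prof$rugosity_mean,
                                    prof$rugosity_sd, lower = 1),
          stringsAsFactors = FALSE)
      }
    }
  }
  observations <- do.call(rbind, obs_list)
  rownames(observations) <- NULL
  rugosity <- do.call(rbind, rug_list)
  rownames(rugosity) <- NULL

  belt_area <- scenario$belt_length_m * scenario$belt_width_m
  belt_list <- list()
  for (tr in intersect(scenario$belt_transects,
                       names(scenario$zones_by_transect))) {
    for (z in setdiff(scenario$zones_by_transect[[tr]], 1L)) {
      prof <- scenario$zone_profiles[[as.character(z)]]
      for (rep in seq_len(scenario$belts_per_zone)) {
        belt_id <- sprintf("%s-Z%d-B%d", tr, z, rep)
        for (g in names(prof$urchin_genus_mix)) {
          lambda <- prof$urchin_density_per_m2 * belt_area *
            prof$urchin_genus_mix[[g]]
          count <- stats::rpois(1L, lambda)
          rng <- scenario$test_size_range_mm[[g]]
          ts <- if (count > 0L) {
            mean(rtrunc_norm(count, prof$urchin_test_mean_mm[[g]],
                             scenario$test_size_sd_mm,
                             lower = rng[1L], upper = rng[2L]))
          } else prof$urchin_test_mean_mm[[g]]
          belt_list[[paste(belt_id, g)]] <- data.frame(
            belt_id = belt_id, transect_id = tr, zone_id = as.integer(z),
            area_m2 = belt_area, genus = g, test_size_mm = ts,
            count = count, stringsAsFactors = FALSE)
        }
      }
    }
  }
  belts <- if (length(belt_list) > 0L) do.call(rbind, belt_list) else
    data.frame(belt_id = character(0), transect_id = character(0),
               zone_id = integer(0), area_m2 = numeric(0),
               genus = character(0), test_size_mm = numeric(0),
               count = integer(0), stringsAsFactors = FALSE)
  rownames(belts) <- NULL

  truth <- scenario_truth(scenario, seed)
  structure(list(observations = validate_observations(observations),
                 rugosity = validate_rugosity(rugosity),
                 belts = validate_belts(belts), truth = truth),
            class = "reef_dataset")
}

# one line's categories, optionally with Markov persistence along the tape
draw_line_categories <- function(probs, patchiness) {
  cats <- names(probs)
  if (patchiness <= 0) {
    return(sample(cats, 100L, replace = TRUE, prob = probs))
  }
  out <- character(100L)
  out[1L] <- sample(cats, 1L, prob = probs)
  persist <- stats::runif(99L) < patchiness
  fresh <- sample(cats, 99L, replace = TRUE, prob = probs)
  for (j in 2:100) {
    out[j] <- if (persist[j - 1L]) out[j - 1L] else fresh[j - 1L]
  }
  out
}

# normal draw truncated to [lower, upper] by rejection
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1L, mean, sd)
      if (x >= lower && x <= upper) break
    }
    out[i] <- x
  }
  out
}

#' Mean of a normal distribution truncated below
#'
#' Closed-form mean of N(mean, sd) conditioned on exceeding `lower`; the
#' expectation of a generated rugosity chain section.
#'
#' @param mean,sd Parameters of the parent normal.
#' @param lower Truncation point (default 1, the rugosity floor).
#' @return The truncated mean.
#' @export
truncated_normal_mean <- function(mean, sd, lower = 1) {
  if (sd == 0) return(max(mean, lower))
  a <- (lower - mean) / sd
  mean + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

# the machine-readable record of what the generator was asked to do
scenario_truth <- function(scenario, seed) {
  zones <- lapply(scenario$zone_profiles, function(p) {
    list(zone_id = p$zone_id,
         category_probs = as.list(p$category_probs),
         live_coral_mix = p$live_coral_mix,
         rugosity_mean = p$rugosity_mean, rugosity_sd = p$rugosity_sd,
         expected_rugosity = truncated_normal_mean(p$rugosity_mean,
                                                   p$rugosity_sd),
         expected_live_cover_pct = 100 * p$category_probs[["live_coral"]],
         urchin_density_per_m2 = p$urchin_density_per_m2,
         urchin_genus_mix = as.list(p$urchin_genus_mix),
         urchin_test_mean_mm = as.list(p$urchin_test_mean_mm))
  })
  list(seed = as.integer(seed),
       lines_per_zone = scenario$lines_per_zone,
       zones_by_transect = scenario$zones_by_transect,
       belt_transects = scenario$belt_transects,
       belts_per_zone = scenario$belts_per_zone,
       belt_area_m2 = scenario$belt_length_m * scenario$belt_width_m,
       patchiness = scenario$patchiness,
       zone_profiles = zones)
}

#' Closed-form expectations for a scenario under given rates
#'
#' The analytically expected per-line quantities implied by a scenario's
#' zone profiles and a rate table, independent of any simulation: for
#' each zone, expected live cover, expected rugosity (truncated-normal
#' mean), expected gross production
#' \eqn{E[R] \sum_i E[X_i]/100 \cdot C_i \cdot 10}
#' (valid because rugosity and composition are drawn independently),
#' expected available-substrate fraction and the implied borer and
#' parrotfish terms; and the reef-scope expectations under the
#' transect-means aggregation convention. Echinoid erosion is excluded
#' (it is belt-derived and, at realistic densities, orders of magnitude
#' below the other terms).
#'
#' @param scenario A [reef_scenario()].
#' @param rates A [rate_table()].
#' @return A list: `zones` (per-zone expectations) and `reef`
#'   (reef-scope expected live cover, rugosity, gross, borer and
#'   parrotfish G, averaging transect means over productive zones).
#' @export
expected_budget <- function(scenario, rates) {
  stopifnot(inherits(scenario, "reef_scenario"),
            inherits(rates, "rate_table"))
  sets <- category_sets()
  zl <- lapply(scenario$zone_profiles, function(p) {
    ER <- truncated_normal_mean(p$rugosity_mean, p$rugosity_sd)
    p_live <- p$category_probs[["live_coral"]]
    p_cca <- p$category_probs[["cca"]]
    egross <- 0
    if (p_live > 0) {
      ci <- lookup_ci(rates, p$live_coral_mix$taxon,
                      p$live_coral_mix$morphology)
      egross <- egross + sum(p_live * p$live_coral_mix$prob * ci * 10)
    }
    if (p_cca > 0) {
      egross <- egross + p_cca * lookup_ci(rates, "CCA", "none") * 10
    }
    egross <- ER * egross
    f_avail <- sum(p$category_probs[sets$available_substrate])
    data.frame(
      zone_id = p$zone_id,
      live_cover_pct = 100 * p_live,
      rugosity = ER,
      f_avail = f_avail,
      gross_G = egross,
      borer_G = ER * f_avail *
        (rates$macro_borer_rate + rates$micro_borer_rate),
      parrotfish_G = rates$parrotfish_rate * f_avail *
        (if (rates$parrotfish_use_rugosity) ER else 1),
      stringsAsFactors = FALSE)
  })
  zones <- do.call(rbind, zl)
  rownames(zones) <- NULL

  vars <- c("live_cover_pct", "rugosity", "f_avail", "gross_G",
            "borer_G", "parrotfish_G")
  tr_means <- lapply(names(scenario$zones_by_transect), function(tr) {
    zs <- setdiff(scenario$zones_by_transect[[tr]], 1L)
    colMeans(zones[zones$zone_id %in% zs, vars, drop = FALSE])
  })
  reef <- as.list(colMeans(do.call(rbind, tr_means)))
  list(zones = zones, reef = reef)
}

#' Write a synthetic reef dataset to disk
#'
#' Writes the four survey files a budget analysis consumes —
#' `observations.csv`, `rugosity.csv`, `belts.csv` — plus `truth.json`,
#' the generator's ground-truth record.
#'
#' @param reef A `reef_dataset` from [generate_reef()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_reef_dataset <- function(reef, dir) {
  stopifnot(inherits(reef, "reef_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_observations(reef$observations, file.path(dir, "observations.csv"))
  write_rugosity(reef$rugosity, file.path(dir, "rugosity.csv"))
  write_belts(reef$belts, file.path(dir, "belts.csv"))
  jsonlite::write_json(reef$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.reef_dataset <- function(x, ...) {
  cat("<reef_dataset>\n")
  cat(sprintf("  %d survey lines (%d observations) on %d transects\n",
              length(unique(x$observations$line_id)),
              nrow(x$observations),
              length(unique(x$observations$transect_id))))
  cat(sprintf("  %d echinoid belt records on %d belts\n",
              nrow(x$belts), length(unique(x$belts$belt_id))))
  invisible(x)
}

#' @export
print.reef_scenario <- function(x, ...) {
  n_cells <- sum(lengths(x$zones_by_transect))
  cat("<reef_scenario>\n")
  cat(sprintf("  %d transects, %d zone crossings, %d lines per crossing (%d lines)\n",
              length(x$zones_by_transect), n_cells, x$lines_per_zone,
              n_cells * x$lines_per_zone))
  cat(sprintf("  zone profiles: %s\n",
              paste(names(x$zone_profiles), collapse = ", ")))
  cat(sprintf("  belts on: %s\n", paste(x$belt_transects, collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
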