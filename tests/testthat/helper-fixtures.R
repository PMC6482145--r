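# Fixture builders and a brute-force budget oracle. The oracle walks every
# observation and belt record with explicit loops and its own hard-coded
# category sets and formulas, so it shares no code path with the package
# functions it cross-checks.

make_line <- function(line_id = "L1", transect = "N", zone = 3L,
                      category = "sand", morphology = NULL, taxon = NULL) {
  category <- rep_len(category, 100L)
  if (is.null(morphology)) {
    morphology <- ifelse(category == "live_coral", "massive", "none")
  } else {
    morphology <- rep_len(morphology, 100L)
  }
  if (is.null(taxon)) {
    taxon <- ifelse(category == "live_coral", "Porites", NA_character_)
  } else {
    taxon <- rep_len(taxon, 100L)
  }
  data.frame(line_id = line_id, transect_id = transect,
             zone_id = as.integer(zone), position_cm = seq(10L, 1000L, 10L),
             category = category, morphology = morphology, taxon = taxon,
             stringsAsFactors = FALSE)
}

make_rugosity <- function(line_id = "L1", sections = c(2, 2, 2)) {
  data.frame(line_id = line_id, section_index = 1:3,
             chain_ratio = sections, stringsAsFactors = FALSE)
}

flat_rates <- function(ci = 1.0, ...) {
  rate_table(
    data.frame(taxon = c(NA, NA, NA, NA, NA, NA, "CCA"),
               morphology = c("massive", "branching", "tabular", "digitate",
                              "encrusting", "free_living", "none"),
               ci_g_cm2_yr = ci, stringsAsFactors = FALSE),
    ...)
}

no_belts <- function() {
  data.frame(belt_id = character(0), transect_id = character(0),
             zone_id = integer(0), area_m2 = numeric(0),
             genus = character(0), test_size_mm = numeric(0),
             count = integer(0), stringsAsFactors = FALSE)
}

# A small randomised scenario for property tests; every probability and
# rate is drawn fresh so repeated calls explore different compositions.
random_scenario <- function(n_transects = 2, n_zones = 2, lines_per_zone = 1) {
  taxa <- data.frame(
    taxon = c("Porites", "Acropora", "Heliopora"),
    morphology = c("massive", "branching", "branching"),
    stringsAsFactors = FALSE)
  profiles <- lapply(seq_len(n_zones) + 1L, function(z) {
    w <- stats::rgamma(9, shape = 1)
    p <- w / sum(w)
    names(p) <- benthic_categories()
    mw <- stats::rgamma(3, shape = 1)
    mix <- cbind(taxa, data.frame(prob = mw / sum(mw)))
    zone_profile(z, p, live_coral_mix = mix,
                 rugosity_mean = stats::runif(1, 1.2, 3),
                 rugosity_sd = stats::runif(1, 0.05, 0.4),
                 urchin_density_per_m2 = stats::runif(1, 0, 0.5))
  })
  trs <- transect_labels()[seq_len(n_transects)]
  zones <- stats::setNames(
    rep(list(seq_len(n_zones) + 1L), n_transects), trs)
  reef_scenario(profiles, zones, lines_per_zone = lines_per_zone,
                belt_transects = trs[1L],
                seed = sample.int(1e6, 1))
}

oracle_lookup_ci <- function(rates, taxon, morphology) {
  calc <- rates$calcification
  for (i in seq_len(nrow(calc))) {
    if (!is.na(calc$taxon[i]) && !is.na(taxon) &&
        calc$taxon[i] == taxon && calc$morphology[i] == morphology) {
      return(calc$ci_g_cm2_yr[i])
    }
  }
  for (i in seq_len(nrow(calc))) {
    if (is.na(calc$taxon[i]) && calc$morphology[i] == morphology) {
      return(calc$ci_g_cm2_yr[i])
    }
  }
  stop("oracle: unresolvable rate")
}

# per-belt echinoid rate by direct evaluation
oracle_belt_rates <- function(belts, rates) {
  ids <- unique(belts$belt_id)
  out <- data.frame(belt_id = ids, transect_id = NA, zone_id = NA,
                    rate = 0, stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    rows <- which(belts$belt_id == ids[k])
    out$transect_id[k] <- belts$transect_id[rows[1]]
    out$zone_id[k] <- belts$zone_id[rows[1]]
    total <- 0
    for (i in rows) {
      cf <- rates$echinoid_coeffs
      j <- which(cf$genus == belts$genus[i])
      e <- belts$count[i] / belts$area_m2[i]
      total <- total +
        (((cf$a[j] * belts$test_size_mm[i]^cf$b[j]) * e) * 365 / 60) / 1000
    }
    out$rate[k] <- total
  }
  out
}

# full line-scope budget recomputed from raw records
oracle_line_budget <- function(obs, rug, belts, rates) {
  avail_set <- c("live_coral", "reef_framework", "dead_coral", "rubble")
  lines <- sort(unique(obs$line_id))
  br <- if (nrow(belts) > 0) oracle_belt_rates(belts, rates) else NULL
  res <- NULL
  for (ln in lines) {
    sub <- obs[obs$line_id == ln, ]
    R <- mean(rug$chain_ratio[rug$line_id == ln])
    n_avail <- 0
    gross <- 0
    keys <- list()
    for (i in seq_len(nrow(sub))) {
      if (sub$category[i] %in% avail_set) n_avail <- n_avail + 1
      if (sub$category[i] == "live_coral") {
        k <- paste(sub$taxon[i], sub$morphology[i], sep = "|")
        keys[[k]] <- c(keys[[k]],
                       oracle_lookup_ci(rates, sub$taxon[i],
                                        sub$morphology[i]))
      } else if (sub$category[i] == "cca") {
        keys[["CCA|none"]] <- c(keys[["CCA|none"]],
                                oracle_lookup_ci(rates, "CCA", "none"))
      }
    }
    for (k in names(keys)) {
      n_k <- length(keys[[k]])
      ci <- keys[[k]][1]
      gross <- gross + R * (n_k / 100) * ((ci * 10000) / 1000)
    }
    f <- n_avail / 100
    borer <- R * f * (rates$macro_borer_rate + rates$micro_borer_rate)
    parrot <- rates$parrotfish_rate * f *
      (if (rates$parrotfish_use_rugosity) R else 1)
    ech <- 0
    if (!is.null(br)) {
      tz <- br$transect_id == sub$transect_id[1] &
        br$zone_id == sub$zone_id[1]
      tt <- br$transect_id == sub$transect_id[1]
      ech <- if (any(tz)) mean(br$rate[tz]) else
        if (any(tt)) mean(br$rate[tt]) else mean(br$rate)
    }
    res <- rbind(res, data.frame(
      line_id = ln, gross_G = gross, borer_G = borer,
      parrotfish_G = parrot, echinoid_G = ech,
      total_erosion_G = borer + parrot + ech,
      net_G = gross - (borer + parrot + ech),
      stringsAsFactors = FALSE))
  }
  res
}
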