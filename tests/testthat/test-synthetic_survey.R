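test_that("the default scenario encodes the study design", {
  sc <- default_mahutigala_scenario()
  # seven radial transects, three replicate lines per productive zone
  expect_setequal(names(sc$zones_by_transect), transect_labels())
  expect_identical(sc$lines_per_zone, 3L)
  # sand moat: no primary or secondary producers
  z1 <- sc$zone_profiles[["1"]]
  expect_identical(z1$category_probs[["live_coral"]], 0)
  expect_identical(z1$category_probs[["cca"]], 0)
  # productive-zone coral mix is massive-dominated
  z3 <- sc$zone_profiles[["3"]]
  massive <- sum(z3$live_coral_mix$prob[z3$live_coral_mix$morphology ==
                                          "massive"])
  expect_equal(massive, 0.66)
  expect_equal(z3$urchin_test_mean_mm[["Diadema"]], 30)
  expect_equal(z3$urchin_test_mean_mm[["Phyllocanthus"]], 90)
})

test_that("the generated census matches the protocol arithmetic", {
  reef <- generate_reef(default_mahutigala_scenario(), seed = 2)
  n_lines <- length(unique(reef$observations$line_id))
  expect_identical(n_lines, 63L)
  expect_identical(nrow(reef$observations), 100L * n_lines)
  per_cell <- table(unique(reef$observations[c("line_id", "transect_id",
                                               "zone_id")])[-1])
  expect_true(all(per_cell[per_cell > 0] == 3L))
  expect_identical(nrow(reef$rugosity), 3L * n_lines)
})

test_that("the same seed reproduces the dataset byte for byte", {
  sc <- default_mahutigala_scenario()
  r1 <- generate_reef(sc, seed = 42)
  r2 <- generate_reef(sc, seed = 42)
  expect_identical(r1$observations, r2$observations)
  expect_identical(r1$rugosity, r2$rugosity)
  expect_identical(r1$belts, r2$belts)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_reef_dataset(r1, d1)
  write_reef_dataset(r2, d2)
  for (f in c("observations.csv", "rugosity.csv", "belts.csv",
              "truth.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  r3 <- generate_reef(sc, seed = 43)
  expect_false(identical(r1$observations, r3$observations))
})

test_that("zero urchin density leaves every belt empty", {
  sc <- default_mahutigala_scenario()
  sc$zone_profiles <- lapply(sc$zone_profiles, function(p) {
    p$urchin_density_per_m2 <- 0
    p
  })
  reef <- generate_reef(sc, seed = 5)
  expect_true(all(reef$belts$count == 0L))
  rt <- default_rate_table()
  expect_true(all(echinoid_erosion(reef$belts, rt)$echinoid_G == 0))
})

test_that("test sizes stay inside the genus size classes", {
  reef <- generate_reef(default_mahutigala_scenario(), seed = 6)
  dia <- reef$belts[reef$belts$genus == "Diadema", ]
  phy <- reef$belts[reef$belts$genus == "Phyllocanthus", ]
  expect_true(all(dia$test_size_mm >= 21 & dia$test_size_mm <= 40))
  expect_true(all(phy$test_size_mm >= 81 & phy$test_size_mm <= 100))
})

test_that("invalid probability vectors are rejected", {
  expect_error(zone_profile(2, c(sand = 0.7, rubble = 0.2)), "sum to 1")
  expect_error(zone_profile(2, c(sand = 1.2, rubble = -0.2)), "sum to 1")
  expect_error(zone_profile(2, c(live_coral = 0.5, sand = 0.5)),
               "live_coral_mix required")
  mix <- data.frame(taxon = "Porites", morphology = "massive", prob = 0.8)
  expect_error(zone_profile(2, c(live_coral = 0.5, sand = 0.5),
                            live_coral_mix = mix), "sum to 1")
})

test_that("generated covers converge to the profile probabilities", {
  # binomial sampling: mean live cover over many lines within 3 SE of 20%
  mix <- data.frame(taxon = "Porites", morphology = "massive", prob = 1)
  prof <- zone_profile(3, c(live_coral = 0.2, sand = 0.8),
                       live_coral_mix = mix)
  sc <- reef_scenario(list(prof), list(N = 3), lines_per_zone = 600,
                      belt_transects = character(0), seed = 123)
  reef <- generate_reef(sc)
  cov <- percent_cover(reef$observations)
  live <- cov$percent[cov$category == "live_coral"]
  se <- 100 * sqrt(0.2 * 0.8 / (100 * length(live)))
  expect_lt(abs(mean(live) - 20), 3 * se)
})

test_that("patchiness preserves the marginal composition", {
  mix <- data.frame(taxon = "Porites", morphology = "massive", prob = 1)
  prof <- zone_profile(3, c(live_coral = 0.2, sand = 0.8),
                       live_coral_mix = mix)
  sc <- reef_scenario(list(prof), list(N = 3), lines_per_zone = 600,
                      belt_transects = character(0), patchiness = 0.5,
                      seed = 321)
  reef <- generate_reef(sc)
  cov <- percent_cover(reef$observations)
  live <- cov$percent[cov$category == "live_coral"]
  # Markov persistence inflates the variance; allow a generous band
  se_iid <- 100 * sqrt(0.2 * 0.8 / (100 * length(live)))
  expect_lt(abs(mean(live) - 20), 9 * se_iid)
})

test_that("the truth record carries every generative parameter", {
  reef <- generate_reef(default_mahutigala_scenario(), seed = 9)
  truth <- reef$truth
  expect_identical(truth$seed, 9L)
  expect_identical(truth$lines_per_zone, 3L)
  z3 <- truth$zone_profiles[["3"]]
  expect_equal(z3$expected_live_cover_pct, 17.5)
  expect_equal(z3$expected_rugosity,
               truncated_normal_mean(2.6, 0.3), tolerance = 1e-12)
  d <- withr::local_tempdir()
  write_reef_dataset(reef, d)
  back <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_equal(back$zone_profiles[["3"]]$expected_live_cover_pct, 17.5)
})

test_that("closed-form expectations match a direct hand computation", {
  mix <- data.frame(taxon = c("Porites", "Acropora"),
                    morphology = c("massive", "branching"),
                    prob = c(0.75, 0.25), stringsAsFactors = FALSE)
  prof <- zone_profile(3, c(live_coral = 0.2, cca = 0.1, dead_coral = 0.3,
                            sand = 0.4),
                       live_coral_mix = mix, rugosity_mean = 2,
                       rugosity_sd = 0)
  sc <- reef_scenario(list(prof), list(N = 3), seed = 1,
                      belt_transects = character(0))
  rt <- rate_table(data.frame(
    taxon = c("Porites", "Acropora", "CCA"),
    morphology = c("massive", "branching", "none"),
    ci_g_cm2_yr = c(1, 2, 0.5), stringsAsFactors = FALSE))
  eb <- expected_budget(sc, rt)
  # E[gross] = R * (0.2*(0.75*1 + 0.25*2) + 0.1*0.5) * 10
  expect_equal(eb$reef$gross_G, 2 * (0.2 * 1.25 + 0.05) * 10)
  expect_equal(eb$reef$f_avail, 0.5)
  expect_equal(eb$reef$borer_G, 2 * 0.5 * 0.105)
  expect_equal(eb$reef$parrotfish_G, 3.81 * 0.5)
  expect_equal(eb$reef$live_cover_pct, 20)
})
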