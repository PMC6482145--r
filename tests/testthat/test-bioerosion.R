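test_that("borer kernel evaluates the printed constants and is bilinear", {
  expect_identical(borer_erosion_rate(R = 1, f_avail = 0), 0)
  expect_equal(borer_erosion_rate(R = 1, f_avail = 1), 0.105)
  expect_equal(borer_erosion_rate(R = 2, f_avail = 0.5),
               borer_erosion_rate(R = 1, f_avail = 1))
})

test_that("parrotfish kernel is planar unless rugosity scaling is asked for", {
  expect_equal(parrotfish_erosion_rate(f_avail = 1), 3.81)
  expect_identical(parrotfish_erosion_rate(f_avail = 0), 0)
  expect_equal(parrotfish_erosion_rate(f_avail = 0.5), 1.905)
  expect_equal(parrotfish_erosion_rate(f_avail = 0.5, R = 2),
               2 * parrotfish_erosion_rate(f_avail = 0.5))

  obs <- make_line(category = "dead_coral")
  rug <- make_rugosity(sections = c(2, 2, 2))
  planar <- parrotfish_erosion(obs, rug, flat_rates())
  scaled <- parrotfish_erosion(obs, rug,
                               flat_rates(parrotfish_use_rugosity = TRUE))
  expect_equal(planar$parrotfish_G, 3.81)
  expect_equal(scaled$parrotfish_G, 2 * 3.81)
})

test_that("echinoid kernel matches direct evaluation of the power law", {
  # ((0.0029 * 30^1.6624) * 1 * 365/60)/1000, frozen independently
  expect_equal(echinoid_erosion_rate(30, 1, a = 0.0029),
               0.00503623498757771, tolerance = 1e-12)
  expect_equal(echinoid_erosion_rate(90, 1, a = 8e-5),
               0.000862907708747188, tolerance = 1e-12)
  expect_equal(echinoid_erosion_rate(30, 2, a = 0.0029),
               2 * echinoid_erosion_rate(30, 1, a = 0.0029))
  expect_identical(echinoid_erosion_rate(30, 0, a = 0.0029), 0)
})

test_that("belt-scale echinoid erosion sums genera and divides by area", {
  belts <- data.frame(
    belt_id = c("B1", "B1"), transect_id = "NE", zone_id = 3L,
    area_m2 = 60, genus = c("Diadema", "Phyllocanthus"),
    test_size_mm = c(30, 90), count = c(6L, 3L), stringsAsFactors = FALSE)
  br <- echinoid_erosion(belts, default_rate_table())
  expect_equal(br$echinoid_G,
               echinoid_erosion_rate(30, 6 / 60, a = 0.0029) +
                 echinoid_erosion_rate(90, 3 / 60, a = 8e-5))
  # urchin-free belts erode nothing
  belts$count <- 0L
  expect_identical(echinoid_erosion(belts, default_rate_table())$echinoid_G, 0)
})

test_that("belt rates broadcast to lines by zone, transect, then reef mean", {
  belts <- data.frame(
    belt_id = c("NE-a", "NE-b", "SW-a"),
    transect_id = c("NE", "NE", "SW"), zone_id = c(3L, 4L, 3L),
    area_m2 = 60, genus = "Diadema", test_size_mm = 30,
    count = c(6L, 12L, 30L), stringsAsFactors = FALSE)
  meta <- data.frame(line_id = c("a", "b", "c"),
                     transect_id = c("NE", "NE", "W"),
                     zone_id = c(3L, 5L, 3L), stringsAsFactors = FALSE)
  rt <- default_rate_table()
  g <- echinoid_erosion_by_line(meta, belts, rt)
  br <- echinoid_erosion(belts, rt)
  # exact zone match on NE
  expect_equal(g$echinoid_G[1], br$echinoid_G[br$belt_id == "NE-a"])
  # no zone-5 belt on NE: transect mean
  expect_equal(g$echinoid_G[2],
               mean(br$echinoid_G[br$transect_id == "NE"]))
  # W has no belts at all: reef-wide mean
  expect_equal(g$echinoid_G[3], mean(br$echinoid_G))
  # no belts anywhere: zero with a warning
  expect_warning(g0 <- echinoid_erosion_by_line(meta, no_belts(), rt),
                 "echinoid erosion set to 0")
  expect_identical(g0$echinoid_G, c(0, 0, 0))
})

test_that("total bioerosion is the exact component sum with shares", {
  # engineered components: borer 0.2, parrotfish 3.0, echinoid 0.003
  obs <- make_line(category = "dead_coral", transect = "N", zone = 3L)
  rug <- make_rugosity(sections = c(1, 1, 1))
  a_engineered <- 0.003 * 1000 * 60 / (365 * 30^1.6624)
  rt <- flat_rates(macro_borer_rate = 0.1, micro_borer_rate = 0.1,
                   parrotfish_rate = 3.0,
                   echinoid_coeffs = data.frame(
                     genus = "Diadema", a = a_engineered, b = 1.6624,
                     stringsAsFactors = FALSE))
  belts <- data.frame(belt_id = "B1", transect_id = "N", zone_id = 3L,
                      area_m2 = 1, genus = "Diadema", test_size_mm = 30,
                      count = 1L, stringsAsFactors = FALSE)
  tb <- total_bioerosion(obs, rug, belts, rt)
  expect_equal(tb$lines$total_erosion_G, 3.203)
  expect_equal(tb$lines$total_erosion_G,
               tb$lines$borer_G + tb$lines$parrotfish_G +
                 tb$lines$echinoid_G)
  expect_equal(unname(tb$shares[["parrotfish"]]), 100 * 3.0 / 3.203)
  expect_equal(sum(tb$shares), 100)
})

test_that("zero-erosion configurations yield empty shares and zero totals", {
  obs <- make_line(category = "sand")
  tb <- suppressWarnings(
    total_bioerosion(obs, make_rugosity(), no_belts(), flat_rates()))
  expect_identical(tb$lines$total_erosion_G, 0)
  expect_identical(length(tb$shares), 0L)
})

test_that("total erosion is monotone in substrate, rugosity and counts", {
  rt <- default_rate_table()
  base_obs <- make_line(category = c(rep("dead_coral", 40), rep("sand", 60)))
  more_avail <- make_line(category = c(rep("dead_coral", 70), rep("sand", 30)))
  rug_lo <- make_rugosity(sections = c(1.5, 1.5, 1.5))
  rug_hi <- make_rugosity(sections = c(2.5, 2.5, 2.5))
  belts <- data.frame(belt_id = "B1", transect_id = "N", zone_id = 3L,
                      area_m2 = 60, genus = "Diadema", test_size_mm = 30,
                      count = 5L, stringsAsFactors = FALSE)
  t_base <- total_bioerosion(base_obs, rug_lo, belts, rt)$lines$total_erosion_G
  t_avail <- total_bioerosion(more_avail, rug_lo, belts, rt)$lines$total_erosion_G
  t_rug <- total_bioerosion(base_obs, rug_hi, belts, rt)$lines$total_erosion_G
  belts_more <- transform(belts, count = 50L)
  t_urch <- total_bioerosion(base_obs, rug_lo, belts_more,
                             rt)$lines$total_erosion_G
  expect_gte(t_avail, t_base)
  expect_gte(t_rug, t_base)
  expect_gte(t_urch, t_base)
})
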