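test_that("net budget is the exact gross-minus-erosion difference per line", {
  reef <- generate_reef(default_mahutigala_scenario(), seed = 21)
  rt <- default_rate_table()
  lb <- line_budgets(reef$observations, reef$rugosity, reef$belts, rt)
  expect_identical(lb$net_G, lb$gross_G - lb$total_erosion_G)
  expect_identical(lb$total_erosion_G,
                   lb$borer_G + lb$parrotfish_G + lb$echinoid_G)
})

test_that("an all-sand line has a zero budget on both sides", {
  lb <- suppressWarnings(
    line_budgets(make_line(category = "sand"), make_rugosity(),
                 no_belts(), flat_rates()))
  expect_identical(lb$gross_G, 0)
  expect_identical(lb$total_erosion_G, 0)
  expect_identical(lb$net_G, 0)
})

test_that("with all erosion constants zero the net budget equals gross", {
  reef <- generate_reef(default_mahutigala_scenario(), seed = 22)
  rt <- default_rate_table(macro_borer_rate = 0, micro_borer_rate = 0,
                           parrotfish_rate = 0,
                           echinoid_coeffs = data.frame(
                             genus = c("Diadema", "Phyllocanthus"),
                             a = c(0, 0), b = c(1.6624, 1.6624),
                             stringsAsFactors = FALSE))
  lb <- line_budgets(reef$observations, reef$rugosity, reef$belts, rt)
  expect_identical(lb$net_G, lb$gross_G)
})

test_that("erosion exceeding production yields a negative net budget", {
  obs <- make_line(category = c(rep("live_coral", 5), rep("dead_coral", 95)))
  lb <- suppressWarnings(
    line_budgets(obs, make_rugosity(), no_belts(), flat_rates()))
  expect_lt(lb$net_G, 0)
})

test_that("aggregation reports sample statistics at each scale", {
  # three lines engineered to net (1, 2, 6) via cover differences
  mk <- function(id, n_live) {
    make_line(id, transect = "N", zone = 3L,
              category = c(rep("live_coral", n_live),
                           rep("sand", 100 - n_live)))
  }
  obs <- rbind(mk("a", 10), mk("b", 20), mk("c", 60))
  rug <- rbind(make_rugosity("a", c(1, 1, 1)), make_rugosity("b", c(1, 1, 1)),
               make_rugosity("c", c(1, 1, 1)))
  rt <- flat_rates(macro_borer_rate = 0, micro_borer_rate = 0,
                   parrotfish_rate = 0)
  lb <- suppressWarnings(line_budgets(obs, rug, no_belts(), rt))
  z <- aggregate_budget(lb, "zone")
  expect_identical(z$n_lines, 3L)
  expect_equal(z$net_G_mean, 3)
  expect_equal(z$net_G_sd, 2.6457513110645907)

  # identical lines collapse to zero dispersion
  obs2 <- rbind(mk("a", 20), mk("b", 20))
  rug2 <- rbind(make_rugosity("a", c(1, 1, 1)), make_rugosity("b", c(1, 1, 1)))
  lb2 <- suppressWarnings(line_budgets(obs2, rug2, no_belts(), rt))
  z2 <- aggregate_budget(lb2, "zone")
  expect_equal(z2$net_G_sd, 0)
  expect_equal(z2$net_G_mean, lb2$net_G[1])
})

test_that("reef scope averages transect means, not pooled lines", {
  reef <- generate_reef(default_mahutigala_scenario(), seed = 23)
  lb <- line_budgets(reef$observations, reef$rugosity, reef$belts,
                     default_rate_table())
  tr <- aggregate_budget(lb, "transect")
  rf <- aggregate_budget(lb, "reef")
  expect_equal(rf$net_G_mean, mean(tr$net_G_mean))
  expect_equal(rf$net_G_sd, sd(tr$net_G_mean))
  expect_identical(rf$n_lines, sum(tr$n_lines))
  pooled <- aggregate_budget(lb, "reef", reef_method = "pooled_lines")
  expect_equal(pooled$net_G_mean, mean(lb$net_G[lb$zone_id != 1]))
})

test_that("exact accounting holds at every aggregation scale", {
  reef <- generate_reef(default_mahutigala_scenario(), seed = 24)
  lb <- line_budgets(reef$observations, reef$rugosity, reef$belts,
                     default_rate_table())
  for (level in c("zone", "transect", "reef")) {
    agg <- aggregate_budget(lb, level)
    expect_equal(agg$net_G_mean,
                 agg$gross_G_mean - agg$total_erosion_G_mean,
                 tolerance = 1e-12)
    expect_equal(agg$total_erosion_G_mean,
                 agg$borer_G_mean + agg$parrotfish_G_mean +
                   agg$echinoid_G_mean,
                 tolerance = 1e-12)
  }
})

test_that("sand-moat lines are excluded from aggregates", {
  obs <- rbind(
    make_line("m", transect = "N", zone = 1L, category = "sand"),
    make_line("p", transect = "N", zone = 3L,
              category = c(rep("live_coral", 20), rep("sand", 80))))
  rug <- rbind(make_rugosity("m", c(1, 1, 1)), make_rugosity("p", c(2, 2, 2)))
  lb <- suppressWarnings(line_budgets(obs, rug, no_belts(), flat_rates()))
  agg <- aggregate_budget(lb, "transect")
  expect_identical(agg$n_lines, 1L)
  expect_equal(agg$live_cover_pct_mean, 20)
  lb_moat <- lb[lb$zone_id == 1L, ]
  expect_error(aggregate_budget(lb_moat, "reef"), "zone > 1")
})

test_that("pipeline agrees with the brute-force oracle on random reefs", {
  set.seed(404)
  for (i in 1:20) {
    sc <- random_scenario(n_transects = 2, n_zones = 2, lines_per_zone = 1)
    reef <- generate_reef(sc)
    rt <- default_rate_table()
    lb <- line_budgets(reef$observations, reef$rugosity, reef$belts, rt)
    oracle <- oracle_line_budget(reef$observations, reef$rugosity,
                                 reef$belts, rt)
    ord <- match(oracle$line_id, lb$line_id)
    for (v in c("gross_G", "borer_G", "parrotfish_G", "echinoid_G",
                "total_erosion_G", "net_G")) {
      expect_equal(lb[[v]][ord], oracle[[v]], tolerance = 1e-12)
    }
  }
})
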