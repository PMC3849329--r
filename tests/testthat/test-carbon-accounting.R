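test_that("carbonate correction rescales acidified %C to whole-soil basis", {
  expect_equal(carbonate_corrected_percent_c(1.0, 0), 1.0)
  expect_equal(carbonate_corrected_percent_c(1.0, 2.99), 0.9701)
  expect_equal(carbonate_corrected_percent_c(0, 50), 0)
  expect_error(carbonate_corrected_percent_c(101, 0), "0, 100")
  expect_error(carbonate_corrected_percent_c(1, -2), "0, 100")
})

test_that("soil layer stocks follow BD x depth x %C with the unit factor", {
  expect_equal(soil_layer_carbon(1.0, 10, 1), 1.0)
  # consistent with the observed un-encroached mineral stock (1.52)
  expect_equal(soil_layer_carbon(1.55, 10, 0.98), 1.519)
  # duff-scale case: thin organic layer over mineral soil (observed 0.05)
  expect_equal(soil_layer_carbon(0.13, 0.38, 10), 0.0494)
  expect_error(soil_layer_carbon(0, 10, 1), "positive")
})

test_that("soil layer stock is linear in BD, depth and %C", {
  set.seed(7)
  for (k in 1:20) {
    bd <- stats::runif(1, 0.1, 2)
    dp <- stats::runif(1, 0.2, 10)
    pc <- stats::runif(1, 0.1, 20)
    f <- stats::runif(1, 0.5, 3)
    base <- soil_layer_carbon(bd, dp, pc)
    expect_equal(soil_layer_carbon(f * bd, dp, pc), f * base)
    expect_equal(soil_layer_carbon(bd, f * dp, pc), f * base)
    expect_equal(soil_layer_carbon(bd, dp, f * pc), f * base)
  }
})

test_that("stem densities scale plot counts to hectares", {
  mk <- function(n_live) {
    trees <- data.frame(
      id = as.character(seq_len(n_live)), species = "pinon",
      status = "live", rcd_cm = 10, canopy_area_m2 = 4,
      x_m = rep_len(seq(1, 14, by = 0.37), n_live),
      y_m = rep_len(seq(1, 19, by = 0.53), n_live),
      stringsAsFactors = FALSE
    )
    plot_inventory("x", trees = trees, covers = uniform_covers(30))
  }
  expect_equal(plot_cover_summary(mk(42))$density_stems_ha, 1400)
  expect_equal(plot_cover_summary(mk(31))$density_stems_ha, 1033.333,
               tolerance = 1e-4)
})

test_that("uniform cover yields its own mean with zero standard error", {
  inv <- plot_inventory("u", covers = uniform_covers(50))
  cov <- plot_cover_summary(inv)$cover
  expect_equal(cov$mean, rep(50, 4))
  expect_equal(cov$se, rep(0, 4))
})

test_that("stock table totals equal the sum of the five pools", {
  tab <- carbon_stock_table(reference_table("plot_stocks"))
  for (p in c("HSC", "LD", "HD", "PJD")) {
    pools <- tab$kg_c_m2[tab$plot == p & tab$pool != "total"]
    tot <- tab$kg_c_m2[tab$plot == p & tab$pool == "total"]
    expect_equal(tot, sum(pools), tolerance = 1e-12)
  }
  # printed pools reproduce the printed totals at their precision
  get_tot <- function(p) tab$kg_c_m2[tab$plot == p & tab$pool == "total"]
  expect_equal(get_tot("HSC"), 1.99, tolerance = 0.005)
  expect_equal(get_tot("HD"), 5.49, tolerance = 0.005)
  expect_error(carbon_stock_table(
    data.frame(plot = "A", pool = "lake", kg_c_m2 = 1)
  ), "unknown pool")
})

test_that("plot_carbon_table integrates trees, cover and cores", {
  inv <- tiny_inventory()
  tab <- plot_carbon_table(inv)
  tree_c <- (tree_biomass_rcd(10, "pinon", "live") * 0.4614 +
               tree_biomass_rcd(10, "pinon", "dead") * 0.4614 +
               tree_biomass_rcd(20, "juniper", "live") * 0.4564) / 300
  expect_equal(tab$kg_c_m2[tab$pool == "pj_tree"], tree_c,
               tolerance = 1e-10)
  # uniform 20% cover through the regressions, g -> kg basis
  expect_equal(tab$kg_c_m2[tab$pool == "sagebrush"],
               12.132 * 20 * 0.4555 / 1000, tolerance = 1e-10)
  expect_equal(tab$kg_c_m2[tab$pool == "grass"],
               0.566 * 20 * 0.4084 / 1000, tolerance = 1e-10)
  # mineral pool: mean of the 9 core stocks
  cores <- tiny_cores()
  mc <- cores[cores$layer == "mineral", ]
  expect_equal(tab$kg_c_m2[tab$pool == "mineral_soil"],
               mean(soil_layer_carbon(core = mc)), tolerance = 1e-12)
  # duff: one core over 9 sampled points, absences count as zero
  duff_kg <- soil_layer_carbon(0.2, 2, 11, 1)
  expect_equal(tab$kg_c_m2[tab$pool == "duff_litter"], duff_kg / 9,
               tolerance = 1e-12)
  expect_equal(tab$kg_c_m2[tab$pool == "total"],
               sum(tab$kg_c_m2[tab$pool != "total"]), tolerance = 1e-12)
})

test_that("a treeless plot has a zero tree pool", {
  inv <- plot_inventory("HSC-like", covers = uniform_covers(30))
  tab <- plot_carbon_table(inv)
  expect_equal(tab$kg_c_m2[tab$pool == "pj_tree"], 0)
})

test_that("plot_carbon_table is deterministic and monotone in tree size", {
  inv <- tiny_inventory()
  t1 <- plot_carbon_table(inv)
  t2 <- plot_carbon_table(inv)
  expect_identical(t1, t2)
  big <- inv
  big$trees$rcd_cm <- big$trees$rcd_cm * 2
  tb <- plot_carbon_table(big)
  expect_gt(tb$kg_c_m2[tb$pool == "pj_tree"],
            t1$kg_c_m2[t1$pool == "pj_tree"])
})

test_that("stock deltas reproduce the published changes from the ledger", {
  tab <- carbon_stock_table(reference_table("plot_stocks"))
  d <- stock_deltas(tab, "HSC")
  pp <- function(p, col) d$per_plot[[col]][d$per_plot$plot == p]
  expect_equal(pp("HSC", "aboveground_delta"), 0)
  expect_equal(pp("HSC", "above_duff_delta"), 0)
  expect_equal(pp("LD", "aboveground_delta"), 1.02, tolerance = 0.01)
  expect_equal(pp("HD", "aboveground_delta"), 2.99, tolerance = 0.005)
  expect_equal(pp("PJD", "aboveground_delta"), 0.99, tolerance = 0.015)
  expect_equal(d$mean_pool_delta[["pj_tree"]], 1.82, tolerance = 0.005)
  expect_equal(d$mean_pool_delta[["duff_litter"]], 0.50, tolerance = 0.01)
  expect_error(stock_deltas(tab, "XX"), "reference")
})

test_that("inventories round-trip through the CSV layout", {
  inv <- tiny_inventory("RT")
  dir <- withr::local_tempdir()
  write_inventory_csv(inv, dir)
  back <- read_inventory_csv(dir, plot_id = "RT")
  expect_equal(back$trees$rcd_cm, inv$trees$rcd_cm)
  expect_equal(back$covers$sagebrush, inv$covers$sagebrush)
  expect_equal(back$cores$percent_c_measured, inv$cores$percent_c_measured)
  expect_equal(plot_carbon_table(back), plot_carbon_table(inv))
})

test_that("inventory validation rejects out-of-extent and bad records", {
  tr <- tiny_trees()
  tr$x_m[1] <- 99
  expect_error(plot_inventory("b", trees = tr), "outside")
  tr <- tiny_trees()
  tr$death_year[2] <- NA
  expect_error(plot_inventory("b", trees = tr), "death_year")
  cov <- uniform_covers(30)
  cov$grass[1] <- 150
  expect_error(plot_inventory("b", covers = cov), "0, 100")
})
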