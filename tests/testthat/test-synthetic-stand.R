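test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- fixture_config("HD", seed = 42)
  a <- sample_soil(sample_cover(generate_stand(cfg, plot_id = "HD")))
  b <- sample_soil(sample_cover(generate_stand(cfg, plot_id = "HD")))
  expect_identical(a$trees, b$trees)
  expect_identical(a$covers, b$covers)
  expect_identical(a$cores, b$cores)
  c2 <- generate_stand(fixture_config("HD", seed = 43), plot_id = "HD")
  expect_false(identical(a$trees$x_m, c2$trees$x_m))
})

test_that("stand composition tracks the configuration", {
  st <- generate_stand(fixture_config("HD", seed = 2), plot_id = "HD")
  expect_equal(nrow(st$trees), 42) # 1400 stems/ha on 300 m^2
  expect_gt(mean(st$trees$species == "pinon"), 0.7)
  expect_true(all(st$trees$rcd_cm > 0))
  expect_true(all(st$trees$x_m >= 0 & st$trees$x_m <= 15))
  ld <- generate_stand(fixture_config("LD", seed = 2), plot_id = "LD")
  expect_equal(nrow(ld$trees), 31)
  expect_equal(min(ld$trees$establishment_year), 1891)
})

test_that("the recruitment pulse lands 43-66% of trees in 1940-59", {
  hits <- vapply(1:50, function(s) {
    st <- generate_stand(fixture_config("HD", seed = s), plot_id = "HD")
    f <- mean(st$trees$establishment_year >= 1940 &
                st$trees$establishment_year <= 1959)
    f >= 0.43 && f <= 0.66
  }, logical(1))
  expect_gte(mean(hits), 0.6) # binomial spread around the 0.55 mass
})

test_that("clustered stands read as clustered to the ANN statistic", {
  hits <- vapply(1:50, function(s) {
    cfg <- stand_config(s, target_density_stems_ha = 1400,
                        cluster = list(parent_intensity_ha = 70,
                                       sigma_m = 1.0))
    st <- generate_stand(cfg, plot_id = "dense")
    ann <- average_nearest_neighbor(st$trees$x_m, st$trees$y_m, 300)
    ann$statistic < 1 && ann$z_score < -1.96
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("cover sampling recovers the open-ground baseline without
           trees and suppresses understory under canopy", {
  hsc <- sample_cover(generate_stand(fixture_config("HSC", seed = 3),
                                     plot_id = "HSC"))
  cs <- plot_cover_summary(hsc)$cover
  expect_equal(cs$mean[cs$class == "sagebrush"], 37.03, tolerance = 0.15)
  expect_equal(cs$mean[cs$class == "grass"], 11.85, tolerance = 0.3)
  # dense stands push understory below the open baseline
  sage_means <- vapply(1:20, function(s) {
    hd <- sample_cover(generate_stand(fixture_config("HD", seed = s),
                                      plot_id = "HD"))
    cv <- plot_cover_summary(hd)$cover
    cv$mean[cv$class == "sagebrush"]
  }, numeric(1))
  expect_lt(mean(sage_means), 37.03)
  # no suppression decouples cover from the trees
  hd0 <- sample_cover(generate_stand(fixture_config("HD", seed = 3),
                                     plot_id = "HD"), suppression = 0)
  cv0 <- plot_cover_summary(hd0)$cover
  expect_equal(cv0$mean[cv0$class == "sagebrush"], 37.03, tolerance = 2)
})

test_that("generated RCDs recover their configured lognormal", {
  cfg <- stand_config(8, extent_m = c(500, 500),
                      target_density_stems_ha = 400)
  st <- generate_stand(cfg, plot_id = "big") # 10^4 stems
  ks <- stats::ks.test(st$trees$rcd_cm, "plnorm",
                       meanlog = log(11), sdlog = 0.4)
  expect_lt(unname(ks$statistic), 0.05) # sanity, not a sharp gate
})

test_that("soil survey spatial structure matches its design", {
  # iid mineral %C reads as random; duff under a dense canopy as
  # clustered; duff without trees as random
  res <- vapply(1:50, function(s) {
    dense <- sample_soil(
      generate_stand(stand_config(s, target_density_stems_ha = 1400,
                                  cluster = list(parent_intensity_ha = 70,
                                                 sigma_m = 1.0)),
                     plot_id = "dense"),
      spacing_m = 2,
      duff = list(base_prob = 0.02, canopy_prob = 1,
                  depth_meanlog = log(2), depth_sdlog = 0.15,
                  bd = 0.25, percent_c = 11)
    )
    open <- sample_soil(generate_stand(fixture_config("HSC", seed = s),
                                       plot_id = "HSC"))
    spd <- spatial_summary(dense)
    spo <- spatial_summary(open)
    c(duff_clustered = spd$verdict[spd$measure == "duff_c"] == "clustered",
      mineral_random = spd$verdict[spd$measure == "mineral_c"] == "random",
      open_duff_random = spo$verdict[spo$measure == "duff_c"] == "random")
  }, logical(3))
  expect_gte(mean(res["duff_clustered", ]), 0.9)
  expect_gte(mean(res["mineral_random", ]), 0.9)
  expect_gte(mean(res["open_duff_random", ]), 0.9)
})

test_that("rendered crowns hit their target pixel area", {
  trees <- data.frame(
    id = "t1", species = "pinon", status = "live", rcd_cm = 10,
    canopy_area_m2 = 4, x_m = 7.5, y_m = 10,
    establishment_year = 1950L, death_year = NA_integer_,
    stringsAsFactors = FALSE
  )
  st <- plot_inventory("one", trees = trees)
  sc <- render_scene(st, mask_cutoff_year = NULL)
  expect_lte(abs(sum(sc$canopy) - 4), 2)
})

test_that("the historical mask opens fully when all trees are recent", {
  st <- generate_stand(stand_config(9, pulse = c("1950" = 1)),
                       plot_id = "young")
  sc <- render_scene(st, mask_cutoff_year = 1937)
  expect_true(all(sc$mask == 1))
  # and closes around old crowns
  st2 <- generate_stand(stand_config(9, pulse = c("1900" = 1)),
                        plot_id = "old")
  sc2 <- render_scene(st2, mask_cutoff_year = 1937)
  expect_lt(mean(sc2$mask), 1)
})

test_that("an end-to-end synthetic pair reproduces the observed pool
           ordering", {
  hits <- vapply(1:30, function(s) {
    mk <- function(p) {
      sample_soil(sample_cover(
        generate_stand(fixture_config(p, seed = s), plot_id = p)
      ))
    }
    tab <- plot_carbon_table(list(mk("HSC"), mk("LD"), mk("HD")))
    g <- function(p, pool) {
      tab$kg_c_m2[tab$plot == p & tab$pool == pool]
    }
    g("HD", "pj_tree") > g("LD", "pj_tree") &&
      g("LD", "pj_tree") > g("HSC", "pj_tree") &&
      g("HD", "duff_litter") > g("HSC", "duff_litter") &&
      abs(g("HD", "mineral_soil") - g("HSC", "mineral_soil")) < 0.5
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
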