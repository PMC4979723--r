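small_cfg <- function(seed = 42) {
  synth_config(
    seed = seed, grid = grid_spec(40, 40, cell_area = 1),
    n_species_per_group = c(amphibian = 2, bird = 5, butterfly = 1,
                            mammal = 1, plant = 3),
    range_size_spectrum = list(min_km2 = 30, max_km2 = 300,
                               distribution = "loguniform"),
    n_ecosystems = 8, n_reserves = 2, n_untouchable = 1,
    n_operative_blocks = 3, n_southern_blocks = 2, max_block_area = 150,
    mask_coverage = 1, deforestation_fraction = 0.03,
    threat_config = list(wells_per_block = 2, n_dams = 1, n_airports = 1,
                         n_mining = 1, n_roads = 1))
}

test_that("the registry scales from the five printed group counts", {
  g <- ecuador_species_groups()
  expect_equal(sum(g), 745)
  expect_equal(names(g),
               c("amphibian", "bird", "butterfly", "mammal", "plant"))
  cfg <- synth_config(species_scale = 0.1)
  expect_equal(unname(cfg$n_species_per_group), c(9, 27, 5, 3, 31))
})

test_that("generation is deterministic in the seed", {
  a <- generate_landscape(small_cfg(42))
  b <- generate_landscape(small_cfg(42))
  expect_identical(a$sdm_surfaces, b$sdm_surfaces)
  expect_identical(unclass(a$ecosystems)[,], unclass(b$ecosystems)[,])
  expect_identical(unclass(a$operative_blocks)[,],
                   unclass(b$operative_blocks)[,])
  expect_identical(a$deforested, b$deforested)
  expect_identical(a$threat_layers$oil_wells$points,
                   b$threat_layers$oil_wells$points)
  c_ <- generate_landscape(small_cfg(43))
  expect_false(identical(a$sdm_surfaces, c_$sdm_surfaces))
})

test_that("generated landscapes respect their structural contract", {
  land <- generate_landscape(small_cfg(42))
  expect_s3_class(land, "landscape")  # construction re-validates
  expect_equal(length(land$sdm_surfaces), 12)
  expect_equal(unname(table(land$species_groups)[c("amphibian", "bird",
                                                   "butterfly", "mammal",
                                                   "plant")]),
               c(2, 5, 1, 1, 3), ignore_attr = TRUE)
  expect_equal(n_zones(land$ecosystems), 8)
  mask <- zone_mask(land$study_mask)
  expect_false(any(is.na(land$ecosystems[mask])))
  # every oil block under the area cap and in its half of the landscape
  for (layer in c("operative_blocks", "southern_blocks")) {
    z <- land[[layer]]
    for (id in unique(stats::na.omit(as.vector(z))))
      expect_lte(sum(!is.na(z) & z == id), 150)
  }
  expect_true(all(which(zone_mask(land$operative_blocks),
                        arr.ind = TRUE)[, 1] <= 20))
  expect_true(all(which(zone_mask(land$southern_blocks),
                        arr.ind = TRUE)[, 1] >= 21))
  expect_equal(sum(land$deforested), round(0.03 * sum(mask)))
})

test_that("thresholded species extents track the requested spectrum", {
  land <- generate_landscape(small_cfg(42))
  ext <- vapply(land$sdm_surfaces,
                function(s) sum(s >= 0.5, na.rm = TRUE), numeric(1))
  # targets are drawn in [30, 300] km^2 and tuned to within ~10%
  expect_true(all(ext >= 20 & ext <= 400))
  expect_gt(stats::sd(log(ext)), 0)  # a spectrum, not one size
})

test_that("the study mask hits its requested coverage", {
  set.seed(1)
  m <- reservaplan:::gen_mask(grid_spec(50, 50), coverage = 0.8)
  expect_lt(abs(mean(m) - 0.8), 0.05)
})

test_that("the mimic landscape reproduces the regional zone proportions", {
  land <- mimic_land()
  t1 <- table1(land)
  pct <- stats::setNames(t1$pct_of_a, t1$element_a)
  expect_true(pct[["all_blocks"]] >= 65 && pct[["all_blocks"]] <= 71)
  expect_true(pct[["protected_zones"]] >= 19 && pct[["protected_zones"]] <= 25)
  expect_true(pct[["operative_blocks"]] >= 29 &&
                pct[["operative_blocks"]] <= 35)
  expect_true(pct[["southern_blocks"]] >= 33 &&
                pct[["southern_blocks"]] <= 39)
  t2 <- table2(land)
  pz_in_blocks <- t2[t2$element_a == "protected_zones" &
                       t2$element_b == "all_blocks", "pct_of_a"]
  expect_true(pz_in_blocks >= 26 && pz_in_blocks <= 32)
  # one reserve fully inside blocks, one block-free
  expect_equal(t2[t2$element_a == "limoncocha_like_br", "pct_of_a"], 100)
  expect_equal(t2[t2$element_a == "quimi_like_br", "pct_of_a"], 0)
})

test_that("the mimic's richness center sits in compromised land", {
  land <- mimic_land()
  ra <- richness_analysis(land)
  expect_gt(ra$center$extent_km2, 0)
  compromised <- all_blocks_mask(land) | zone_mask(land$deforested)
  v <- center_vulnerability(ra$center, compromised,
                            protected_zones_mask(land))
  expect_gte(v[["pct_compromised"]], 90)
  expect_lte(v[["pct_protected"]], 15)
})

test_that("infeasible packing errors instead of looping", {
  cfg <- small_cfg(1)
  cfg$n_operative_blocks <- 2000  # cannot fit in the northern half
  expect_error(generate_landscape(cfg), "infeasible packing")
})
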