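test_that("target endpoints and midpoint match the interpolation by hand", {
  sch <- target_scheme(scale = 0.4)
  expect_equal(target_fraction(5000, "species", sch), 0.36)
  expect_equal(target_fraction(1e5, "species", sch), 0.04)
  # midpoint of the species thresholds: base 0.5, scaled 0.20
  expect_equal(target_fraction(42500, "species", sch), 0.20)
  # exactly at the thresholds: the endpoint values
  expect_equal(target_fraction(10000, "species", sch), 0.36)
  expect_equal(target_fraction(75000, "species", sch), 0.04)
  # ecosystems use their own thresholds
  expect_equal(target_fraction(50, "ecosystem", sch), 0.36)
  expect_equal(target_fraction(20000, "ecosystem", sch), 0.04)
  expect_error(target_fraction(0, "species", sch), "positive")
  expect_error(target_fraction(-5, "species", sch), "positive")
})

test_that("target fractions are non-increasing in range size", {
  sch <- target_scheme(scale = 0.4)
  for (kind in c("species", "ecosystem")) {
    ranges <- sort(exp(seq(log(10), log(2e5), length.out = 200)))
    fr <- target_fraction(ranges, kind, sch)
    expect_true(all(diff(fr) <= 1e-12), info = kind)
    expect_true(all(fr >= 0.04 - 1e-12 & fr <= 0.36 + 1e-12), info = kind)
  }
})

test_that("target fractions are linear in the scenario factor", {
  ranges <- c(500, 10000, 30000, 75000, 2e5)
  base <- target_fraction(ranges, "species", target_scheme(scale = 0.4))
  for (s in c(0.1, 0.2, 0.5, 1)) {
    expect_equal(target_fraction(ranges, "species", target_scheme(scale = s)),
                 base * s / 0.4)
  }
})

test_that("halve_targets halves every target fraction exactly", {
  sch <- target_scheme(scale = 0.4)
  half <- halve_targets(sch)
  expect_equal(half$scale, 0.2)
  ranges <- c(100, 20000, 1e5)
  expect_equal(target_fraction(ranges, "species", half),
               target_fraction(ranges, "species", sch) / 2)
})

test_that("the target table combines extents, kinds and protected amounts", {
  land <- toy_landscape()
  pus <- tessellate(land, pu_area = 4)
  pus$pu$status[1] <- "locked_in"
  fm <- refresh_protected_amounts(build_feature_matrix(land, pus), pus)
  tt <- build_target_table(fm, target_scheme(scale = 0.4))
  expect_equal(tt$feature_id, fm$features$feature_id)
  # all toy extents are far below the small-range thresholds: fraction 0.36
  expect_equal(tt$target_fraction, rep(0.36, 5))
  expect_equal(tt$target_km2, 0.36 * tt$extent_km2)
  expect_equal(tt$achieved_km2, fm$features$protected_km2)
  # spA: 4 of 9 km^2 protected >= 3.24 target; spB: 0 protected
  expect_true(tt$met[tt$feature_id == "spA"])
  expect_false(tt$met[tt$feature_id == "spB"])
})

test_that("achievement reports match direct amount sums", {
  land <- toy_landscape()
  pus <- tessellate(land, pu_area = 4)
  fm <- build_feature_matrix(land, pus)
  tt <- build_target_table(fm)
  all_in <- achievement_report(rep(TRUE, nrow(pus$pu)), fm, tt)
  expect_equal(all_in$per_feature$achieved_km2,
               fm$features$total_extent_km2)
  expect_true(all(all_in$per_feature$met))
  expect_equal(unname(all_in$summary),
               c(100, 100, 100))
  none <- achievement_report(rep(FALSE, nrow(pus$pu)), fm, tt)
  expect_true(all(none$per_feature$achieved_km2 == 0))
  expect_false(any(none$per_feature$met))
  # integer-id and logical selections agree
  sel <- c(1, 4, 7)
  lg <- rep(FALSE, nrow(pus$pu)); lg[sel] <- TRUE
  expect_equal(achievement_report(sel, fm, tt),
               achievement_report(lg, fm, tt))
})
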