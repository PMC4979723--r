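test_that("richness stacking sums presences cellwise", {
  a <- matrix(c(TRUE, FALSE, NA, TRUE), 2, 2)
  b <- matrix(c(TRUE, TRUE, NA, FALSE), 2, 2)
  r <- stack_richness(list(a = a, b = b), group = "g", cell_area = 2)
  expect_equal(r$values, matrix(c(2L, 1L, NA, 1L), 2, 2))
  expect_equal(r$group, "g")
  expect_equal(r$cell_area, 2)
  expect_error(stack_richness(list(a, matrix(TRUE, 3, 3))), "aligned")
})

test_that("upper tertile of 1..9 selects exactly {7, 8, 9}", {
  r <- structure(list(values = matrix(1:9, 3, 3), group = "g",
                      cell_area = 1), class = "richness_map")
  m <- upper_tertile_mask(r)
  expect_equal(sum(m), 3)
  expect_true(all(r$values[m] %in% 7:9))
  expect_equal(attr(m, "tertile_cut"), 7L)
})

test_that("ties at the tertile cut are all included", {
  vals <- matrix(c(1, 1, 1, 2, 2, 2, 3, 3, 3), 3, 3)
  r <- structure(list(values = vals, group = "g", cell_area = 1),
                 class = "richness_map")
  m <- upper_tertile_mask(r)
  expect_equal(attr(m, "tertile_cut"), 3)
  expect_equal(sum(m), 3)               # k = 3 top cells, all value 3
  expect_true(all(vals[m] == 3))
})

test_that("zeros are excluded from the default tertile pool", {
  vals <- matrix(0, 4, 4)
  vals[1, 1:3] <- c(5, 6, 7)            # 3 positive cells, k = 1
  r <- structure(list(values = vals, group = "g", cell_area = 1),
                 class = "richness_map")
  m <- upper_tertile_mask(r)
  expect_equal(which(m), which(vals == 7))
  m_all <- upper_tertile_mask(r, positive_only = FALSE)
  # all-cells variant: k = ceiling(16/3) = 6, cut is the 6th largest (0)
  expect_true(sum(m_all) > sum(m))
})

test_that("every masked cell outranks every unmasked one", {
  set.seed(3)
  vals <- matrix(rpois(100, 4), 10, 10)
  r <- structure(list(values = vals, group = "g", cell_area = 1),
                 class = "richness_map")
  m <- upper_tertile_mask(r)
  expect_true(min(vals[m]) >= max(vals[!m & vals > 0], 0))
})

test_that("the richness center is the intersection of group tertiles", {
  m1 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  m2 <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  ct <- richness_center(list(g1 = m1, g2 = m2), cell_area = 3)
  expect_equal(ct$mask, m1 & m2)
  expect_equal(ct$extent_km2, 3)
  expect_error(richness_center(list(g1 = m1), groups = c("g1", "g2")),
               "g2")
})

test_that("center vulnerability reports 1-decimal percentages", {
  center <- structure(list(mask = matrix(c(rep(TRUE, 3), rep(FALSE, 6)), 3, 3),
                           extent_km2 = 3), class = "richness_center")
  comp <- matrix(FALSE, 3, 3); comp[1:2, 1] <- TRUE
  prot <- matrix(FALSE, 3, 3); prot[3, 1] <- TRUE
  v <- center_vulnerability(center, comp, prot)
  expect_equal(v[["pct_compromised"]], 66.7)
  expect_equal(v[["pct_protected"]], 33.3)
})

test_that("richness_analysis wires groups, tertiles and center together", {
  land <- toy_landscape()
  ra <- richness_analysis(land)
  expect_setequal(names(ra$by_group), c("bird", "mammal"))
  # birds: spA on rows 1:3 x cols 1:3, spB on rows 4:6 -> richness 1 or 0/1
  expect_equal(max(ra$by_group$bird$values, na.rm = TRUE), 1)
  expect_equal(ra$by_group$mammal$values,
               matrix(1L, 6, 6))              # spC present everywhere
  expect_equal(ra$all$values[1, 1], 2L)       # spA + spC
  expect_equal(ra$center$mask, ra$tertiles$bird & ra$tertiles$mammal)
  expect_equal(nrow(ra$summary), 2)
  expect_equal(ra$summary$center_extent_km2,
               rep(ra$center$extent_km2, 2))
})
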