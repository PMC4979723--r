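test_that("decay kernels evaluate by hand", {
  lin <- threat_spec("t", decay_radius = 2, kernel = "linear")
  expect_equal(reservaplan:::kernel_value(c(0, 1, 2, 3), lin),
               c(1, 0.5, 0, 0))
  ex <- threat_spec("t", decay_radius = 2, kernel = "exponential")
  expect_equal(reservaplan:::kernel_value(0, ex), 1)
  expect_equal(reservaplan:::kernel_value(1, ex), exp(-1.5))
  expect_equal(reservaplan:::kernel_value(2.1, ex), 0)  # truncated
  zero <- threat_spec("t", decay_radius = 0)
  expect_equal(reservaplan:::kernel_value(c(0, 0.5), zero), c(1, 0))
})

test_that("distance to segment handles interior and endpoint projections", {
  d <- reservaplan:::dist_to_segment
  expect_equal(d(1, 1, 0, 0, 2, 0), 1)      # perpendicular foot inside
  expect_equal(d(-3, 4, 0, 0, 2, 0), 5)     # clamps to the (0,0) endpoint
  expect_equal(d(5, 0, 0, 0, 2, 0), 3)      # clamps to the (2,0) endpoint
  expect_equal(d(1, 2, 1, 1, 1, 1), 1)      # degenerate segment = point
})

test_that("multiple sources combine by cellwise maximum", {
  g <- grid_spec(6, 6, cell_area = 1)
  spec <- threat_spec("wells", decay_radius = 3)
  p1 <- data.frame(x = 1.5, y = -1.5)
  p2 <- data.frame(x = 4.5, y = -4.5)
  f1 <- threat_footprint(list(points = p1), spec, g)
  f2 <- threat_footprint(list(points = p2), spec, g)
  f12 <- threat_footprint(list(points = rbind(p1, p2)), spec, g)
  expect_equal(f12, pmax(f1, f2))
  # a point source peaks at 1 on its own cell and decays outward
  expect_equal(f1[2, 2], 1)
  expect_equal(f1[2, 3], 1 - 1 / 3)
})

test_that("field layers pass through, rescaled to [0, 1]", {
  g <- grid_spec(3, 3, cell_area = 1)
  f <- matrix(seq(0, 8), 3, 3)
  fp <- threat_footprint(list(field = f), threat_spec("pop", decay_radius = 0), g)
  expect_equal(fp, f / 8)
  mask <- matrix(TRUE, 3, 3); mask[1, 1] <- FALSE
  fp2 <- threat_footprint(list(field = f), threat_spec("pop", decay_radius = 0),
                          g, mask)
  expect_true(is.na(fp2[1, 1]))
})

test_that("the ERS is the weighted footprint mean scaled to 0..100", {
  specs <- list(a = threat_spec("a", weight = 1),
                b = threat_spec("b", weight = 3))
  fa <- matrix(1, 2, 2)
  fb <- matrix(0.5, 2, 2)
  ers <- compose_ers(list(a = fa, b = fb), specs)
  expect_equal(ers$values, matrix(100 * (1 + 3 * 0.5) / 4, 2, 2))
  expect_equal(ers$threshold, 32)
  expect_error(compose_ers(list(a = fa),
                           list(a = threat_spec("a", weight = 0))), "zero")
})

test_that("the ERS is bounded and monotone in any footprint", {
  set.seed(5)
  specs <- list(a = threat_spec("a", weight = 2),
                b = threat_spec("b", weight = 1))
  fa <- matrix(runif(25), 5, 5)
  fb <- matrix(runif(25), 5, 5)
  e1 <- compose_ers(list(a = fa, b = fb), specs)$values
  expect_true(all(e1 >= 0 & e1 <= 100))
  fb2 <- pmin(1, fb + 0.2)
  e2 <- compose_ers(list(a = fa, b = fb2), specs)$values
  expect_true(all(e2 >= e1))
})

test_that("high-impact exclusion is strictly above the threshold", {
  ers <- structure(list(values = matrix(c(31.9, 32, 32.0001, 100), 2, 2),
                        threshold = 32), class = "ers")
  expect_equal(high_impact_mask(ers),
               matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2))
  expect_equal(sum(high_impact_mask(ers, threshold = 50)), 1)
})

test_that("PU cost is the mean ERS over member cells, floored", {
  land <- toy_landscape()
  pus <- tessellate(land, pu_area = 4)
  vals <- matrix(0, 6, 6)
  vals[1:2, 1:2] <- c(10, 20, 30, 40)   # PU 1
  ers <- structure(list(values = vals, threshold = 32), class = "ers")
  pus <- pu_cost(ers, pus)
  expect_equal(pus$pu$cost[1], 25)
  expect_true(all(pus$pu$cost[-1] == 0.01))  # zero ERS floors at epsilon
})
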