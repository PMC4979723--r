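square_land <- function(n, mask = matrix(TRUE, n, n)) {
  sp <- matrix(1, n, n); sp[!mask] <- NA
  eco <- matrix(1L, n, n); eco[!mask] <- NA
  landscape(grid = grid_spec(n, n, cell_area = 1), study_mask = mask,
            sdm_surfaces = list(sp1 = sp),
            species_groups = c(sp1 = "bird"), ecosystems = eco)
}

test_that("a full 10 x 10 grid at pu_area 4 yields 25 4-km^2 units", {
  pus <- tessellate(square_land(10), pu_area = 4)
  expect_equal(nrow(pus$pu), 25)
  expect_true(all(pus$pu$area_km2 == 4))
  expect_equal(sum(pus$pu$area_km2), 100)
  expect_true(all(pus$pu$status == "available"))
})

test_that("a 60 x 60 grid at pu_area 4 yields the block-count oracle 900", {
  pus <- tessellate(square_land(60), pu_area = 4)
  expect_equal(nrow(pus$pu), 900)
  expect_equal(sum(pus$pu$area_km2), 3600)
})

test_that("mask clipping shrinks edge units instead of dropping them", {
  mask <- matrix(TRUE, 10, 10)
  mask[1, 1] <- FALSE               # clip one cell of the corner PU
  mask[9:10, 9:10] <- FALSE         # remove an entire PU
  pus <- tessellate(square_land(10, mask), pu_area = 4)
  expect_equal(nrow(pus$pu), 24)
  expect_equal(sort(unique(pus$pu$area_km2)), c(3, 4))
  expect_equal(sum(pus$pu$area_km2), sum(mask))
  expect_true(all(is.na(pus$pu_raster[!mask])))
})

test_that("tessellate validates pu_area and empty masks", {
  expect_error(tessellate(square_land(4), pu_area = 0.5), "cell area")
})

test_that("rook adjacency records shared boundary lengths", {
  pus <- tessellate(square_land(4), pu_area = 4)  # four 2x2-cell PUs
  adj <- pus$adjacency
  expect_equal(nrow(adj), 4)
  expect_true(all(adj$id1 < adj$id2))
  expect_equal(adj[order(adj$id1, adj$id2), c("id1", "id2")],
               data.frame(id1 = c(1, 1, 2, 3), id2 = c(2, 3, 4, 4)),
               ignore_attr = TRUE)
  expect_true(all(adj$boundary_km == 2))  # two shared 1-km cell edges
})

test_that("lock rules implement the three scenarios on the toy landscape", {
  land <- toy_landscape()
  pus <- tessellate(land, pu_area = 4)  # 9 PUs in a 3 x 3 arrangement
  expect_equal(nrow(pus$pu), 9)
  # PU 1 = rows 1:2 x cols 1:2 (exactly the protected zone)
  # PU 2 = rows 1:2 x cols 3:4 (fully operative block)
  # PU 5 = rows 3:4 x cols 3:4 (half operative: at the majority boundary)
  # PUs 7, 8 = rows 5:6 x cols 1:4 (fully southern blocks)
  s1 <- apply_lock_rules(pus, land, 1)$pu$status
  expect_equal(s1[1], "locked_in")
  expect_equal(s1[c(2, 7, 8)], rep("locked_out", 3))
  expect_equal(s1[5], "available")  # exactly 50% is not a majority
  s2 <- apply_lock_rules(pus, land, 2)$pu$status
  expect_equal(s2[2], "locked_out")
  expect_equal(s2[c(7, 8)], rep("available", 2))
  s3 <- apply_lock_rules(pus, land, 3)$pu$status
  expect_false(any(s3 == "locked_out"))
  expect_equal(s3[1], "locked_in")
  expect_error(apply_lock_rules(pus, land, 4), "scenario")
})

test_that("high-impact cells lock PUs out, with protected precedence", {
  land <- toy_landscape()
  pus <- tessellate(land, pu_area = 4)
  impact <- matrix(FALSE, 6, 6)
  impact[1:2, 1:2] <- TRUE  # the protected-zone PU is also high impact
  s_in <- apply_lock_rules(pus, land, 3, impact)$pu$status
  expect_equal(s_in[1], "locked_in")   # default: protection wins
  s_out <- apply_lock_rules(pus, land, 3, impact,
                            precedence = "locked_out")$pu$status
  expect_equal(s_out[1], "locked_out")
})
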