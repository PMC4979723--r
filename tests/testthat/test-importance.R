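test_that("quartile scores reproduce nearest-rank examples", {
  expect_equal(quartile_scores(1:8), c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_equal(quartile_scores(1:4), 1:4)
  expect_equal(quartile_scores(c(8, 1, 5, 3, 7, 2, 6, 4)),
               c(4L, 1L, 3L, 2L, 4L, 1L, 3L, 2L))
  expect_error(quartile_scores(1:3), "at least 4")
})

test_that("tied values share the lower quartile score", {
  expect_equal(quartile_scores(rep(5, 6)), rep(1L, 6))
  expect_equal(quartile_scores(c(1, 1, 1, 2)), c(1L, 1L, 1L, 4L))
})

test_that("distinct values split into near-equal quartiles", {
  set.seed(8)
  for (n in c(4, 7, 10, 25)) {
    v <- sample(seq_len(100), n)
    counts <- tabulate(quartile_scores(v), nbins = 4)
    expect_lte(max(counts) - min(counts), 1)
    expect_equal(sum(counts), n)
  }
})

test_that("the importance index sums the four quartile scores", {
  m <- data.frame(block_id = 1:4, label = letters[1:4],
                  kind = "operative", area_km2 = 10,
                  mean_total_richness = c(1, 2, 3, 4),
                  mean_priority_richness = 0,
                  species_diversity = c(0.1, 0.4, 0.2, 0.9),
                  n_ecosystems = c(3, 1, 4, 2),
                  preservation = c(1, 0.5, 0.25, 0.75),
                  conservation_overlap = c(0, 0.2, 0.4, 0.6))
  out <- importance_index(m)
  expect_equal(out$importance_index,
               out$q_species_diversity + out$q_n_ecosystems +
                 out$q_preservation + out$q_conservation_overlap)
  expect_true(all(out$importance_index >= 4 & out$importance_index <= 16))
  expect_true(!is.unsorted(rev(out$importance_index)))
  # block 4 tops three metrics and is second in the fourth: index 4+2+3+4
  expect_equal(out$importance_index[out$block_id == 4], 13)
})

test_that("oil block zones merge with offset ids and kinds", {
  z <- oil_blocks_zones(toy_landscape())
  expect_equal(sort(unique(as.vector(z[!is.na(z)]))), c(1, 2))
  expect_equal(attr(z, "labels"), c(`1` = "toy_oper", `2` = "toy_south"))
  expect_equal(attr(z, "kind"), c(`1` = "operative", `2` = "southern"))
  expect_equal(sum(!is.na(z) & z == 1), 6)
  expect_equal(sum(!is.na(z) & z == 2), 8)
})

test_that("block metrics compute zonal means against hand counts", {
  land <- toy_landscape()
  ra <- richness_analysis(land)
  prio_rich <- stack_richness(presence_rasters(land, "spA"), "priority")
  bm <- block_metrics(land, ra$all, prio_rich,
                      priority_cells = matrix(FALSE, 6, 6))
  expect_equal(bm$area_km2, c(6, 8))
  # operative block rows 1:3 x cols 3:4: col 3 has spA+spC, col 4 only spC
  expect_equal(bm$mean_total_richness, c(1.5, 2))
  expect_equal(bm$mean_priority_richness, c(0.5, 0))
  expect_equal(bm$n_ecosystems, c(2, 2))
  expect_equal(bm$preservation, c(1, 1))
  expect_equal(bm$conservation_overlap, c(0, 0))
  # min-max normalized richness means, averaged with equal weights
  expect_equal(bm$species_diversity, c(0.5, 0.5))
  # priority cells covering the southern block lift its overlap to 1
  prio <- matrix(FALSE, 6, 6); prio[5:6, 1:4] <- TRUE
  bm2 <- block_metrics(land, ra$all, prio_rich, priority_cells = prio)
  expect_equal(bm2$conservation_overlap, c(0, 1))
})
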