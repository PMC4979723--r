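test_that("the objective matches hand arithmetic on a 4-PU problem", {
  p <- manual_problem(spf = 10)
  # targets: every feature has extent 4 and fraction 0.36 -> target 1.44 km^2
  expect_equal(p$targets$target_km2, rep(1.44, 3))
  # cost_scale = mean available cost (2.5) x (sum targets 4.32 / mean area 4)
  expect_equal(p$cost_scale, 2.5 * 4.32 / 4)
  cs <- p$cost_scale
  # PU 1 only: cost 1; spB fully unmet, eco_01 short by 0.44 of 1.44
  expect_equal(objective(p, c(TRUE, FALSE, FALSE, FALSE)),
               1 + 10 * cs * 1 + 10 * cs * (1.44 - 1) / 1.44)
  # PUs 2 + 3: cost 5; only spA (fully unmet) is short
  expect_equal(objective(p, c(FALSE, TRUE, TRUE, FALSE)),
               5 + 10 * cs * 1)
  # everything selected: no shortfall, objective = total cost
  expect_equal(objective(p, rep(TRUE, 4)), 10)
  # integer-id selections agree with logical ones
  expect_equal(objective(p, c(1L, 4L)),
               objective(p, c(TRUE, FALSE, FALSE, TRUE)))
})

test_that("the boundary term adds blm times the exterior boundary", {
  p0 <- manual_problem(blm = 0)
  p1 <- manual_problem(blm = 1.5)
  sel <- c(TRUE, FALSE, FALSE, FALSE)
  # PU 1 touches PUs 2 and 3 over 2 km each -> 4 km exterior boundary
  expect_equal(objective(p1, sel), objective(p0, sel) + 1.5 * 4)
  # the full square has no exterior boundary
  expect_equal(objective(p1, rep(TRUE, 4)), objective(p0, rep(TRUE, 4)))
})

test_that("brute force minimizes over the full enumeration", {
  p <- manual_problem(spf = 10)
  bf <- brute_force_optimum(p)
  # independent enumeration of all 16 subsets through objective()
  objs <- apply(expand.grid(rep(list(c(FALSE, TRUE)), 4)), 1,
                function(sel) objective(p, as.logical(sel)))
  expect_equal(bf$objective, min(objs))
  expect_equal(objective(p, bf$selected), bf$objective)
})

test_that("brute-force ties break to the lexicographically smallest subset", {
  pus <- structure(
    list(pu = data.frame(pu_id = 1:2, area_km2 = c(4, 4), cost = c(1, 1),
                         status = "available", stringsAsFactors = FALSE),
         pu_raster = matrix(c(1L, 1L, 2L, 2L), 2, 2),
         adjacency = data.frame(id1 = 1, id2 = 2, boundary_km = 2),
         grid = grid_spec(2, 2)),
    class = "planning_units")
  amounts <- rbind(f1 = c(4, 4))
  fm <- structure(
    list(features = data.frame(feature_id = "f1", kind = "species",
                               total_extent_km2 = 8, protected_km2 = 0,
                               stringsAsFactors = FALSE),
         amounts = amounts),
    class = "feature_amounts")
  p <- selection_problem(pus, fm, build_target_table(fm), spf = 10)
  # either PU alone meets the 2.88 km^2 target at cost 1: a perfect tie;
  # (FALSE, TRUE) precedes (TRUE, FALSE)
  bf <- brute_force_optimum(p)
  expect_equal(bf$selected, c(FALSE, TRUE))
  expect_equal(bf$objective, 1)
})

test_that("annealing matches the brute-force oracle on >= 95 of 100 seeds", {
  ok <- 0
  for (s in 1:100) {
    p <- rand_problem(s)
    bf <- brute_force_optimum(p)
    an <- anneal(p, n_iter = 1e5, seed = s, restarts = 8)
    if (abs(an$objective - bf$objective) < 1e-8) ok <- ok + 1
    expect_gte(an$objective, bf$objective - 1e-8)  # oracle is a lower bound
  }
  expect_gte(ok, 95)
})

test_that("annealing is deterministic for a fixed seed and honors locks", {
  p <- rand_problem(11)
  a <- anneal(p, n_iter = 2e4, seed = 99, restarts = 2)
  b <- anneal(p, n_iter = 2e4, seed = 99, restarts = 2)
  expect_identical(a, b)

  p$pus$pu$status[c(1, 2)] <- "locked_in"
  p$pus$pu$status[3] <- "locked_out"
  for (s in 1:5) {
    sol <- anneal(p, n_iter = 1e4, seed = s, restarts = 2)
    expect_true(all(sol$selected[c(1, 2)]))
    expect_false(sol$selected[3])
  }
})

test_that("unreachable targets are reported, not errors", {
  p <- rand_problem(4)
  p$pus$pu$status[2:15] <- "locked_out"
  sol <- anneal(p, n_iter = 5e3, seed = 1, restarts = 2)
  expect_true(is.finite(sol$objective))
  expect_lt(sum(sol$met), length(sol$met))
  expect_false(any(sol$selected[2:15]))
})

test_that("summed solutions count selections and keep the best replicate", {
  p <- rand_problem(21)
  p$pus$pu$status[1] <- "locked_in"
  p$pus$pu$status[15] <- "locked_out"
  ss <- summed_solution(p, n_reps = 12, base_seed = 5, n_iter = 1e4,
                        restarts = 2, priority_threshold = 9)
  expect_equal(length(ss$frequency), 15)
  expect_equal(ss$frequency[1], 12)   # locked in: selected in every replicate
  expect_equal(ss$frequency[15], 0)   # locked out: never
  expect_true(all(ss$frequency >= 0 & ss$frequency <= 12))
  expect_equal(ss$best$objective, min(ss$objectives))
  ss2 <- summed_solution(p, n_reps = 12, base_seed = 5, n_iter = 1e4,
                         restarts = 2, priority_threshold = 9)
  expect_identical(ss$frequency, ss2$frequency)
})

test_that("priority areas include the threshold frequency itself", {
  ss <- structure(list(frequency = c(74, 75, 76, 0), n_reps = 100,
                       priority_threshold = 75), class = "summed_solution")
  expect_equal(priority_areas(ss), c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(priority_areas(ss, threshold = 74), c(TRUE, TRUE, TRUE, FALSE))
})

test_that("PU selections map back to cell masks", {
  land <- toy_landscape()
  pus <- tessellate(land, pu_area = 4)
  sel <- rep(FALSE, 9); sel[1] <- TRUE
  m <- pu_mask_to_cells(sel, pus)
  expect_equal(sum(m), 4)
  expect_true(all(m[1:2, 1:2]))
})
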