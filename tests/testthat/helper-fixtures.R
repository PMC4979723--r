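# deterministic 6 x 6 toy landscape with hand-countable zones:
#   spA: 9 cells (rows 1:3, cols 1:3, suitability 1)
#   spB: 18 cells (rows 4:6, suitability 0.8)
#   spC: everywhere (suitability 0.6)
#   ecosystems: 1 = cols 1:3, 2 = cols 4:6 (18 cells each)
#   PA rows 1:2 x cols 1:2 (4 cells), UA row 1 col 1 (inside PA)
#   operative block rows 1:3 x cols 3:4 (6 cells)
#   southern block rows 5:6 x cols 1:4 (8 cells)
toy_landscape <- function() {
  g <- grid_spec(6, 6, cell_area = 1)
  mask <- matrix(TRUE, 6, 6)
  spA <- matrix(0, 6, 6); spA[1:3, 1:3] <- 1
  spB <- matrix(0, 6, 6); spB[4:6, ] <- 0.8
  spC <- matrix(0.6, 6, 6)
  eco <- matrix(1L, 6, 6); eco[, 4:6] <- 2L
  zone <- function(rows, cols, label) {
    z <- matrix(NA_integer_, 6, 6)
    z[rows, cols] <- 1L
    attr(z, "labels") <- c(`1` = label)
    z
  }
  landscape(grid = g, study_mask = mask,
            sdm_surfaces = list(spA = spA, spB = spB, spC = spC),
            species_groups = c(spA = "bird", spB = "bird", spC = "mammal"),
            priority_species = c(spA = TRUE, spB = FALSE, spC = FALSE),
            ecosystems = eco,
            protected_areas = zone(1:2, 1:2, "toy_reserve"),
            untouchable_areas = zone(1, 1, "toy_ua"),
            operative_blocks = zone(1:3, 3:4, "toy_oper"),
            southern_blocks = zone(5:6, 1:4, "toy_south"),
            deforested = matrix(FALSE, 6, 6))
}

# seeded random landscape on a 10 x 6 grid (15 planning units at pu_area 4)
rand_landscape <- function(seed, n_rows = 10, n_cols = 6, n_sp = 6) {
  set.seed(seed)
  g <- grid_spec(n_rows, n_cols, cell_area = 1)
  sdm <- stats::setNames(
    lapply(seq_len(n_sp), function(i)
      matrix(stats::runif(n_rows * n_cols), n_rows, n_cols)),
    sprintf("sp%02d", seq_len(n_sp)))
  landscape(grid = g, study_mask = matrix(TRUE, n_rows, n_cols),
            sdm_surfaces = sdm,
            species_groups = stats::setNames(rep("bird", n_sp), names(sdm)),
            ecosystems = matrix(sample(1:3, n_rows * n_cols, TRUE),
                                n_rows, n_cols))
}

# seeded 15-available-PU selection problem (shared by the solver-vs-oracle
# checks); spf = 100 makes shortfalls decisively worse than any cost
rand_problem <- function(seed, spf = 100) {
  land <- rand_landscape(seed)
  pus <- tessellate(land, pu_area = 4)
  set.seed(seed + 7)
  pus$pu$cost <- stats::runif(nrow(pus$pu), 0.5, 2)
  fm <- build_feature_matrix(land, pus)
  targets <- build_target_table(fm, target_scheme())
  selection_problem(pus, fm, targets, spf = spf)
}

# 4-PU problem with hand-set costs and amounts, for objective arithmetic
manual_problem <- function(spf = 10, blm = 0) {
  pr <- matrix(NA_integer_, 4, 4)
  pr[1:2, 1:2] <- 1L; pr[1:2, 3:4] <- 2L
  pr[3:4, 1:2] <- 3L; pr[3:4, 3:4] <- 4L
  pus <- structure(
    list(pu = data.frame(pu_id = 1:4, area_km2 = rep(4, 4),
                         cost = c(1, 2, 3, 4), status = "available",
                         stringsAsFactors = FALSE),
         pu_raster = pr,
         adjacency = data.frame(id1 = c(1, 1, 2, 3), id2 = c(2, 3, 4, 4),
                                boundary_km = rep(2, 4)),
         grid = grid_spec(4, 4, cell_area = 1)),
    class = "planning_units")
  amounts <- rbind(spA = c(4, 0, 0, 0), spB = c(0, 2, 2, 0),
                   eco_01 = c(1, 1, 1, 1))
  fm <- structure(
    list(features = data.frame(feature_id = rownames(amounts),
                               kind = c("species", "species", "ecosystem"),
                               total_extent_km2 = rowSums(amounts),
                               protected_km2 = 0, stringsAsFactors = FALSE),
         amounts = amounts),
    class = "feature_amounts")
  targets <- build_target_table(fm, target_scheme())
  selection_problem(pus, fm, targets, spf = spf, blm = blm)
}

# the mimic landscape is expensive; generate it once per test run
mimic_land <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_paper_mimic(seed = 1)
    cache
  }
})
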