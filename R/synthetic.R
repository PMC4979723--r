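#' Species group sizes of the full-scale Amazonian indicator registry
#'
#' The full regional analysis tracks 86 amphibians, 267 birds, 49 heliconiine
#' butterflies, 32 medium/large terrestrial mammals and 311 vascular plants
#' (745 species), plus 25 ecosystems, for 770 biodiversity indicators in
#' total. Synthetic landscapes default to a scaled-down registry with the
#' same group proportions.
#'
#' @return named integer vector of species counts per group.
#' @export
ecuador_species_groups <- function() {
  c(amphibian = 86L, bird = 267L, butterfly = 49L, mammal = 32L, plant = 311L)
}

# stable 31-based string hash, kept below 2^31 so seeds stay R integers
stable_hash <- function(name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  h
}

layer_seed <- function(seed, name) {
  as.integer((seed %% 65521) * 32749 + stable_hash(name)) %% 2147483647L
}

# evaluate expr under a sub-seed derived from (seed, layer name); one stream
# per layer, so adding a layer never perturbs the others
with_layer_seed <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(layer_seed(seed, name))
  force(expr)
}

# smooth random field by bilinear upsampling of a coarse normal grid
smooth_field <- function(n_rows, n_cols, coarse = 6) {
  g <- matrix(stats::rnorm((coarse + 1)^2), coarse + 1, coarse + 1)
  rr <- seq(1, coarse + 1 - 1e-9, length.out = n_rows)
  cc <- seq(1, coarse + 1 - 1e-9, length.out = n_cols)
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  outer(1 - fr, 1 - fc) * g[r0, c0] + outer(fr, 1 - fc) * g[r0 + 1, c0] +
    outer(1 - fr, fc) * g[r0, c0 + 1] + outer(fr, fc) * g[r0 + 1, c0 + 1]
}

#' Configuration of the synthetic-landscape generator
#'
#' Defaults emulate the structure the planning analysis assumes at desk
#' scale: a ~10,000 km^2 landscape, a species registry with the standard
#' five-group proportions scaled by `species_scale`, 25 ecosystems, square
#' oil blocks capped at 2,000 km^2 (the 200,000 ha concession maximum) with
#' biddable blocks clustered in the southern half, reserves partially
#' overlapping blocks, and point/line/field threat sources.
#'
#' @param seed master integer seed; every layer derives its own sub-seed by
#'   stable hashing of the layer name.
#' @param grid a [grid_spec()] (default 100 x 100 cells of 1 km^2).
#' @param n_species_per_group named integer vector over the five groups
#'   (default: [ecuador_species_groups()] scaled by `species_scale`).
#' @param species_scale scaling of the full registry (default 0.1).
#' @param range_size_spectrum list `(min_km2, max_km2, distribution)`;
#'   ranges are drawn log-uniformly between the bounds by default.
#' @param n_ecosystems number of ecosystem categories (default 25).
#' @param n_reserves,n_untouchable,n_operative_blocks,n_southern_blocks zone
#'   counts.
#' @param max_block_area km^2 cap on any oil block (default 2,000 = the
#'   200,000 ha concession ceiling).
#' @param reserve_block_overlap fraction of reserves deliberately centred
#'   inside oil blocks (default 0.3).
#' @param priority_fraction fraction of species flagged endemic/red-listed.
#' @param south_confined_fraction fraction of species whose ranges are
#'   confined to the southern-block region (default 0).
#' @param north_bias strength of the north-biased placement gradient giving
#'   the landscape a richness centre by construction (default 2).
#' @param mask_coverage fraction of the grid kept inside the irregular study
#'   mask (default 0.95).
#' @param deforestation_fraction fraction of the mask deforested, nearest to
#'   roads and wells first (default 0.05).
#' @param threat_config list of source counts: `wells_per_block`, `n_dams`,
#'   `n_airports`, `n_mining`, `n_roads`.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         grid = grid_spec(100, 100, cell_area = 1),
                         n_species_per_group = NULL, species_scale = 0.1,
                         range_size_spectrum = list(min_km2 = 100,
                                                    max_km2 = 5000,
                                                    distribution = "loguniform"),
                         n_ecosystems = 25, n_reserves = 3, n_untouchable = 2,
                         n_operative_blocks = 6, n_southern_blocks = 5,
                         max_block_area = 2000, reserve_block_overlap = 0.3,
                         priority_fraction = 0.2,
                         south_confined_fraction = 0, north_bias = 2,
                         mask_coverage = 0.95,
                         deforestation_fraction = 0.05,
                         threat_config = list(wells_per_block = 3, n_dams = 2,
                                              n_airports = 2, n_mining = 3,
                                              n_roads = 2)) {
  if (is.null(n_species_per_group)) {
    n_species_per_group <- round(ecuador_species_groups() * species_scale)
    n_species_per_group[n_species_per_group < 1] <- 1
  }
  stopifnot(all(n_species_per_group >= 1), n_ecosystems >= 1,
            n_reserves >= 1, n_operative_blocks >= 1,
            n_southern_blocks >= 1, max_block_area > 0,
            range_size_spectrum$min_km2 > 0,
            range_size_spectrum$min_km2 < range_size_spectrum$max_km2)
  structure(
    list(seed = seed, grid = grid,
         n_species_per_group = n_species_per_group,
         range_size_spectrum = range_size_spectrum,
         n_ecosystems = n_ecosystems, n_reserves = n_reserves,
         n_untouchable = n_untouchable,
         n_operative_blocks = n_operative_blocks,
         n_southern_blocks = n_southern_blocks,
         max_block_area = max_block_area,
         reserve_block_overlap = reserve_block_overlap,
         priority_fraction = priority_fraction,
         south_confined_fraction = south_confined_fraction,
         north_bias = north_bias, mask_coverage = mask_coverage,
         deforestation_fraction = deforestation_fraction,
         threat_config = threat_config),
    class = "synth_config"
  )
}

gen_mask <- function(grid, coverage) {
  if (coverage >= 1) return(matrix(TRUE, grid$n_rows, grid$n_cols))
  f <- smooth_field(grid$n_rows, grid$n_cols, coarse = 5)
  f >= stats::quantile(f, 1 - coverage)
}

gen_ecosystems <- function(grid, mask, k) {
  cells <- which(mask)
  if (length(cells) < k) stop("mask too small for ", k, " ecosystems")
  seeds <- sample(cells, k)
  sr <- (seeds - 1) %% grid$n_rows + 1
  sc <- (seeds - 1) %/% grid$n_rows + 1
  rows <- (cells - 1) %% grid$n_rows + 1
  cols <- (cells - 1) %/% grid$n_rows + 1
  d2 <- outer(rows, sr, function(a, b) (a - b)^2) +
        outer(cols, sc, function(a, b) (a - b)^2)
  eco <- matrix(NA_integer_, grid$n_rows, grid$n_cols)
  eco[cells] <- max.col(-d2, ties.method = "first")
  eco
}

# place n non-overlapping rectangles inside row_range; returns a zone raster
place_rectangles <- function(grid, mask, n, area_range, row_range,
                             max_area, label_prefix, id_offset = 0,
                             center_in = NULL, center_frac = 0,
                             max_tries = 500) {
  z <- matrix(NA_integer_, grid$n_rows, grid$n_cols)
  labels <- character(0)
  ca <- grid$cell_area
  n_forced <- round(center_frac * n)
  for (k in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      area <- stats::runif(1, area_range[1], min(area_range[2], max_area))
      aspect <- stats::runif(1, 0.5, 2)
      h <- max(1L, round(sqrt(area / ca * aspect)))
      w <- max(1L, round(sqrt(area / ca / aspect)))
      if (h * w * ca > max_area) next
      if (!is.null(center_in) && k <= n_forced) {
        anchors <- which(center_in)
        if (length(anchors) == 0) next
        a <- sample(anchors, 1)
        r0 <- (a - 1) %% grid$n_rows + 1 - h %/% 2
        c0 <- (a - 1) %/% grid$n_rows + 1 - w %/% 2
      } else {
        if (row_range[2] - h + 1 < row_range[1] || grid$n_cols - w + 1 < 1) next
        r0 <- sample(seq(row_range[1], row_range[2] - h + 1), 1)
        c0 <- sample(seq(1, grid$n_cols - w + 1), 1)
      }
      rows <- max(1, r0):min(grid$n_rows, r0 + h - 1)
      cols <- max(1, c0):min(grid$n_cols, c0 + w - 1)
      cells <- as.matrix(expand.grid(rows, cols))
      idx <- cells[, 1] + (cells[, 2] - 1) * grid$n_rows
      idx <- idx[mask[idx]]
      if (length(idx) == 0) next
      if (any(!is.na(z[idx]))) next  # no self-overlap within the layer
      z[idx] <- id_offset + k
      labels[as.character(id_offset + k)] <- sprintf("%s_%02d", label_prefix, k)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("infeasible packing: could not place ", label_prefix, " ", k)
  }
  attr(z, "labels") <- labels
  z
}

# anisotropic Gaussian suitability bump whose thresholded extent is tuned
# to the requested range size; noise is a fixed low-amplitude smooth field
gen_species_surface <- function(grid, mask, target_km2, center_cells,
                                center_weights, noise_amp = 0.02,
                                threshold = 0.5, max_iter = 8) {
  cc <- cell_centers(grid)
  ci <- sample(center_cells, 1,
               prob = center_weights / sum(center_weights))
  cx <- cc$x[ci]; cy <- cc$y[ci]
  aspect <- stats::runif(1, 0.6, 1.6)
  theta <- stats::runif(1, 0, pi)
  noise <- noise_amp * smooth_field(grid$n_rows, grid$n_cols, coarse = 8)
  sigma <- sqrt(target_km2 / (2 * pi * log(2)))
  dx <- cc$x - cx; dy <- cc$y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  ca <- grid$cell_area
  s <- NULL
  for (it in seq_len(max_iter)) {
    sx <- sigma * sqrt(aspect); sy <- sigma / sqrt(aspect)
    q <- (u / sx)^2 + (v / sy)^2
    s <- exp(-q / 2) + noise
    s[s < 0] <- 0; s[s > 1] <- 1
    extent <- sum(s[mask] >= threshold) * ca
    if (extent > 0 && abs(extent / target_km2 - 1) <= 0.1) break
    sigma <- sigma * if (extent == 0) 1.5 else sqrt(target_km2 / extent)
  }
  s[!mask] <- NA
  s
}

gen_all_species <- function(cfg, mask, southern_mask = NULL) {
  grid <- cfg$grid
  spec <- cfg$range_size_spectrum
  cells <- which(mask)
  rows <- (cells - 1) %% grid$n_rows + 1
  w_north <- exp(-cfg$north_bias * (rows - 1) / max(1, grid$n_rows - 1))
  surfaces <- list(); groups <- character(0); priority <- logical(0)
  south_cells <- if (!is.null(southern_mask)) which(mask & southern_mask)
                 else integer(0)
  for (g in names(cfg$n_species_per_group)) {
    n <- cfg$n_species_per_group[[g]]
    n_south <- if (length(south_cells) > 0)
      round(cfg$south_confined_fraction * n) else 0
    for (i in seq_len(n)) {
      nm <- sprintf("%s_%03d", g, i)
      south <- i <= n_south
      target <- if (south) {
        # confined ranges: small relative to the southern-block region
        exp(stats::runif(1, log(spec$min_km2),
                         log(min(4 * spec$min_km2, spec$max_km2))))
      } else {
        exp(stats::runif(1, log(spec$min_km2), log(spec$max_km2)))
      }
      surfaces[[nm]] <- if (south) {
        gen_species_surface(grid, mask, target, south_cells,
                            rep(1, length(south_cells)))
      } else {
        gen_species_surface(grid, mask, target, cells, w_north)
      }
      groups[nm] <- g
      priority[nm] <- stats::runif(1) < cfg$priority_fraction
    }
  }
  list(surfaces = surfaces, groups = groups, priority = priority)
}

gen_threats <- function(cfg, mask, operative_blocks) {
  grid <- cfg$grid
  tc <- cfg$threat_config
  cc <- cell_centers(grid)
  rand_points <- function(n, cells) {
    if (n == 0 || length(cells) == 0)
      return(data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0)))
    idx <- sample(cells, min(n, length(cells)))
    data.frame(x = cc$x[idx], y = cc$y[idx],
               intensity = stats::runif(length(idx), 0.6, 1))
  }
  oper_cells <- which(zone_mask(operative_blocks))
  wells <- rand_points(tc$wells_per_block *
                         max(1, n_zones(operative_blocks)), oper_cells)
  dams <- rand_points(tc$n_dams, which(mask))
  airports <- rand_points(tc$n_airports, which(mask))
  mining <- rand_points(tc$n_mining, which(mask))
  side <- cell_side_km(grid)
  roads <- lapply(seq_len(tc$n_roads), function(i) {
    y <- grid$origin[2] - stats::runif(1, 0.2, 0.8) * grid$n_rows * side
    xs <- seq(grid$origin[1], grid$origin[1] + grid$n_cols * side,
              length.out = 12)
    ys <- y + cumsum(stats::rnorm(12, 0, 3 * side))
    cbind(xs, ys)
  })
  pop <- smooth_field(grid$n_rows, grid$n_cols, coarse = 5)
  pop <- (pop - min(pop)) / (max(pop) - min(pop))
  agri <- smooth_field(grid$n_rows, grid$n_cols, coarse = 5)
  agri <- (agri - min(agri)) / (max(agri) - min(agri))
  pop[!mask] <- NA; agri[!mask] <- NA
  list(population = list(field = pop), agriculture = list(field = agri),
       mining = list(points = mining), oil_wells = list(points = wells),
       dams = list(points = dams), roads = list(lines = roads),
       airports = list(points = airports))
}

gen_deforested <- function(cfg, mask, threats) {
  grid <- cfg$grid
  n_target <- round(cfg$deforestation_fraction * sum(mask))
  if (n_target == 0) return(matrix(FALSE, grid$n_rows, grid$n_cols))
  specs <- default_threat_specs()
  specs$roads$decay_radius <- 3 * specs$roads$decay_radius
  fp <- threat_footprint(threats$roads, specs$roads, grid, mask) +
        threat_footprint(threats$oil_wells, specs$oil_wells, grid, mask)
  score <- fp + 1e-6 * smooth_field(grid$n_rows, grid$n_cols, coarse = 5)
  score[!mask] <- NA
  cand <- order(score, decreasing = TRUE, na.last = NA)[seq_len(n_target)]
  def <- matrix(FALSE, grid$n_rows, grid$n_cols)
  def[cand] <- TRUE
  def
}

#' Generate a seeded synthetic landscape
#'
#' Produces a [landscape()] with the statistical structure the planning
#' pipeline assumes: smooth unimodal species suitability bumps whose
#' thresholded extents track a requested range-size spectrum, placed with a
#' north-biased density so a richness centre exists by construction; a
#' Voronoi ecosystem partition; non-self-overlapping rectangular reserves and
#' oil blocks (southern/biddable blocks clustered in the southern half,
#' every block under the area cap); point, line and field threat sources;
#' and deforestation concentrated near roads and wells. Deterministic for a
#' fixed seed; each layer draws from its own hashed sub-stream.
#'
#' @param cfg a [synth_config()].
#' @return a validated [landscape()].
#' @export
generate_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  grid <- cfg$grid
  seed <- cfg$seed
  mask <- with_layer_seed(seed, "mask", gen_mask(grid, cfg$mask_coverage))
  eco <- with_layer_seed(seed, "ecosystems",
                         gen_ecosystems(grid, mask, cfg$n_ecosystems))
  half <- floor(grid$n_rows / 2)
  mask_km2 <- sum(mask) * grid$cell_area
  block_area_hi <- min(cfg$max_block_area,
                       0.5 * mask_km2 / max(cfg$n_operative_blocks,
                                            cfg$n_southern_blocks))
  oper <- with_layer_seed(seed, "operative_blocks",
    place_rectangles(grid, mask, cfg$n_operative_blocks,
                     c(0.3 * block_area_hi, block_area_hi),
                     c(1, half), cfg$max_block_area, "oper_block"))
  south <- with_layer_seed(seed, "southern_blocks",
    place_rectangles(grid, mask, cfg$n_southern_blocks,
                     c(0.3 * block_area_hi, block_area_hi),
                     c(half + 1, grid$n_rows), cfg$max_block_area,
                     "southern_block"))
  blocks <- zone_mask(oper) | zone_mask(south)
  pa <- with_layer_seed(seed, "protected_areas",
    place_rectangles(grid, mask, cfg$n_reserves,
                     c(0.02 * mask_km2, 0.08 * mask_km2),
                     c(1, grid$n_rows), Inf, "reserve",
                     center_in = blocks,
                     center_frac = cfg$reserve_block_overlap))
  ua <- with_layer_seed(seed, "untouchable_areas",
    place_rectangles(grid, mask, cfg$n_untouchable,
                     c(0.01 * mask_km2, 0.03 * mask_km2),
                     c(1, grid$n_rows), Inf, "untouchable",
                     center_in = zone_mask(pa), center_frac = 1))
  threats <- with_layer_seed(seed, "threats", gen_threats(cfg, mask, oper))
  def <- with_layer_seed(seed, "deforested",
                         gen_deforested(cfg, mask, threats))
  sp <- with_layer_seed(seed, "species",
                        gen_all_species(cfg, mask, zone_mask(south)))
  landscape(grid = grid, study_mask = mask, sdm_surfaces = sp$surfaces,
            species_groups = sp$groups, priority_species = sp$priority,
            ecosystems = eco, protected_areas = pa, untouchable_areas = ua,
            operative_blocks = oper, southern_blocks = south,
            deforested = def, threat_layers = threats)
}

# band rectangle helper on the cell grid
band_zone <- function(z, rows, cols, id) {
  z[rows, cols] <- id
  z
}

#' Scaled-down landscape mimicking the regional zone proportions
#'
#' A 100 x 100-cell (10,000 km^2) landscape whose zone layout reproduces, by
#' direct cell-count construction, the headline regional proportions: all oil
#' blocks ~68% of the study area (operative ~32% in the north, biddable ~36%
#' in the south), protected zones ~22%, and ~29% of the protected zones
#' inside blocks — each within a few percentage points. The reserve registry
#' includes a large national-park-like reserve straddling the operative
#' blocks, a small reserve fully inside them, and one block-free reserve.
#' Species hotspots concentrate inside the northern operative band (so the
#' richness centre falls in compromised land) and a quarter of each group is
#' confined to the southern blocks (so excluding those blocks makes their
#' targets unreachable).
#'
#' @param seed integer seed for the stochastic layers (species, ecosystems,
#'   threats).
#' @param species_scale registry scaling (default 0.12, ~89 species).
#' @return a validated [landscape()].
#' @export
make_paper_mimic <- function(seed = 1, species_scale = 0.12) {
  grid <- grid_spec(100, 100, cell_area = 1)
  mask <- matrix(TRUE, 100, 100)
  none <- matrix(NA_integer_, 100, 100)

  # operative blocks: rows 1..32 (32%) in six strips
  oper <- none
  ob <- round(seq(0, 100, length.out = 7))
  for (k in 1:6) oper <- band_zone(oper, 1:32, (ob[k] + 1):ob[k + 1], k)
  attr(oper, "labels") <- stats::setNames(sprintf("oper_block_%02d", 1:6),
                                          as.character(1:6))
  # southern blocks: rows 65..100 (36%) in five strips
  south <- none
  sb <- round(seq(0, 100, length.out = 6))
  for (k in 1:5) south <- band_zone(south, 65:100, (sb[k] + 1):sb[k + 1], k)
  attr(south, "labels") <- stats::setNames(sprintf("southern_block_%02d", 1:5),
                                           as.character(1:5))
  # protected areas: a Yasuni-like park straddling the operative band, a
  # small reserve fully inside blocks, one block-free reserve
  pa <- none
  pa <- band_zone(pa, 27:44, 1:100, 1L)    # 1800 cells, 600 inside blocks
  pa <- band_zone(pa, 10:12, 10:18, 2L)    # 27 cells, 100% inside blocks
  pa <- band_zone(pa, 50:54, 85:94, 3L)    # 50 cells, block-free
  attr(pa, "labels") <- c(`1` = "yasuni_like_np", `2` = "limoncocha_like_br",
                          `3` = "quimi_like_br")
  # untouchable areas inside the park band, one nicking the operative band
  ua <- none
  ua <- band_zone(ua, 32:43, 1:50, 1L)     # 600 cells, 50 inside blocks
  ua <- band_zone(ua, 33:46, 51:100, 2L)   # 700 cells
  attr(ua, "labels") <- c(`1` = "tagaeri_like_ua", `2` = "cuyabeno_like_ua")

  cfg <- synth_config(
    seed = seed, grid = grid, species_scale = species_scale,
    range_size_spectrum = list(min_km2 = 100, max_km2 = 4000,
                               distribution = "loguniform"),
    n_ecosystems = 25, south_confined_fraction = 0.25, north_bias = 2,
    mask_coverage = 1, deforestation_fraction = 0.04)

  eco <- with_layer_seed(seed, "ecosystems", gen_ecosystems(grid, mask, 25))
  threats <- with_layer_seed(seed, "threats", gen_threats(cfg, mask, oper))
  def <- with_layer_seed(seed, "deforested", gen_deforested(cfg, mask, threats))
  # species hotspots inside the operative band (rows 5..28), southern
  # confined species deep inside the biddable band (rows 70..95)
  sp <- with_layer_seed(seed, "species", {
    cfg2 <- cfg
    north_cells <- which(row(mask) >= 5 & row(mask) <= 28)
    south_deep <- matrix(FALSE, 100, 100); south_deep[70:95, 5:95] <- TRUE
    gen_all_species_in(cfg2, mask, north_cells, which(south_deep))
  })
  landscape(grid = grid, study_mask = mask, sdm_surfaces = sp$surfaces,
            species_groups = sp$groups, priority_species = sp$priority,
            ecosystems = eco, protected_areas = pa, untouchable_areas = ua,
            operative_blocks = oper, southern_blocks = south,
            deforested = def, threat_layers = threats)
}

# species generation with explicit center pools (mimic construction)
gen_all_species_in <- function(cfg, mask, north_cells, south_cells) {
  grid <- cfg$grid
  spec <- cfg$range_size_spectrum
  surfaces <- list(); groups <- character(0); priority <- logical(0)
  for (g in names(cfg$n_species_per_group)) {
    n <- cfg$n_species_per_group[[g]]
    n_south <- round(cfg$south_confined_fraction * n)
    for (i in seq_len(n)) {
      nm <- sprintf("%s_%03d", g, i)
      south <- i <= n_south
      target <- if (south)
        exp(stats::runif(1, log(spec$min_km2), log(3 * spec$min_km2)))
      else exp(stats::runif(1, log(spec$min_km2), log(spec$max_km2)))
      pool <- if (south) south_cells else north_cells
      surfaces[[nm]] <- gen_species_surface(grid, mask, target, pool,
                                            rep(1, length(pool)))
      groups[nm] <- g
      priority[nm] <- stats::runif(1) < cfg$priority_fraction
    }
  }
  list(surfaces = surfaces, groups = groups, priority = priority)
}
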