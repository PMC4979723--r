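#' Tessellate a landscape into square planning units
#'
#' Divides the grid into square blocks of `ceiling(sqrt(pu_area / cell_area))`
#' cells per side, clipped to the study mask. A planning unit (PU) exists iff
#' at least one of its member cells lies inside the mask, so edge fragments
#' are kept rather than dropped; a PU's area is its in-mask member-cell count
#' times the cell area. Adjacency records the shared boundary length (km) of
#' every rook-neighbouring PU pair.
#'
#' @param land a [landscape()].
#' @param pu_area nominal PU area in km^2 (>= cell area). The regional
#'   analysis this mirrors used 3.45 km^2 units.
#' @return an object of class `planning_units`: list with
#'   \describe{
#'     \item{pu}{data.frame `pu_id`, `area_km2`, `cost`, `status`}
#'     \item{pu_raster}{integer matrix mapping in-mask cells to `pu_id`}
#'     \item{adjacency}{data.frame `id1`, `id2`, `boundary_km` (id1 < id2)}
#'     \item{grid}{the shared [grid_spec()]}
#'   }
#' @export
tessellate <- function(land, pu_area = 3.45) {
  grid <- land$grid
  if (pu_area < grid$cell_area)
    stop("pu_area must be at least one cell area")
  mask <- zone_mask(land$study_mask)
  if (!any(mask)) stop("no planning units: empty study mask")
  b <- ceiling(sqrt(pu_area / grid$cell_area))
  brow <- (seq_len(grid$n_rows) - 1L) %/% b
  bcol <- (seq_len(grid$n_cols) - 1L) %/% b
  block <- outer(brow, bcol, function(r, c) r * (max(bcol) + 1L) + c)
  block[!mask] <- NA_integer_
  ids <- sort(unique(as.vector(block)))
  pu_raster <- matrix(match(block, ids), grid$n_rows, grid$n_cols)
  n_pu <- length(ids)
  area <- tabulate(pu_raster[mask], nbins = n_pu) * grid$cell_area

  side <- cell_side_km(grid)
  pairs <- list()
  if (grid$n_cols > 1) {
    a <- pu_raster[, -grid$n_cols]; z <- pu_raster[, -1]
    keep <- !is.na(a) & !is.na(z) & a != z
    pairs[[1]] <- cbind(a[keep], z[keep])
  }
  if (grid$n_rows > 1) {
    a <- pu_raster[-grid$n_rows, ]; z <- pu_raster[-1, ]
    keep <- !is.na(a) & !is.na(z) & a != z
    pairs[[2]] <- cbind(a[keep], z[keep])
  }
  pr <- do.call(rbind, pairs)
  if (is.null(pr) || nrow(pr) == 0) {
    adjacency <- data.frame(id1 = integer(0), id2 = integer(0),
                            boundary_km = numeric(0))
  } else {
    id1 <- pmin(pr[, 1], pr[, 2]); id2 <- pmax(pr[, 1], pr[, 2])
    agg <- stats::aggregate(list(n = rep(1L, length(id1))),
                            by = list(id1 = id1, id2 = id2), FUN = sum)
    adjacency <- data.frame(id1 = agg$id1, id2 = agg$id2,
                            boundary_km = agg$n * side)
    adjacency <- adjacency[order(adjacency$id1, adjacency$id2), ]
    rownames(adjacency) <- NULL
  }

  structure(
    list(pu = data.frame(pu_id = seq_len(n_pu), area_km2 = area,
                         cost = NA_real_, status = "available",
                         stringsAsFactors = FALSE),
         pu_raster = pu_raster, adjacency = adjacency, grid = grid),
    class = "planning_units"
  )
}

#' @export
print.planning_units <- function(x, ...) {
  cat(sprintf("<planning_units> %d PUs, %g km^2 total; status: %s\n",
              nrow(x$pu), sum(x$pu$area_km2),
              paste(sprintf("%s=%d", names(table(x$pu$status)),
                            as.integer(table(x$pu$status))), collapse = ", ")))
  invisible(x)
}

# fraction of a PU's in-mask member cells lying inside `mask`
pu_zone_fraction <- function(pus, land, mask) {
  in_mask <- zone_mask(land$study_mask)
  ids <- pus$pu_raster[in_mask]
  tot <- tabulate(ids, nbins = nrow(pus$pu))
  hit <- tabulate(ids[mask[in_mask]], nbins = nrow(pus$pu))
  hit / pmax(tot, 1L)
}

#' Apply scenario lock rules to planning units
#'
#' Protected-zone PUs are locked in (forced into every solution) in all
#' scenarios; high-environmental-impact PUs are locked out in all scenarios;
#' oil-block PUs are locked out depending on the scenario:
#' \describe{
#'   \item{Scenario 1}{both operative and southern (biddable) blocks excluded}
#'   \item{Scenario 2}{only operative blocks excluded — southern blocks stay
#'     selectable as conservation options}
#'   \item{Scenario 3}{no block exclusion: priority areas may fall anywhere}
#' }
#' A PU is "within" a zone when more than half of its in-mask member cells
#' are (`majority` rule). Where a PU qualifies both as protected and as
#' excluded (reserves overlapping operative blocks are common), the
#' `precedence` rule decides; the default keeps the protected-zone lock-in,
#' because existing reserves are forced into the solution even where they
#' overlap blocks.
#'
#' @param pus a [tessellate()] result.
#' @param land the [landscape()].
#' @param scenario integer 1, 2 or 3.
#' @param ers_mask logical matrix of high-impact cells (see
#'   [high_impact_mask()]); `NULL` for no impact exclusion.
#' @param majority fraction strictly above which a PU counts as inside a
#'   zone (default 0.5).
#' @param precedence `"locked_in"` (default) or `"locked_out"`: which state
#'   wins when both rules fire.
#' @return the `planning_units` with `pu$status` filled in.
#' @export
apply_lock_rules <- function(pus, land, scenario, ers_mask = NULL,
                             majority = 0.5, precedence = "locked_in") {
  if (!scenario %in% 1:3) stop("unknown scenario id: ", scenario)
  precedence <- match.arg(precedence, c("locked_in", "locked_out"))
  pz <- protected_zones_mask(land)
  oper <- zone_mask(land$operative_blocks)
  south <- zone_mask(land$southern_blocks)
  excl <- switch(scenario, `1` = oper | south, `2` = oper,
                 `3` = matrix(FALSE, land$grid$n_rows, land$grid$n_cols))
  if (!is.null(ers_mask)) {
    check_aligned(ers_mask, land$grid, "ers_mask")
    excl <- excl | (ers_mask & !is.na(ers_mask))
  }
  f_in <- pu_zone_fraction(pus, land, pz)
  f_out <- pu_zone_fraction(pus, land, excl)
  status <- rep("available", nrow(pus$pu))
  status[f_out > majority] <- "locked_out"
  if (precedence == "locked_in") {
    status[f_in > majority] <- "locked_in"
  } else {
    status[f_in > majority & !(f_out > majority)] <- "locked_in"
  }
  pus$pu$status <- status
  pus
}
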