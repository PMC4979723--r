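#' Per-species presence rasters from suitability surfaces
#'
#' @param land a [landscape()].
#' @param species character vector of species to include (default all).
#' @param threshold presence threshold on suitability (default 0.5).
#' @return named list of logical matrices (NA outside the study mask).
#' @export
presence_rasters <- function(land, species = names(land$sdm_surfaces),
                             threshold = 0.5) {
  mask <- zone_mask(land$study_mask)
  lapply(stats::setNames(species, species), function(sp) {
    p <- land$sdm_surfaces[[sp]] >= threshold
    p[!mask] <- NA
    p
  })
}

#' Stack presence rasters into a species-richness map
#'
#' The richness of a cell is the number of species present there — the
#' cellwise sum of the individual (thresholded) distribution surfaces.
#'
#' @param presences list of aligned logical/0-1 matrices, one per species.
#' @param group label of the taxonomic group being stacked, or `"all"`.
#' @param cell_area km^2 per cell (carried for extent reporting).
#' @return object of class `richness_map`: list with integer matrix `values`,
#'   `group`, `cell_area`.
#' @export
stack_richness <- function(presences, group = "all", cell_area = 1) {
  stopifnot(length(presences) >= 1)
  d <- dim(presences[[1]])
  vals <- matrix(0L, d[1], d[2])
  na_any <- matrix(FALSE, d[1], d[2])
  for (p in presences) {
    if (!all(dim(p) == d)) stop("presence rasters are not aligned")
    na_any <- na_any | is.na(p)
    q <- p; q[is.na(q)] <- 0
    vals <- vals + as.integer(q)
  }
  vals[na_any] <- NA_integer_
  structure(list(values = vals, group = group, cell_area = cell_area),
            class = "richness_map")
}

#' @export
print.richness_map <- function(x, ...) {
  cat(sprintf("<richness_map> group '%s', richness 0..%d over %d cells\n",
              x$group, max(x$values, na.rm = TRUE), sum(!is.na(x$values))))
  invisible(x)
}

#' Upper-tertile mask of a richness map
#'
#' Flags the top-diversity third of the map: with `n` positive-richness cells
#' the cut is the `ceiling(n/3)`-th largest richness value and every cell at
#' or above the cut is included (ties at the cut are kept, so the mask can
#' exceed a third of the cells). By default the tertile is computed over
#' cells with richness > 0 only — with large empty fractions a literal
#' all-cells tertile can include zero-richness cells, which is not "highest
#' diversity"; set `positive_only = FALSE` for the all-cells variant.
#'
#' @param r a [stack_richness()] map.
#' @param positive_only compute the cut over positive cells only (default).
#' @return logical matrix (NA outside the map's data region).
#' @export
upper_tertile_mask <- function(r, positive_only = TRUE) {
  vals <- r$values
  in_map <- !is.na(vals)
  if (sum(in_map) < 3) stop("need at least 3 in-mask cells")
  pool <- vals[in_map]
  if (positive_only) pool <- pool[pool > 0]
  out <- matrix(NA, nrow(vals), ncol(vals))
  if (length(pool) == 0) {
    warning("all-zero richness map: empty tertile mask")
    out[in_map] <- FALSE
    return(out)
  }
  k <- ceiling(length(pool) / 3)
  cut <- sort(pool, decreasing = TRUE)[k]
  out[in_map] <- vals[in_map] >= cut & vals[in_map] > 0
  if (!positive_only) out[in_map] <- vals[in_map] >= cut
  attr(out, "tertile_cut") <- cut
  out
}

#' Multi-group richness center
#'
#' The richness center is where the highest diversity of *every* taxonomic
#' group coincides: the cellwise intersection of the groups' upper-tertile
#' masks.
#'
#' @param group_masks named list of tertile masks, one per group (all groups
#'   required — a missing group errors rather than silently shrinking the
#'   overlay's meaning).
#' @param cell_area km^2 per cell.
#' @param groups the group set expected (default: the mask names).
#' @return object of class `richness_center`: list with logical `mask` and
#'   `extent_km2`.
#' @export
richness_center <- function(group_masks, cell_area = 1,
                            groups = names(group_masks)) {
  missing <- setdiff(groups, names(group_masks))
  if (length(missing) > 0)
    stop("missing tertile mask for group(s): ", paste(missing, collapse = ", "))
  m <- Reduce(function(a, b) a & b, group_masks[groups])
  structure(list(mask = m, extent_km2 = sum(m, na.rm = TRUE) * cell_area),
            class = "richness_center")
}

#' @export
print.richness_center <- function(x, ...) {
  cat(sprintf("<richness_center> %g km^2\n", x$extent_km2))
  invisible(x)
}

#' How compromised and how protected is the richness center?
#'
#' @param center a [richness_center()].
#' @param compromised_mask logical matrix: oil blocks and/or deforested areas.
#' @param protected_mask logical matrix: protected zones.
#' @return named numeric: `pct_compromised`, `pct_protected` (percent of
#'   center cells, 1 decimal).
#' @export
center_vulnerability <- function(center, compromised_mask, protected_mask) {
  cm <- center$mask & !is.na(center$mask)
  n <- sum(cm)
  if (n == 0) return(c(pct_compromised = NA_real_, pct_protected = NA_real_))
  comp <- compromised_mask & !is.na(compromised_mask)
  prot <- protected_mask & !is.na(protected_mask)
  c(pct_compromised = round(100 * sum(cm & comp) / n, 1),
    pct_protected = round(100 * sum(cm & prot) / n, 1))
}

#' Stacked richness maps for each group and overall
#'
#' Convenience wrapper producing the per-group richness maps, their tertile
#' masks, the all-species map and the richness center in one pass.
#'
#' @param land a [landscape()].
#' @param threshold presence threshold.
#' @param positive_only see [upper_tertile_mask()].
#' @return list with `by_group` (richness_map list), `all` (richness_map),
#'   `tertiles` (mask list), `center` ([richness_center()]), and a `summary`
#'   data.frame (group, tertile_cut, tertile_extent_km2, center_extent_km2).
#' @export
richness_analysis <- function(land, threshold = 0.5, positive_only = TRUE) {
  groups <- sort(unique(land$species_groups))
  pres <- presence_rasters(land, threshold = threshold)
  ca <- land$grid$cell_area
  by_group <- lapply(stats::setNames(groups, groups), function(g)
    stack_richness(pres[names(which(land$species_groups == g))], g, ca))
  tert <- lapply(by_group, upper_tertile_mask, positive_only = positive_only)
  center <- richness_center(tert, cell_area = ca)
  summary <- data.frame(
    group = groups,
    tertile_cut = vapply(tert, function(m) as.numeric(attr(m, "tertile_cut")),
                         numeric(1)),
    tertile_extent_km2 = vapply(tert, function(m) sum(m, na.rm = TRUE) * ca,
                                numeric(1)),
    center_extent_km2 = center$extent_km2, row.names = NULL)
  list(by_group = by_group, all = stack_richness(pres, "all", ca),
       tertiles = tert, center = center, summary = summary)
}
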