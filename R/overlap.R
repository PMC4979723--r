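#' Extent and overlap accounting
#'
#' All overlap statistics are computed on the cell grid (exact at grid
#' resolution): the area of a mask is its in-mask cell count times the cell
#' area, and overlaps are cellwise intersections. Reported tables round km^2
#' to integers and percentages to integers by default, matching the precision
#' conservation gap analyses usually print; `digits` restores 1-2 decimals.
#'
#' @name overlap_statistics
NULL

#' @rdname overlap_statistics
#' @param mask logical matrix (`NA` treated as `FALSE`).
#' @param cell_area km^2 per cell.
#' @return `area_of`: area in km^2.
#' @export
area_of <- function(mask, cell_area = 1) {
  sum(mask, na.rm = TRUE) * cell_area
}

#' @rdname overlap_statistics
#' @param part_km2,whole_km2 areas in km^2; `part` may not exceed `whole`.
#' @param digits decimals for the percentage (default 0).
#' @return `percent_cover`: 100 * part / whole, rounded.
#' @export
percent_cover <- function(part_km2, whole_km2, digits = 0) {
  if (whole_km2 <= 0) stop("whole extent must be positive")
  if (part_km2 > whole_km2 * (1 + 1e-9)) stop("part exceeds whole")
  round(100 * part_km2 / whole_km2, digits)
}

overlap_row <- function(a, b, a_mask, b_mask, base_km2, cell_area, digits) {
  ov <- area_of(a_mask & b_mask, cell_area)
  data.frame(element_a = a, element_b = b,
             overlap_km2 = round(ov),
             pct_of_a = percent_cover(ov, base_km2, digits),
             stringsAsFactors = FALSE)
}

#' Extent of reserves and oil blocks relative to the study area
#'
#' Six rows: protected areas (PA), untouchable areas (UA), their union
#' (protected zones), operative blocks, southern blocks, and all blocks —
#' each with its extent and its percent of the study area.
#'
#' @param land a [landscape()].
#' @param digits decimals on the percent column (default 0).
#' @return data.frame `element_a`, `element_b`, `overlap_km2`, `pct_of_a`.
#' @export
table1 <- function(land, digits = 0) {
  ca <- land$grid$cell_area
  study <- zone_mask(land$study_mask)
  study_km2 <- area_of(study, ca)
  pa <- zone_mask(land$protected_areas)
  ua <- zone_mask(land$untouchable_areas)
  oper <- zone_mask(land$operative_blocks)
  south <- zone_mask(land$southern_blocks)
  rows <- list(
    c("protected_areas", list(pa)), c("untouchable_areas", list(ua)),
    c("protected_zones", list(pa | ua)), c("operative_blocks", list(oper)),
    c("southern_blocks", list(south)), c("all_blocks", list(oper | south)))
  do.call(rbind, lapply(rows, function(r)
    overlap_row(r[[1]], "study_area", r[[2]], study, study_km2, ca, digits)))
}

#' Overlaps of oil blocks with protected zones
#'
#' Rows: PA in operative blocks, PA in southern blocks, UA in operative, UA
#' in southern, protected zones in all blocks, each named reserve in all
#' blocks, study area in blocks, protected zones free of blocks, and the
#' remainder with neither — percentages relative to the first-named element.
#'
#' @inheritParams table1
#' @export
table2 <- function(land, digits = 0) {
  ca <- land$grid$cell_area
  study <- zone_mask(land$study_mask)
  study_km2 <- area_of(study, ca)
  pa <- zone_mask(land$protected_areas)
  ua <- zone_mask(land$untouchable_areas)
  pz <- pa | ua
  blocks <- all_blocks_mask(land)
  oper <- zone_mask(land$operative_blocks)
  south <- zone_mask(land$southern_blocks)
  rows <- list(
    overlap_row("protected_areas", "operative_blocks", pa, oper,
                area_of(pa, ca), ca, digits),
    overlap_row("protected_areas", "southern_blocks", pa, south,
                area_of(pa, ca), ca, digits),
    overlap_row("untouchable_areas", "operative_blocks", ua, oper,
                area_of(ua, ca), ca, digits),
    overlap_row("untouchable_areas", "southern_blocks", ua, south,
                area_of(ua, ca), ca, digits),
    overlap_row("protected_zones", "all_blocks", pz, blocks,
                area_of(pz, ca), ca, digits))
  labels <- attr(land$protected_areas, "labels")
  for (id in names(labels)) {
    zm <- !is.na(land$protected_areas) & land$protected_areas == as.integer(id)
    zext <- area_of(zm, ca)
    if (zext > 0)
      rows[[length(rows) + 1]] <- overlap_row(labels[[id]], "all_blocks", zm,
                                              blocks, zext, ca, digits)
  }
  rows[[length(rows) + 1]] <-
    overlap_row("study_area", "all_blocks", study, blocks, study_km2, ca, digits)
  rows[[length(rows) + 1]] <-
    overlap_row("study_area", "protected_zones_without_blocks", study,
                pz & !blocks, study_km2, ca, digits)
  rows[[length(rows) + 1]] <-
    overlap_row("study_area", "neither_blocks_nor_protected", study,
                study & !pz & !blocks, study_km2, ca, digits)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-ecosystem block cover and effective protection
#'
#' For each ecosystem: percent of its extent inside oil blocks, and percent
#' inside *effective* protection — protected zones that coincide with neither
#' oil blocks nor deforested areas. Also returns summary counts: ecosystems
#' with > 50% and > 95% block cover, and with zero effective protection.
#'
#' @param land a [landscape()].
#' @param digits decimals on percentages (default 1).
#' @return list with `table` (data.frame `ecosystem_id`, `extent_km2`,
#'   `pct_in_blocks`, `pct_protected_free`) and `summary` (named counts
#'   `n_over_50_blocks`, `n_over_95_blocks`, `n_unprotected`,
#'   `n_touching_blocks`).
#' @export
ecosystem_coverage <- function(land, digits = 1) {
  ca <- land$grid$cell_area
  blocks <- all_blocks_mask(land)
  eff_prot <- protected_zones_mask(land) & !blocks & !zone_mask(land$deforested)
  ids <- sort(stats::na.omit(unique(as.vector(land$ecosystems))))
  tab <- do.call(rbind, lapply(ids, function(k) {
    em <- !is.na(land$ecosystems) & land$ecosystems == k
    ext <- area_of(em, ca)
    data.frame(ecosystem_id = k, extent_km2 = ext,
               pct_in_blocks = percent_cover(area_of(em & blocks, ca), ext, digits),
               pct_protected_free = percent_cover(area_of(em & eff_prot, ca),
                                                  ext, digits))
  }))
  list(table = tab,
       summary = c(n_over_50_blocks = sum(tab$pct_in_blocks > 50),
                   n_over_95_blocks = sum(tab$pct_in_blocks > 95),
                   n_unprotected = sum(tab$pct_protected_free == 0),
                   n_touching_blocks = sum(tab$pct_in_blocks > 0)))
}
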