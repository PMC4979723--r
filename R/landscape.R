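#' Assemble a landscape: the aligned raster stack for one study area
#'
#' A `landscape` bundles every spatial input of the planning pipeline on a
#' single [grid_spec()]: the study-area mask, one suitability surface per
#' species, the categorical ecosystem map, zone layers (reserves, untouchable
#' areas, operative and biddable oil blocks), the deforestation mask and the
#' threat layers feeding the environmental-risk surface. Outside the study
#' mask every layer is no-data.
#'
#' Zone layers are integer matrices whose values are stable zone ids with a
#' `labels` attribute (a named character vector, names = ids); `NA` means
#' "no zone".
#'
#' @param grid a [grid_spec()].
#' @param study_mask logical matrix; `TRUE` = inside the study area.
#' @param sdm_surfaces named list of numeric matrices in \[0, 1\], one
#'   suitability surface per species.
#' @param species_groups named character vector mapping each species to its
#'   taxonomic group (e.g. amphibian/bird/butterfly/mammal/plant).
#' @param priority_species named logical vector: is the species endemic or
#'   red-listed?
#' @param ecosystems integer matrix of ecosystem categories `1..K`; must
#'   partition the study mask (no `NA` inside it).
#' @param protected_areas,untouchable_areas,operative_blocks,southern_blocks
#'   zone rasters as described above (may be all-`NA`).
#' @param deforested logical matrix: cells without natural vegetation.
#' @param threat_layers named list; each element is either a `points`
#'   data.frame (`x`, `y`, optional `intensity`), a `lines` list of coordinate
#'   matrices, or a `field` raster in \[0, 1\] (see [threat_footprint()]).
#' @return an object of class `landscape`.
#' @export
landscape <- function(grid, study_mask, sdm_surfaces, species_groups,
                      priority_species = NULL, ecosystems,
                      protected_areas = NULL, untouchable_areas = NULL,
                      operative_blocks = NULL, southern_blocks = NULL,
                      deforested = NULL, threat_layers = list()) {
  stopifnot(inherits(grid, "grid_spec"))
  empty_zone <- function() {
    m <- matrix(NA_integer_, grid$n_rows, grid$n_cols)
    attr(m, "labels") <- character(0)
    m
  }
  if (is.null(protected_areas)) protected_areas <- empty_zone()
  if (is.null(untouchable_areas)) untouchable_areas <- empty_zone()
  if (is.null(operative_blocks)) operative_blocks <- empty_zone()
  if (is.null(southern_blocks)) southern_blocks <- empty_zone()
  if (is.null(deforested)) deforested <- matrix(FALSE, grid$n_rows, grid$n_cols)
  if (is.null(priority_species)) {
    priority_species <- stats::setNames(rep(FALSE, length(sdm_surfaces)),
                                        names(sdm_surfaces))
  }
  x <- structure(
    list(grid = grid, study_mask = study_mask, sdm_surfaces = sdm_surfaces,
         species_groups = species_groups, priority_species = priority_species,
         ecosystems = ecosystems, protected_areas = protected_areas,
         untouchable_areas = untouchable_areas,
         operative_blocks = operative_blocks,
         southern_blocks = southern_blocks, deforested = deforested,
         threat_layers = threat_layers),
    class = "landscape"
  )
  validate_landscape(x)
}

#' Validate a landscape's alignment and partition invariants
#'
#' Checks that every layer sits on the shared grid, that no layer carries
#' data outside the study mask, and that the ecosystem map partitions the
#' mask. Called by [landscape()]; exported so that landscapes read from disk
#' can be re-checked.
#'
#' @param x a `landscape`.
#' @return `x`, invisibly-checked (errors on violation).
#' @export
validate_landscape <- function(x) {
  grid <- x$grid
  check_aligned(x$study_mask, grid, "study_mask")
  if (!is.logical(x$study_mask)) stop("study_mask must be logical")
  mask <- x$study_mask & !is.na(x$study_mask)
  if (!any(mask)) stop("study mask is empty")
  for (sp in names(x$sdm_surfaces)) {
    s <- check_aligned(x$sdm_surfaces[[sp]], grid, paste0("sdm:", sp))
    v <- s[mask]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop(sprintf("suitability surface '%s' has values outside [0, 1]", sp))
    if (any(!is.na(s[!mask])))
      stop(sprintf("suitability surface '%s' has data outside the study mask", sp))
  }
  if (!setequal(names(x$sdm_surfaces), names(x$species_groups)))
    stop("species_groups must name exactly the species in sdm_surfaces")
  if (!all(names(x$sdm_surfaces) %in% names(x$priority_species)))
    stop("priority_species must cover every species")
  check_aligned(x$ecosystems, grid, "ecosystems")
  if (any(is.na(x$ecosystems[mask])))
    stop("ecosystems must partition the study mask (no-data inside mask)")
  if (any(!is.na(x$ecosystems[!mask])))
    stop("ecosystems has data outside the study mask")
  for (nm in c("protected_areas", "untouchable_areas",
               "operative_blocks", "southern_blocks")) {
    z <- check_aligned(x[[nm]], grid, nm)
    if (any(!is.na(z[!mask])))
      stop(sprintf("zone layer '%s' has data outside the study mask", nm))
  }
  check_aligned(x$deforested, grid, "deforested")
  if (any(x$deforested[!mask] & !is.na(x$deforested[!mask])))
    stop("deforested has data outside the study mask")
  invisible(x)
}

#' @export
print.landscape <- function(x, ...) {
  mask <- zone_mask(x$study_mask)
  cat(sprintf(paste0(
    "<landscape> %d x %d cells (%g km^2 in mask)\n",
    "  %d species in %d groups, %d ecosystems\n",
    "  zones: %d PA, %d UA, %d operative blocks, %d southern blocks\n"),
    x$grid$n_rows, x$grid$n_cols, sum(mask) * x$grid$cell_area,
    length(x$sdm_surfaces), length(unique(x$species_groups)),
    length(stats::na.omit(unique(as.vector(x$ecosystems)))),
    n_zones(x$protected_areas), n_zones(x$untouchable_areas),
    n_zones(x$operative_blocks), n_zones(x$southern_blocks)))
  invisible(x)
}

n_zones <- function(z) length(stats::na.omit(unique(as.vector(z))))

# logical in-mask view of a mask-like raster (NA -> FALSE)
zone_mask <- function(m) {
  if (is.logical(m)) m & !is.na(m) else !is.na(m)
}

#' Combined oil-block mask (operative plus southern/biddable blocks)
#' @param x a `landscape`.
#' @return logical matrix.
#' @export
all_blocks_mask <- function(x) {
  zone_mask(x$operative_blocks) | zone_mask(x$southern_blocks)
}

#' Combined protected-zone mask (protected areas plus untouchable areas)
#' @param x a `landscape`.
#' @return logical matrix.
#' @export
protected_zones_mask <- function(x) {
  zone_mask(x$protected_areas) | zone_mask(x$untouchable_areas)
}
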