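#' Raster and table I/O
#'
#' Rasters are stored as single-band ESRI ASCII grids (`.asc`): a plain-text
#' header (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value)
#' followed by the cell values, row 1 = north. Values are written with 17
#' significant digits so `read_asc(write_asc(x))` reproduces doubles exactly.
#' Zone layers travel either as integer `.asc` rasters plus a label CSV, or
#' as GeoJSON polygon layers rasterized at cell centres.
#'
#' @param raster numeric/integer/logical matrix (`NA` = no-data).
#' @param grid the [grid_spec()] the raster sits on.
#' @param path file path.
#' @return `write_asc`: `path`, invisibly. `read_asc`: list with `raster`
#'   (numeric matrix) and `grid` (a [grid_spec()]).
#' @name raster_io
NULL

#' @rdname raster_io
#' @export
write_asc <- function(raster, grid, path) {
  check_aligned(raster, grid, basename(path))
  side <- cell_side_km(grid)
  hdr <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.17g", grid$origin[1]),
    sprintf("yllcorner %.17g", grid$origin[2] - grid$n_rows * side),
    sprintf("cellsize %.17g", side),
    "NODATA_value -9999")
  vals <- matrix(as.numeric(raster), nrow(raster), ncol(raster))
  vals[is.na(vals)] <- -9999
  body <- apply(vals, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname raster_io
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, " "), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  n_cols <- as.integer(val("ncols")); n_rows <- as.integer(val("nrows"))
  side <- val("cellsize"); nodata <- val("NODATA_value")
  x0 <- val("xllcorner"); y0 <- val("yllcorner") + n_rows * side
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, n_rows, n_cols, byrow = TRUE)
  m[m == nodata] <- NA
  list(raster = m,
       grid = grid_spec(n_rows, n_cols, cell_area = side^2, origin = c(x0, y0)))
}

# even-odd (ray casting) point-in-polygon; ring: 2-col matrix of vertices
points_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]; xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize a GeoJSON polygon layer to a zone raster
#'
#' Cells whose centre falls inside a feature's polygon (even-odd rule, holes
#' honoured) take that feature's zone id. Later features overwrite earlier
#' ones where polygons overlap. Feature ids come from an `id` property when
#' present, otherwise the 1-based feature order; labels from a `label` or
#' `name` property.
#'
#' @param path GeoJSON file with a FeatureCollection of Polygon/MultiPolygon
#'   features (planar km coordinates, matching the grid's CRS convention).
#' @param grid the target [grid_spec()].
#' @param mask optional logical matrix; cells outside it stay no-data.
#' @return integer zone matrix with a `labels` attribute.
#' @export
read_zones_geojson <- function(path, grid, mask = NULL) {
  gj <- jsonlite::read_json(path)
  cc <- cell_centers(grid)
  px <- as.vector(cc$x); py <- as.vector(cc$y)
  z <- rep(NA_integer_, length(px))
  labels <- character(0)
  for (k in seq_along(gj$features)) {
    ft <- gj$features[[k]]
    props <- ft$properties
    id <- if (!is.null(props$id)) as.integer(props$id) else k
    lab <- if (!is.null(props$label)) props$label
           else if (!is.null(props$name)) props$name else paste0("zone_", id)
    geom <- ft$geometry
    polys <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("unsupported geometry type: ", geom$type))
    inside <- rep(FALSE, length(px))
    for (poly in polys) {
      for (ring in poly) {
        m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
        inside <- xor(inside, points_in_ring(px, py, m))
      }
    }
    z[inside] <- id
    labels[as.character(id)] <- lab
  }
  zm <- matrix(z, grid$n_rows, grid$n_cols)
  if (!is.null(mask)) zm[!zone_mask(mask)] <- NA_integer_
  attr(zm, "labels") <- labels
  zm
}

write_zone_layer <- function(z, grid, stem) {
  write_asc(z, grid, paste0(stem, ".asc"))
  labels <- attr(z, "labels")
  utils::write.csv(
    data.frame(zone_id = as.integer(names(labels)),
               label = as.character(labels), stringsAsFactors = FALSE),
    paste0(stem, "_labels.csv"), row.names = FALSE)
}

read_zone_layer <- function(stem, grid) {
  r <- read_asc(paste0(stem, ".asc"))
  if (!same_grid(r$grid, grid))
    stop(sprintf("misaligned grid in '%s.asc': expected %d x %d (cell %g km^2)",
                 stem, grid$n_rows, grid$n_cols, grid$cell_area))
  z <- matrix(as.integer(r$raster), grid$n_rows, grid$n_cols)
  lab <- utils::read.csv(paste0(stem, "_labels.csv"), stringsAsFactors = FALSE)
  attr(z, "labels") <- stats::setNames(as.character(lab$label),
                                       as.character(lab$zone_id))
  z
}

#' Write / read a landscape as a directory of plain-text layers
#'
#' Layers are `.asc` rasters (one per species, plus mask/ecosystems/zones/
#' deforestation), CSV tables for the species registry and zone labels, and a
#' JSON manifest recording the grid. `read_landscape(write_landscape(x))`
#' reproduces every raster value exactly and re-validates the result.
#' Threat point/line layers are stored as CSV (points: `x,y,intensity`;
#' lines: `line_id,x,y` vertex tables); threat fields as `.asc`.
#'
#' @param land a [landscape()].
#' @param dir target directory (created if needed).
#' @return `write_landscape`: `dir` invisibly; `read_landscape`: a
#'   [landscape()].
#' @export
write_landscape <- function(land, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "sdm"), showWarnings = FALSE)
  g <- land$grid
  jsonlite::write_json(
    list(n_rows = g$n_rows, n_cols = g$n_cols, cell_area = g$cell_area,
         origin = g$origin, species = names(land$sdm_surfaces)),
    file.path(dir, "landscape.json"), auto_unbox = TRUE, digits = NA)
  write_asc(land$study_mask, g, file.path(dir, "study_mask.asc"))
  write_asc(land$ecosystems, g, file.path(dir, "ecosystems.asc"))
  write_asc(land$deforested, g, file.path(dir, "deforested.asc"))
  for (sp in names(land$sdm_surfaces))
    write_asc(land$sdm_surfaces[[sp]], g, file.path(dir, "sdm", paste0(sp, ".asc")))
  utils::write.csv(
    data.frame(species = names(land$sdm_surfaces),
               group = land$species_groups[names(land$sdm_surfaces)],
               priority = land$priority_species[names(land$sdm_surfaces)],
               stringsAsFactors = FALSE),
    file.path(dir, "species.csv"), row.names = FALSE)
  for (nm in c("protected_areas", "untouchable_areas",
               "operative_blocks", "southern_blocks"))
    write_zone_layer(land[[nm]], g, file.path(dir, nm))
  for (nm in names(land$threat_layers)) {
    tl <- land$threat_layers[[nm]]
    if (!is.null(tl$points)) {
      utils::write.csv(tl$points, file.path(dir, paste0("threat_", nm, "_points.csv")),
                       row.names = FALSE)
    } else if (!is.null(tl$lines)) {
      tab <- do.call(rbind, lapply(seq_along(tl$lines), function(i)
        data.frame(line_id = i, x = tl$lines[[i]][, 1], y = tl$lines[[i]][, 2])))
      utils::write.csv(tab, file.path(dir, paste0("threat_", nm, "_lines.csv")),
                       row.names = FALSE)
    } else if (!is.null(tl$field)) {
      write_asc(tl$field, g, file.path(dir, paste0("threat_", nm, "_field.asc")))
    }
  }
  invisible(dir)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "landscape.json"),
                              simplifyVector = TRUE)
  g <- grid_spec(meta$n_rows, meta$n_cols, meta$cell_area, meta$origin)
  rd <- function(name) {
    r <- read_asc(file.path(dir, paste0(name, ".asc")))
    if (!same_grid(r$grid, g))
      stop(sprintf("misaligned grid in '%s': expected %d x %d (cell %g km^2)",
                   name, g$n_rows, g$n_cols, g$cell_area))
    r$raster
  }
  spp <- utils::read.csv(file.path(dir, "species.csv"), stringsAsFactors = FALSE)
  sdm <- lapply(spp$species, function(sp) {
    r <- read_asc(file.path(dir, "sdm", paste0(sp, ".asc")))
    if (!same_grid(r$grid, g))
      stop(sprintf("misaligned grid in 'sdm/%s': expected %d x %d", sp,
                   g$n_rows, g$n_cols))
    r$raster
  })
  names(sdm) <- spp$species
  threats <- list()
  for (f in list.files(dir, pattern = "^threat_")) {
    nm <- sub("^threat_", "", sub("_(points\\.csv|lines\\.csv|field\\.asc)$", "", f))
    if (grepl("_points\\.csv$", f)) {
      threats[[nm]] <- list(points = utils::read.csv(file.path(dir, f)))
    } else if (grepl("_lines\\.csv$", f)) {
      tab <- utils::read.csv(file.path(dir, f))
      threats[[nm]] <- list(lines = lapply(split(tab, tab$line_id), function(d)
        cbind(d$x, d$y)))
    } else {
      threats[[nm]] <- list(field = read_asc(file.path(dir, f))$raster)
    }
  }
  landscape(
    grid = g,
    study_mask = rd("study_mask") == 1,
    sdm_surfaces = sdm,
    species_groups = stats::setNames(spp$group, spp$species),
    priority_species = stats::setNames(as.logical(spp$priority), spp$species),
    ecosystems = matrix(as.integer(rd("ecosystems")), g$n_rows, g$n_cols),
    protected_areas = read_zone_layer(file.path(dir, "protected_areas"), g),
    untouchable_areas = read_zone_layer(file.path(dir, "untouchable_areas"), g),
    operative_blocks = read_zone_layer(file.path(dir, "operative_blocks"), g),
    southern_blocks = read_zone_layer(file.path(dir, "southern_blocks"), g),
    deforested = rd("deforested") == 1,
    threat_layers = threats)
}

#' Write the planning-unit and feature tables of a problem
#'
#' Mirrors Marxan's dat-file semantics in CSV: `pu.csv` (pu_id, area_km2,
#' cost, status), `features.csv` (feature_id, kind, total_extent_km2,
#' protected_km2), `amounts.csv` in long format (feature_id, pu_id,
#' amount_km2; zero rows omitted), and `bound.csv` (id1, id2, boundary_km).
#'
#' @param pus a [tessellate()] result.
#' @param fm a [build_feature_matrix()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_problem_tables <- function(pus, fm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(pus$pu, file.path(dir, "pu.csv"), row.names = FALSE)
  utils::write.csv(fm$features, file.path(dir, "features.csv"), row.names = FALSE)
  nz <- which(fm$amounts > 0, arr.ind = TRUE)
  long <- data.frame(feature_id = rownames(fm$amounts)[nz[, 1]],
                     pu_id = nz[, 2], amount_km2 = fm$amounts[nz],
                     stringsAsFactors = FALSE)
  long <- long[order(long$feature_id, long$pu_id), ]
  utils::write.csv(long, file.path(dir, "amounts.csv"), row.names = FALSE)
  utils::write.csv(pus$adjacency, file.path(dir, "bound.csv"), row.names = FALSE)
  invisible(dir)
}
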