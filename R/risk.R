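#' Threat specification for the environmental-risk surface
#'
#' Each threat to biodiversity (human population density, agriculture and
#' cattle ranching, mining, oil wells, dams, roads, airports) contributes a
#' footprint raster that decays with distance from its sources. Defaults —
#' equal weights, linear decay, radii of 2 km for roads, 1 km for wells, 5 km
#' for dams and airports, pass-through for density fields — are declared
#' stand-ins exposed in configuration, not estimated values.
#'
#' @param name threat name.
#' @param weight nonnegative contribution weight (default 1).
#' @param decay_radius km beyond which the threat's influence is zero.
#' @param kernel `"linear"` (`1 - d/radius`) or `"exponential"`
#'   (`exp(-3 d / radius)`, truncated at the radius).
#' @return object of class `threat_spec`.
#' @export
threat_spec <- function(name, weight = 1, decay_radius = 2,
                        kernel = c("linear", "exponential")) {
  kernel <- match.arg(kernel)
  stopifnot(weight >= 0, decay_radius >= 0)
  structure(list(name = name, weight = weight, decay_radius = decay_radius,
                 kernel = kernel), class = "threat_spec")
}

#' Default threat specifications
#' @return named list of [threat_spec()]s for the seven standard threats.
#' @export
default_threat_specs <- function() {
  list(population = threat_spec("population", decay_radius = 0),
       agriculture = threat_spec("agriculture", decay_radius = 0),
       mining = threat_spec("mining", decay_radius = 2),
       oil_wells = threat_spec("oil_wells", decay_radius = 1),
       dams = threat_spec("dams", decay_radius = 5),
       roads = threat_spec("roads", decay_radius = 2),
       airports = threat_spec("airports", decay_radius = 5))
}

kernel_value <- function(d, spec) {
  if (spec$decay_radius <= 0) return(as.numeric(d <= 0))
  v <- switch(spec$kernel,
              linear = pmax(0, 1 - d / spec$decay_radius),
              exponential = exp(-3 * d / spec$decay_radius))
  v[d > spec$decay_radius] <- 0
  v
}

dist_to_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  t <- if (len2 == 0) rep(0, length(px))
       else pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

#' Footprint raster of one threat layer
#'
#' Point and line sources spread by the spec's decay kernel; where several
#' sources reach a cell the strongest one wins (cellwise max). Field layers
#' (population, agriculture) pass through, rescaled to \[0, 1\] by their
#' maximum when they exceed it.
#'
#' @param layer a threat layer: list with one of `points` (data.frame `x`,
#'   `y`, optional `intensity` in \[0, 1\]), `lines` (list of 2-column
#'   vertex matrices), or `field` (raster).
#' @param spec a [threat_spec()].
#' @param grid the [grid_spec()].
#' @param mask optional study mask; outside cells are set to `NA`.
#' @return numeric matrix in \[0, 1\].
#' @export
threat_footprint <- function(layer, spec, grid, mask = NULL) {
  cc <- cell_centers(grid)
  px <- as.vector(cc$x); py <- as.vector(cc$y)
  fp <- rep(0, length(px))
  if (!is.null(layer$field)) {
    f <- layer$field
    check_aligned(f, grid, spec$name)
    v <- f
    mx <- max(v, na.rm = TRUE)
    if (is.finite(mx) && mx > 1) v <- v / mx
    v[v < 0] <- 0
    fp <- as.vector(v)
    fp[is.na(fp)] <- 0
  } else if (!is.null(layer$points)) {
    pts <- layer$points
    if (nrow(pts) > 0) {
      inten <- if (!is.null(pts$intensity)) pts$intensity else rep(1, nrow(pts))
      for (i in seq_len(nrow(pts))) {
        d <- sqrt((px - pts$x[i])^2 + (py - pts$y[i])^2)
        fp <- pmax(fp, inten[i] * kernel_value(d, spec))
      }
    }
  } else if (!is.null(layer$lines)) {
    for (ln in layer$lines) {
      if (nrow(ln) < 2) next
      for (s in seq_len(nrow(ln) - 1)) {
        d <- dist_to_segment(px, py, ln[s, 1], ln[s, 2], ln[s + 1, 1], ln[s + 1, 2])
        fp <- pmax(fp, kernel_value(d, spec))
      }
    }
  }
  out <- matrix(fp, grid$n_rows, grid$n_cols)
  if (!is.null(mask)) out[!zone_mask(mask)] <- NA
  out
}

#' Compose threat footprints into the environmental-risk surface (ERS)
#'
#' The ERS is the weighted mean of the normalized footprints, affinely
#' rescaled so zero threat maps to 0 and the theoretical maximum (every
#' threat at full intensity) maps to 100, then clipped to \[0, 100\]. Pixels
#' above the exclusion `threshold` (default 32) count as highly impacted.
#'
#' @param footprints named list of [threat_footprint()] rasters.
#' @param specs named list of [threat_spec()]s (weights used).
#' @param threshold high-impact threshold carried on the result (default 32).
#' @return object of class `ers`: list with `values` (matrix in \[0, 100\])
#'   and `threshold`.
#' @export
compose_ers <- function(footprints, specs, threshold = 32) {
  w <- vapply(specs[names(footprints)], function(s) s$weight, numeric(1))
  if (all(w == 0)) stop("all threat weights are zero")
  acc <- 0
  for (nm in names(footprints)) acc <- acc + w[[nm]] * footprints[[nm]]
  vals <- 100 * acc / sum(w)
  vals[vals < 0] <- 0; vals[vals > 100] <- 100
  structure(list(values = vals, threshold = threshold), class = "ers")
}

#' @export
print.ers <- function(x, ...) {
  cat(sprintf("<ers> impact 0-100, mean %.1f, %d cells above threshold %g\n",
              mean(x$values, na.rm = TRUE),
              sum(x$values > x$threshold, na.rm = TRUE), x$threshold))
  invisible(x)
}

#' High-impact exclusion mask from an ERS
#'
#' @param ers an [compose_ers()] result.
#' @param threshold impact value; cells *strictly above* it are flagged
#'   (default: the ERS's own threshold, 32) — a pixel exactly at the
#'   threshold stays available.
#' @return logical matrix.
#' @export
high_impact_mask <- function(ers, threshold = ers$threshold) {
  ers$values > threshold
}

#' Planning-unit cost from the ERS
#'
#' Each PU's cost equals its environmental impact — the mean ERS over its
#' member cells — floored at a small positive epsilon so pristine PUs still
#' carry cost (a zero-cost PU would make the minimum-set objective
#' degenerate).
#'
#' @param ers an [compose_ers()] result.
#' @param pus a [tessellate()] result.
#' @param epsilon cost floor (default 0.01).
#' @return the `planning_units` with `pu$cost` filled.
#' @export
pu_cost <- function(ers, pus, epsilon = 0.01) {
  ids <- pus$pu_raster[!is.na(pus$pu_raster)]
  vals <- ers$values[!is.na(pus$pu_raster)]
  m <- tapply(vals, factor(ids, levels = seq_len(nrow(pus$pu))), mean)
  pus$pu$cost <- pmax(as.numeric(m), epsilon)
  pus
}
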