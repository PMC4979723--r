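#' Combined oil-block zone raster
#'
#' Operative and southern blocks merged into one id space (southern ids are
#' offset past the operative ones); labels preserved.
#'
#' @param land a [landscape()].
#' @return integer zone matrix with `labels` and `kind` attributes.
#' @export
oil_blocks_zones <- function(land) {
  oper <- land$operative_blocks
  south <- land$southern_blocks
  off <- max(0L, suppressWarnings(max(oper, na.rm = TRUE)))
  if (!is.finite(off)) off <- 0L
  z <- oper
  idx <- !is.na(south)
  z[idx] <- south[idx] + off
  lab_o <- attr(oper, "labels"); lab_s <- attr(south, "labels")
  labels <- c(lab_o, stats::setNames(lab_s,
                as.character(as.integer(names(lab_s)) + off)))
  attr(z, "labels") <- labels
  attr(z, "kind") <- stats::setNames(
    c(rep("operative", length(lab_o)), rep("southern", length(lab_s))),
    names(labels))
  z
}

#' Per-block conservation metrics
#'
#' For every oil block: (1) species diversity — the mean of the min-max
#' normalized (across blocks) averages of total species richness and
#' priority-species richness over the block's cells; (2) ecosystem diversity
#' — the number of ecosystems present; (3) land preservation — natural
#' (non-deforested) vegetation area divided by block area; (4) conservation
#' overlap — the fraction of the block inside priority areas or protected
#' zones.
#'
#' @param land a [landscape()].
#' @param total_richness a [stack_richness()] map over all species.
#' @param priority_richness a [stack_richness()] map over priority (endemic /
#'   red-listed) species; pass `NULL` if no species is flagged (the priority
#'   mean is then 0 everywhere).
#' @param priority_cells logical matrix of priority-area cells (e.g.
#'   [pu_mask_to_cells()] of [priority_areas()], conventionally from the
#'   all-blocks-selectable scenario).
#' @param richness_weights length-2 weights combining the two normalized
#'   richness means (default equal).
#' @return data.frame: `block_id`, `label`, `kind`, `area_km2`,
#'   `mean_total_richness`, `mean_priority_richness`, `species_diversity`,
#'   `n_ecosystems`, `preservation`, `conservation_overlap`.
#' @export
block_metrics <- function(land, total_richness, priority_richness,
                          priority_cells, richness_weights = c(0.5, 0.5)) {
  z <- oil_blocks_zones(land)
  ids <- sort(stats::na.omit(unique(as.vector(z))))
  labels <- attr(z, "labels"); kind <- attr(z, "kind")
  pz <- protected_zones_mask(land)
  conserved <- (priority_cells & !is.na(priority_cells)) | pz
  ca <- land$grid$cell_area
  rows <- lapply(ids, function(id) {
    bm <- !is.na(z) & z == id
    n <- sum(bm)
    data.frame(
      block_id = id, label = labels[[as.character(id)]],
      kind = kind[[as.character(id)]], area_km2 = n * ca,
      mean_total_richness = mean(total_richness$values[bm], na.rm = TRUE),
      mean_priority_richness = if (is.null(priority_richness)) 0 else
        mean(priority_richness$values[bm], na.rm = TRUE),
      n_ecosystems = length(stats::na.omit(unique(land$ecosystems[bm]))),
      preservation = sum(bm & !zone_mask(land$deforested)) / n,
      conservation_overlap = sum(bm & conserved) / n,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  minmax <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) rep(0, length(v)) else (v - r[1]) / (r[2] - r[1])
  }
  w <- richness_weights / sum(richness_weights)
  out$species_diversity <- w[1] * minmax(out$mean_total_richness) +
    w[2] * minmax(out$mean_priority_richness)
  out
}

#' Quartile scores 1 (bottom) to 4 (top)
#'
#' Nearest-rank quartile assignment: a block's score is 1 plus the number of
#' quartile cuts its value strictly exceeds, so tied values share the lower
#' score (ambiguous blocks are not inflated) and quartile sizes differ by at
#' most one when values are distinct.
#'
#' @param values numeric vector across blocks (length >= 4).
#' @return integer scores in 1..4.
#' @export
quartile_scores <- function(values) {
  n <- length(values)
  if (n < 4)
    stop("need at least 4 blocks for quartile scores; rank the ",
         n, " blocks directly instead")
  s <- sort(values)
  cuts <- s[ceiling(c(0.25, 0.5, 0.75) * n)]
  as.integer(1 + vapply(values, function(v) sum(v > cuts), numeric(1)))
}

#' Oil-block importance index
#'
#' Each of the four block metrics is scored into quartiles (1 bottom .. 4
#' top); a block's importance index is the sum of its four scores, between 4
#' and 16.
#'
#' @param metrics a [block_metrics()] data.frame.
#' @return the metrics with `q_species_diversity`, `q_n_ecosystems`,
#'   `q_preservation`, `q_conservation_overlap` and `importance_index`
#'   columns appended, sorted by decreasing index.
#' @export
importance_index <- function(metrics) {
  metrics$q_species_diversity <- quartile_scores(metrics$species_diversity)
  metrics$q_n_ecosystems <- quartile_scores(metrics$n_ecosystems)
  metrics$q_preservation <- quartile_scores(metrics$preservation)
  metrics$q_conservation_overlap <-
    quartile_scores(metrics$conservation_overlap)
  metrics$importance_index <- metrics$q_species_diversity +
    metrics$q_n_ecosystems + metrics$q_preservation +
    metrics$q_conservation_overlap
  metrics[order(-metrics$importance_index, metrics$block_id), ]
}
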