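#' Build the per-feature, per-planning-unit amount matrix
#'
#' For every conservation feature — each species and each ecosystem — compute
#' the amount (km^2) falling inside each planning unit. Species surfaces are
#' binarized at `binarize_threshold` (presence where suitability >= threshold)
#' in the default `"thresholded"` mode; `"continuous"` mode instead sums the
#' raw suitability values times cell area, for stacking untruncated model
#' outputs. Ecosystem amounts count the cells of each category.
#'
#' @param land a [landscape()].
#' @param pus a [tessellate()] result (lock status, if already applied, seeds
#'   the per-feature protected amounts).
#' @param binarize_threshold presence threshold on the \[0, 1\] suitability
#'   scale; default 0.5.
#' @param mode `"thresholded"` (default) or `"continuous"`.
#' @return an object of class `feature_amounts`: list with
#'   \describe{
#'     \item{features}{data.frame `feature_id`, `kind` (species/ecosystem),
#'       `total_extent_km2`, `protected_km2`}
#'     \item{amounts}{numeric matrix, features (rows, named) x PUs (cols)}
#'   }
#' @export
build_feature_matrix <- function(land, pus, binarize_threshold = 0.5,
                                 mode = c("thresholded", "continuous")) {
  mode <- match.arg(mode)
  grid <- land$grid
  mask <- zone_mask(land$study_mask)
  ids <- pus$pu_raster[mask]
  n_pu <- nrow(pus$pu)
  ca <- grid$cell_area

  amount_of <- function(vals) {  # vals: per in-mask-cell weight
    v <- tapply(vals, factor(ids, levels = seq_len(n_pu)), sum)
    out <- as.numeric(v) * ca
    out[is.na(out)] <- 0
    out
  }

  sp_names <- names(land$sdm_surfaces)
  sp_rows <- lapply(sp_names, function(sp) {
    s <- land$sdm_surfaces[[sp]][mask]
    s[is.na(s)] <- 0
    w <- if (mode == "thresholded") as.numeric(s >= binarize_threshold) else s
    amount_of(w)
  })
  eco_ids <- sort(stats::na.omit(unique(as.vector(land$ecosystems))))
  eco_vals <- land$ecosystems[mask]
  eco_rows <- lapply(eco_ids, function(k) amount_of(as.numeric(eco_vals == k)))

  amounts <- do.call(rbind, c(sp_rows, eco_rows))
  rownames(amounts) <- c(sp_names, sprintf("eco_%02d", eco_ids))
  kind <- c(rep("species", length(sp_names)), rep("ecosystem", length(eco_ids)))

  total <- rowSums(amounts)
  zero <- total <= 0
  if (any(zero)) {
    stop("features with zero total extent: ",
         paste(rownames(amounts)[zero], collapse = ", "))
  }
  locked_in <- pus$pu$status == "locked_in"
  protected <- if (any(locked_in)) rowSums(amounts[, locked_in, drop = FALSE])
               else numeric(nrow(amounts))

  structure(
    list(features = data.frame(feature_id = rownames(amounts), kind = kind,
                               total_extent_km2 = total,
                               protected_km2 = protected,
                               stringsAsFactors = FALSE, row.names = NULL),
         amounts = amounts),
    class = "feature_amounts"
  )
}

#' @export
print.feature_amounts <- function(x, ...) {
  cat(sprintf("<feature_amounts> %d features (%d species, %d ecosystems) x %d PUs\n",
              nrow(x$amounts), sum(x$features$kind == "species"),
              sum(x$features$kind == "ecosystem"), ncol(x$amounts)))
  invisible(x)
}

#' Recompute per-feature protected amounts for a lock assignment
#'
#' @param fm a [build_feature_matrix()] result.
#' @param pus planning units whose `status` column holds the lock states.
#' @return `fm` with `features$protected_km2` refreshed.
#' @export
refresh_protected_amounts <- function(fm, pus) {
  locked_in <- pus$pu$status == "locked_in"
  fm$features$protected_km2 <-
    if (any(locked_in)) rowSums(fm$amounts[, locked_in, drop = FALSE])
    else numeric(nrow(fm$amounts))
  fm
}
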