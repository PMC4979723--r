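#' Range-size-dependent conservation target scheme
#'
#' Conservation targets assign each feature the fraction of its extent that a
#' reserve network must represent. Small-ranged features get the highest
#' target `t_max`, widespread ones the lowest `t_min`, with linear
#' interpolation between the range-size thresholds; the whole scheme is then
#' multiplied by a scenario factor `scale`. The base scheme spans 90-10% of a
#' feature's extent; scaling it to 0.4 yields the 36-4% targets that remain
#' achievable at regional scale. Species use range thresholds of
#' 10,000 / 75,000 km^2, ecosystems 100 / 10,000 km^2.
#'
#' @param t_max,t_min base target fractions at the small/large range
#'   endpoints (defaults 0.90 and 0.10).
#' @param species_thresholds,ecosystem_thresholds length-2 numeric
#'   `(A_small, A_large)` in km^2.
#' @param scale scenario scaling factor in (0, 1] (default 0.4).
#' @return object of class `target_scheme`.
#' @export
target_scheme <- function(t_max = 0.90, t_min = 0.10,
                          species_thresholds = c(10000, 75000),
                          ecosystem_thresholds = c(100, 10000),
                          scale = 0.4) {
  stopifnot(0 < t_min, t_min < t_max, t_max <= 1, 0 < scale, scale <= 1,
            species_thresholds[1] < species_thresholds[2],
            ecosystem_thresholds[1] < ecosystem_thresholds[2])
  structure(list(t_max = t_max, t_min = t_min,
                 species_thresholds = species_thresholds,
                 ecosystem_thresholds = ecosystem_thresholds, scale = scale),
            class = "target_scheme")
}

#' Halve a target scheme's scenario factor
#'
#' Halving applies to the already-scaled scheme (0.4 becomes 0.2, i.e. 18-2%
#' endpoint targets), used to re-run a scenario with more modest goals.
#'
#' @param scheme a [target_scheme()].
#' @return the scheme with `scale` halved.
#' @export
halve_targets <- function(scheme) {
  scheme$scale <- scheme$scale / 2
  scheme
}

#' Target fraction for a feature of a given range size
#'
#' @param range_km2 the feature's total extent (> 0); vectorized.
#' @param kind `"species"` or `"ecosystem"` (selects the thresholds).
#' @param scheme a [target_scheme()].
#' @return target fraction(s) in (0, `scale * t_max`\].
#' @export
target_fraction <- function(range_km2, kind = c("species", "ecosystem"),
                            scheme = target_scheme()) {
  kind <- match.arg(kind)
  if (any(range_km2 <= 0)) stop("range_km2 must be positive")
  th <- if (kind == "species") scheme$species_thresholds
        else scheme$ecosystem_thresholds
  frac <- ifelse(
    range_km2 < th[1], scheme$t_max,
    ifelse(range_km2 > th[2], scheme$t_min,
           scheme$t_max + (scheme$t_min - scheme$t_max) *
             (range_km2 - th[1]) / (th[2] - th[1])))
  scheme$scale * frac
}

#' Build the per-feature target table
#'
#' One row per feature with its target fraction and amount; achievement is
#' initialized from the amount already inside locked-in (protected) planning
#' units, so features well covered by existing reserves can be met before any
#' selection happens.
#'
#' @param fm a [build_feature_matrix()] result (with protected amounts
#'   reflecting the current lock assignment; see
#'   [refresh_protected_amounts()]).
#' @param scheme a [target_scheme()].
#' @param met_tol relative tolerance on "met" (default 1e-9, absorbing float
#'   accumulation).
#' @return data.frame of class `target_table`: `feature_id`, `kind`,
#'   `extent_km2`, `target_fraction`, `target_km2`, `achieved_km2`, `met`.
#' @export
build_target_table <- function(fm, scheme = target_scheme(), met_tol = 1e-9) {
  ft <- fm$features
  frac <- numeric(nrow(ft))
  for (k in c("species", "ecosystem")) {
    i <- ft$kind == k
    if (any(i)) frac[i] <- target_fraction(ft$total_extent_km2[i], k, scheme)
  }
  tt <- data.frame(feature_id = ft$feature_id, kind = ft$kind,
                   extent_km2 = ft$total_extent_km2,
                   target_fraction = frac,
                   target_km2 = frac * ft$total_extent_km2,
                   achieved_km2 = ft$protected_km2,
                   stringsAsFactors = FALSE)
  tt$met <- tt$achieved_km2 >= tt$target_km2 * (1 - met_tol)
  class(tt) <- c("target_table", class(tt))
  tt
}

#' Target achievement of a solution
#'
#' @param selected integer/logical vector of selected PUs (including
#'   locked-in ones).
#' @param fm a [build_feature_matrix()] result.
#' @param targets a [build_target_table()] result.
#' @param met_tol relative tolerance on "met".
#' @return list with `per_feature` (data.frame feature_id, kind,
#'   achieved_km2, target_km2, met) and `summary` (named percentages
#'   `pct_species_met`, `pct_ecosystems_met`, `pct_all_met`).
#' @export
achievement_report <- function(selected, fm, targets, met_tol = 1e-9) {
  sel <- if (is.logical(selected)) which(selected) else selected
  achieved <- if (length(sel) > 0)
    rowSums(fm$amounts[, sel, drop = FALSE]) else numeric(nrow(fm$amounts))
  stopifnot(identical(rownames(fm$amounts), targets$feature_id))
  met <- achieved >= targets$target_km2 * (1 - met_tol)
  pf <- data.frame(feature_id = targets$feature_id, kind = targets$kind,
                   achieved_km2 = achieved, target_km2 = targets$target_km2,
                   met = met, stringsAsFactors = FALSE)
  pct <- function(i) if (any(i)) 100 * mean(met[i]) else NA_real_
  list(per_feature = pf,
       summary = c(pct_species_met = pct(targets$kind == "species"),
                   pct_ecosystems_met = pct(targets$kind == "ecosystem"),
                   pct_all_met = 100 * mean(met)))
}
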