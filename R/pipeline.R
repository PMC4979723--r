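#' Configuration of an end-to-end prioritization run
#'
#' Validates every knob of the pipeline before any stage runs.
#'
#' @param landscape a [landscape()], a [synth_config()] to generate one, or a
#'   directory path for [read_landscape()].
#' @param pu_area planning-unit area in km^2 (default 3.45, the regional
#'   unit size).
#' @param binarize_threshold suitability presence threshold (default 0.5).
#' @param scheme a [target_scheme()] (default: 90-10% scaled by 0.4).
#' @param ers_threshold high-impact exclusion cut on the 0-100 risk surface
#'   (default 32).
#' @param threat_specs named list of [threat_spec()]s (default
#'   [default_threat_specs()]).
#' @param scenarios integer subset of 1:3 (default all three).
#' @param n_reps annealing replicates per scenario (default 100).
#' @param n_iter proposals per replicate (default 1e5).
#' @param restarts best-of-k restarts inside each replicate (default 4).
#' @param priority_threshold selection-frequency cut for priority areas
#'   (default 75).
#' @param spf species penalty factor (default 10).
#' @param blm boundary-length modifier (default 0).
#' @param seed master seed; replicate k of scenario s uses
#'   `seed + 1000 * s + k`.
#' @return object of class `run_config`.
#' @export
run_config <- function(landscape, pu_area = 3.45, binarize_threshold = 0.5,
                       scheme = target_scheme(), ers_threshold = 32,
                       threat_specs = default_threat_specs(),
                       scenarios = 1:3, n_reps = 100, n_iter = 1e5,
                       restarts = 4, priority_threshold = 75, spf = 10,
                       blm = 0, seed = 1) {
  stopifnot(inherits(scheme, "target_scheme"),
            all(scenarios %in% 1:3), length(scenarios) >= 1,
            pu_area > 0, binarize_threshold >= 0, binarize_threshold <= 1,
            ers_threshold >= 0, n_reps >= 1, n_iter >= 1,
            priority_threshold >= 0, priority_threshold <= n_reps,
            spf > 0, blm >= 0, is.numeric(seed))
  stopifnot(restarts >= 1)
  structure(list(landscape = landscape, pu_area = pu_area,
                 binarize_threshold = binarize_threshold, scheme = scheme,
                 ers_threshold = ers_threshold, threat_specs = threat_specs,
                 scenarios = scenarios, n_reps = n_reps, n_iter = n_iter,
                 restarts = restarts,
                 priority_threshold = priority_threshold, spf = spf,
                 blm = blm, seed = seed),
            class = "run_config")
}

resolve_landscape <- function(x) {
  if (inherits(x, "landscape")) return(x)
  if (inherits(x, "synth_config")) return(generate_landscape(x))
  if (is.character(x)) return(read_landscape(x))
  stop("landscape must be a landscape, a synth_config, or a directory path")
}

#' Run the full prioritization pipeline
#'
#' Executes, for each requested scenario: landscape (resolve or generate),
#' planning-unit tessellation, feature amounts, environmental-risk surface
#' and PU costs, scenario lock rules, conservation targets (seeded with the
#' already-protected amounts), replicate annealing, summed solution, priority
#' areas and the achievement report — plus the richness analysis, overlap
#' tables and ecosystem coverage shared by all scenarios. Identical
#' config and seed reproduce identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir optional run directory; when given, tables (CSV), rasters
#'   (`.asc`) and a JSON manifest with every parameter and seed are written
#'   under it.
#' @return object of class `reserve_run`: list with `landscape`, `pus`,
#'   `ers`, `features`, `richness`, `overlap` (table1/table2/ecosystems) and
#'   per-scenario entries `scenarios[[s]]` holding `pus` (locked), `targets`,
#'   `summed`, `priority` (PU logical), `achievement`,
#'   `pct_southern_in_priority`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  land <- resolve_landscape(config$landscape)
  pus <- tessellate(land, config$pu_area)
  fm <- build_feature_matrix(land, pus, config$binarize_threshold)

  fps <- lapply(names(config$threat_specs), function(nm) {
    if (is.null(land$threat_layers[[nm]]))
      matrix(0, land$grid$n_rows, land$grid$n_cols)
    else threat_footprint(land$threat_layers[[nm]], config$threat_specs[[nm]],
                          land$grid, land$study_mask)
  })
  names(fps) <- names(config$threat_specs)
  fps <- lapply(fps, function(f) { f[is.na(f)] <- 0; f })
  ers <- compose_ers(fps, config$threat_specs, config$ers_threshold)
  pus <- pu_cost(ers, pus)
  impact <- high_impact_mask(ers)

  rich <- richness_analysis(land, config$binarize_threshold)
  overlap <- list(table1 = table1(land), table2 = table2(land),
                  ecosystems = ecosystem_coverage(land))

  south <- zone_mask(land$southern_blocks)
  scen <- list()
  for (s in config$scenarios) {
    ps <- apply_lock_rules(pus, land, s, impact)
    fms <- refresh_protected_amounts(fm, ps)
    targets <- build_target_table(fms, config$scheme)
    problem <- selection_problem(ps, fms, targets, spf = config$spf,
                                 blm = config$blm)
    ss <- summed_solution(problem, n_reps = config$n_reps,
                          base_seed = config$seed + 1000 * s,
                          n_iter = config$n_iter, restarts = config$restarts,
                          priority_threshold = config$priority_threshold)
    prio <- priority_areas(ss)
    # headline achievement follows the best replicate (the network the
    # scenario proposes); the summed-solution priority areas additionally
    # get their own report, as their dispersion can leave marginal targets
    # below the selection-frequency cut
    ach <- achievement_report(ss$best$selected, fms, targets)
    ach_priority <- achievement_report(
      prio | (ps$pu$status == "locked_in"), fms, targets)
    prio_cells <- pu_mask_to_cells(prio, ps)
    pct_south <- if (any(south))
      percent_cover(area_of(prio_cells & south, land$grid$cell_area),
                    area_of(south, land$grid$cell_area), digits = 1)
      else NA_real_
    scen[[as.character(s)]] <- list(
      scenario = s, pus = ps, targets = targets, summed = ss,
      priority = prio, achievement = ach,
      achievement_priority = ach_priority,
      pct_southern_in_priority = pct_south)
  }
  run <- structure(
    list(config = config, landscape = land, pus = pus, ers = ers,
         features = fm, richness = rich, overlap = overlap,
         scenarios = scen),
    class = "reserve_run")
  if (!is.null(out_dir)) write_run_outputs(run, out_dir)
  run
}

#' @export
print.reserve_run <- function(x, ...) {
  cat(sprintf("<reserve_run> %d PUs, %d features, scenarios: %s\n",
              nrow(x$pus$pu), nrow(x$features$features),
              paste(names(x$scenarios), collapse = ", ")))
  for (s in x$scenarios) {
    cat(sprintf("  scenario %d: %d priority PUs, %.1f%% of targets met\n",
                s$scenario, sum(s$priority),
                s$achievement$summary[["pct_all_met"]]))
  }
  invisible(x)
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  land <- run$landscape
  g <- land$grid
  utils::write.csv(run$overlap$table1, file.path(out_dir, "table1.csv"),
                   row.names = FALSE)
  utils::write.csv(run$overlap$table2, file.path(out_dir, "table2.csv"),
                   row.names = FALSE)
  utils::write.csv(run$overlap$ecosystems$table,
                   file.path(out_dir, "ecosystem_coverage.csv"),
                   row.names = FALSE)
  utils::write.csv(run$richness$summary,
                   file.path(out_dir, "richness_summary.csv"),
                   row.names = FALSE)
  write_asc(run$ers$values, g, file.path(out_dir, "ers.asc"))
  write_problem_tables(run$pus, run$features, out_dir)
  for (s in run$scenarios) {
    sd <- file.path(out_dir, sprintf("scenario_%d", s$scenario))
    dir.create(sd, showWarnings = FALSE)
    utils::write.csv(data.frame(pu_id = seq_along(s$summed$frequency),
                                frequency = s$summed$frequency),
                     file.path(sd, "ssoln.csv"), row.names = FALSE)
    utils::write.csv(s$targets, file.path(sd, "targets.csv"),
                     row.names = FALSE)
    utils::write.csv(s$achievement$per_feature,
                     file.path(sd, "achievement.csv"), row.names = FALSE)
    write_asc(pu_mask_to_cells(s$priority, s$pus), g,
              file.path(sd, "priority_mask.asc"))
  }
  cfg <- run$config
  manifest <- list(
    package_version = as.character(utils::packageVersion("reservaplan")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed, pu_area = cfg$pu_area,
    binarize_threshold = cfg$binarize_threshold,
    scheme = unclass(cfg$scheme), ers_threshold = cfg$ers_threshold,
    scenarios = cfg$scenarios, n_reps = cfg$n_reps, n_iter = cfg$n_iter,
    priority_threshold = cfg$priority_threshold, spf = cfg$spf,
    blm = cfg$blm,
    note = paste("spf, n_iter and ERS weights are declared defaults,",
                 "not values estimated from data"),
    threat_specs = lapply(cfg$threat_specs, unclass),
    achievement = lapply(run$scenarios, function(s)
      as.list(s$achievement$summary)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Re-run scenarios with halved conservation targets
#'
#' Repeats the pipeline with the target scheme's scenario factor halved
#' (e.g. 36-4% endpoint targets become 18-2%) and reports, per scenario, the
#' achievement under full and half targets side by side.
#'
#' @param config a [run_config()] (the *full*-target configuration).
#' @param out_dir optional run directory for the half-target run.
#' @return list with `full` and `half` (`reserve_run`s) and `comparison`
#'   data.frame (scenario, pct_all_met_full, pct_all_met_half).
#' @export
rerun_with_half_targets <- function(config, out_dir = NULL) {
  full <- run_pipeline(config)
  cfg_half <- config
  cfg_half$scheme <- halve_targets(config$scheme)
  half <- run_pipeline(cfg_half, out_dir)
  comparison <- data.frame(
    scenario = as.integer(names(full$scenarios)),
    pct_all_met_full = vapply(full$scenarios, function(s)
      s$achievement$summary[["pct_all_met"]], numeric(1)),
    pct_all_met_half = vapply(half$scenarios, function(s)
      s$achievement$summary[["pct_all_met"]], numeric(1)),
    row.names = NULL)
  list(full = full, half = half, comparison = comparison)
}
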