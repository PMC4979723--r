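#' Assemble a minimum-set reserve-selection problem
#'
#' The minimum-set problem selects planning units that meet every feature's
#' conservation target at minimum total cost. Locked-in PUs belong to every
#' solution; locked-out PUs to none (their feature amounts are never
#' selectable). Shortfalls enter the objective normalized by the target
#' (`shortfall / target`) so that small-range features are not drowned out by
#' large ones, scaled by a species penalty factor (SPF) and a documented
#' cost-scale constant: mean available-PU cost times the estimated number of
#' PUs a full solution needs (total target area / mean PU area). With the
#' default SPF of 10, leaving one feature entirely unmet costs roughly ten
#' times a whole plausible solution — shortfalls are only tolerated when
#' targets are genuinely unreachable.
#'
#' @param pus a [tessellate()] result with costs ([pu_cost()]) and lock
#'   states ([apply_lock_rules()]) applied.
#' @param fm a [build_feature_matrix()] result.
#' @param targets a [build_target_table()] result.
#' @param spf species penalty factor: scalar or per-feature vector (> 0).
#' @param blm boundary-length modifier (default 0: no compactness pressure).
#' @return object of class `selection_problem`.
#' @export
selection_problem <- function(pus, fm, targets, spf = 10, blm = 0) {
  stopifnot(all(pus$pu$cost > 0), all(spf > 0),
            identical(rownames(fm$amounts), targets$feature_id))
  n_pu <- nrow(pus$pu)
  n_f <- nrow(targets)
  spf <- rep_len(spf, n_f)
  avail <- pus$pu$status == "available"
  mean_cost <- if (any(avail)) mean(pus$pu$cost[avail]) else mean(pus$pu$cost)
  n_needed <- max(1, sum(targets$target_km2) / mean(pus$pu$area_km2))
  structure(
    list(pus = pus, amounts = fm$amounts, targets = targets,
         spf = spf, blm = blm, cost_scale = mean_cost * n_needed),
    class = "selection_problem"
  )
}

#' @export
print.selection_problem <- function(x, ...) {
  cat(sprintf("<selection_problem> %d PUs (%d available), %d features, spf %g, blm %g\n",
              nrow(x$pus$pu), sum(x$pus$pu$status == "available"),
              nrow(x$targets), x$spf[1], x$blm))
  invisible(x)
}

shortfall_penalty <- function(problem, achieved) {
  tgt <- problem$targets$target_km2
  sf <- pmax(0, tgt - achieved)
  ok <- tgt > 0
  sum(problem$spf[ok] * problem$cost_scale * sf[ok] / tgt[ok])
}

#' Minimum-set objective of a candidate selection
#'
#' Total cost of the selected PUs, plus the normalized-shortfall penalty,
#' plus `blm` times the exterior boundary length of the selected set (shared
#' boundaries between a selected and an unselected PU).
#'
#' @param problem a [selection_problem()].
#' @param selected logical vector over PUs, or integer PU ids.
#' @return the objective score (finite).
#' @export
objective <- function(problem, selected) {
  if (!is.logical(selected)) {
    sel <- rep(FALSE, nrow(problem$pus$pu)); sel[selected] <- TRUE
  } else sel <- selected
  achieved <- if (any(sel))
    rowSums(problem$amounts[, sel, drop = FALSE]) else
    numeric(nrow(problem$targets))
  score <- sum(problem$pus$pu$cost[sel]) + shortfall_penalty(problem, achieved)
  if (problem$blm != 0) {
    adj <- problem$pus$adjacency
    ext <- xor(sel[adj$id1], sel[adj$id2])
    score <- score + problem$blm * sum(adj$boundary_km[ext])
  }
  score
}

problem_csc <- function(problem) {
  am <- problem$amounts
  nz <- which(am > 0, arr.ind = TRUE)
  ord <- order(nz[, 2], nz[, 1])
  nz <- nz[ord, , drop = FALSE]
  n_pu <- ncol(am)
  counts <- tabulate(nz[, 2], nbins = n_pu)
  list(pu_ptr = as.integer(c(0, cumsum(counts))),
       feat = as.integer(nz[, 1] - 1L),
       amt = am[nz])
}

adjacency_csr <- function(pus) {
  adj <- pus$adjacency
  n <- nrow(pus$pu)
  if (nrow(adj) == 0) {
    return(list(ptr = integer(n + 1), to = integer(0), len = numeric(0)))
  }
  from <- c(adj$id1, adj$id2); to <- c(adj$id2, adj$id1)
  len <- c(adj$boundary_km, adj$boundary_km)
  ord <- order(from, to)
  from <- from[ord]; to <- to[ord]; len <- len[ord]
  list(ptr = as.integer(c(0, cumsum(tabulate(from, nbins = n)))),
       to = as.integer(to - 1L), len = len)
}

#' Solve a selection problem by simulated annealing
#'
#' One annealing run: starting from a seeded random subset of the available
#' PUs, single-PU add/remove proposals are accepted when improving and with
#' probability `exp(-delta / T)` when worsening, under geometric cooling from
#' an initial temperature set by sampling move deltas; a final greedy pass
#' drops every PU whose removal still lowers the objective. Locked PUs are
#' never touched. Deterministic for a fixed seed. If the targets are
#' unreachable even selecting everything available, the solution is returned
#' with the unmet features flagged rather than erroring.
#'
#' @param problem a [selection_problem()].
#' @param n_iter number of proposals (default 1e5; production-size runs of
#'   the original analyses use ~1e6, configurable down for small problems).
#' @param seed integer seed for this run.
#' @param init_prob inclusion probability of each available PU in the random
#'   start (default 0.5).
#' @param restarts best-of-k restarts within the run (default 4): the
#'   annealing chain is restarted from fresh seeded states and the
#'   lowest-objective end state is kept, a cheap guard against the
#'   penalty-induced local minima of minimum-set landscapes.
#' @param met_tol relative tolerance on "met".
#' @return object of class `reserve_solution`: list with `selected` (logical),
#'   `objective`, `achieved` (per-feature km^2), `met` (per-feature logical),
#'   `seed`.
#' @export
anneal <- function(problem, n_iter = 1e5, seed = 1, init_prob = 0.5,
                   restarts = 4, met_tol = 1e-9) {
  status <- match(problem$pus$pu$status,
                  c("available", "locked_in", "locked_out")) - 1L
  csc <- problem_csc(problem)
  adj <- adjacency_csr(problem$pus)
  res <- NULL
  for (r in seq_len(restarts)) {
    sub_seed <- (seed + 104729 * (r - 1)) %% 2147483647
    cand <- .anneal_cpp(problem$pus$pu$cost, status, csc$pu_ptr, csc$feat,
                        csc$amt, problem$targets$target_km2, problem$spf,
                        problem$cost_scale, problem$blm, adj$ptr, adj$to,
                        adj$len, as.integer(n_iter), as.integer(sub_seed),
                        init_prob)
    if (is.null(res) || cand$objective < res$objective) res <- cand
  }
  sel <- res$selected
  achieved <- as.numeric(res$achieved)
  structure(
    list(selected = sel, objective = objective(problem, sel),
         achieved = achieved,
         met = achieved >= problem$targets$target_km2 * (1 - met_tol),
         seed = seed),
    class = "reserve_solution"
  )
}

#' @export
print.reserve_solution <- function(x, ...) {
  cat(sprintf("<reserve_solution> %d PUs selected, objective %.4g, %d/%d targets met\n",
              sum(x$selected), x$objective, sum(x$met), length(x$met)))
  invisible(x)
}

#' Exact optimum by exhaustive enumeration (oracle for small instances)
#'
#' Enumerates every lock-respecting subset of the available PUs (at most 20)
#' and returns the minimizer of [objective()]. Ties are broken by the subset
#' whose inclusion vector over the available PUs, read in PU order, is
#' lexicographically smallest. Kept in plain R, independent of the annealer's
#' compiled path, so the two can check each other.
#'
#' @param problem a [selection_problem()].
#' @param met_tol relative tolerance on "met".
#' @return a `reserve_solution`.
#' @export
brute_force_optimum <- function(problem, met_tol = 1e-9) {
  status <- problem$pus$pu$status
  avail <- which(status == "available")
  n <- length(avail)
  if (n > 20) stop("brute force limited to 20 available PUs; got ", n)
  base <- status == "locked_in"
  if (n == 0) {
    best_obj <- objective(problem, base)
    best_sel <- base
  } else {
    # row order of expand.grid with reversed columns is lexicographic over
    # (PU1, PU2, ...), FALSE < TRUE, so which.min realizes the tie-break
    combos <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))[,
      n:1, drop = FALSE]
    cost <- problem$pus$pu$cost
    cost_all <- sum(cost[base]) + as.vector(combos %*% cost[avail])
    base_ach <- if (any(base))
      rowSums(problem$amounts[, base, drop = FALSE]) else
      numeric(nrow(problem$targets))
    ach_all <- base_ach +
      problem$amounts[, avail, drop = FALSE] %*% t(combos)
    tgt <- problem$targets$target_km2
    ok <- tgt > 0
    pen_all <- colSums(
      (problem$spf[ok] * problem$cost_scale / tgt[ok]) *
        pmax(tgt[ok] - ach_all[ok, , drop = FALSE], 0))
    obj_all <- cost_all + pen_all
    if (problem$blm != 0) {
      adj <- problem$pus$adjacency
      selm <- matrix(base, nrow(combos), length(base), byrow = TRUE)
      selm[, avail] <- combos
      for (r in seq_len(nrow(adj))) {
        ext <- xor(selm[, adj$id1[r]], selm[, adj$id2[r]])
        obj_all <- obj_all + problem$blm * adj$boundary_km[r] * ext
      }
    }
    r <- which.min(obj_all)
    best_obj <- obj_all[r]
    best_sel <- base
    best_sel[avail] <- combos[r, ]
  }
  achieved <- if (any(best_sel))
    rowSums(problem$amounts[, best_sel, drop = FALSE]) else
    numeric(nrow(problem$targets))
  structure(
    list(selected = best_sel, objective = best_obj, achieved = achieved,
         met = achieved >= problem$targets$target_km2 * (1 - met_tol),
         seed = NA_integer_),
    class = "reserve_solution"
  )
}

#' Summed solution: selection frequency over replicate runs
#'
#' Runs the annealer `n_reps` times with seeds `base_seed + 1 .. base_seed +
#' n_reps` and counts how often each PU is selected. The selection frequency
#' is a proxy for a PU's irreplaceability in building an efficient network.
#'
#' @param problem a [selection_problem()].
#' @param n_reps number of replicates (default 100).
#' @param base_seed integer; replicate k uses seed `base_seed + k`.
#' @param priority_threshold frequency at or above which a PU is a priority
#'   area (default 75 of 100).
#' @inheritParams anneal
#' @return object of class `summed_solution`: list with `frequency`
#'   (integer per PU), `n_reps`, `priority_threshold`, `objectives`,
#'   `pct_met` (per-replicate percent of targets met), and `best` (the
#'   lowest-objective replicate's `reserve_solution`).
#' @export
summed_solution <- function(problem, n_reps = 100, base_seed = 0,
                            n_iter = 1e5, init_prob = 0.5, restarts = 4,
                            priority_threshold = 75) {
  freq <- integer(nrow(problem$pus$pu))
  objs <- numeric(n_reps); pct <- numeric(n_reps)
  best <- NULL
  for (k in seq_len(n_reps)) {
    sol <- anneal(problem, n_iter = n_iter, seed = base_seed + k,
                  init_prob = init_prob, restarts = restarts)
    freq <- freq + sol$selected
    objs[k] <- sol$objective
    pct[k] <- 100 * mean(sol$met)
    if (is.null(best) || sol$objective < best$objective) best <- sol
  }
  structure(
    list(frequency = freq, n_reps = n_reps,
         priority_threshold = priority_threshold,
         objectives = objs, pct_met = pct, best = best),
    class = "summed_solution"
  )
}

#' @export
print.summed_solution <- function(x, ...) {
  cat(sprintf("<summed_solution> %d replicates; %d PUs at frequency >= %g\n",
              x$n_reps, sum(x$frequency >= x$priority_threshold),
              x$priority_threshold))
  invisible(x)
}

#' Priority areas from a summed solution
#'
#' PUs selected in at least `threshold` of the replicates (inclusive: a PU at
#' exactly the threshold is a priority area).
#'
#' @param ss a [summed_solution()].
#' @param threshold selection-frequency cut (default: the summed solution's
#'   own, 75 of 100 replicates).
#' @return logical vector over PUs.
#' @export
priority_areas <- function(ss, threshold = ss$priority_threshold) {
  ss$frequency >= threshold
}

#' Cell-level mask of a planning-unit selection
#'
#' @param pu_sel logical vector over PUs.
#' @param pus the [tessellate()] result.
#' @return logical matrix over cells (FALSE outside the mask).
#' @export
pu_mask_to_cells <- function(pu_sel, pus) {
  m <- matrix(FALSE, nrow(pus$pu_raster), ncol(pus$pu_raster))
  idx <- !is.na(pus$pu_raster)
  m[idx] <- pu_sel[pus$pu_raster[idx]]
  m
}
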