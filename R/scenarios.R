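#' One management/climate scenario
#'
#' A scenario is one cell of the fishing x bleaching x water-quality
#' factorial (Table-3-style levels).
#'
#' @param fishing_level `"none"`, `"moderate"` (50% of current yield) or
#'   `"high"` (current yield).
#' @param bleaching_level `"none"`, `"once-per-decade"` or
#'   `"twice-per-decade"`.
#' @param water_quality `"regulated"` (no impact) or `"unregulated"`
#'   (nutrification and sedimentation present).
#' @param label optional scenario label; a default is composed from the
#'   levels.
#' @return A list of class `"reef_scenario"`.
#' @export
reef_scenario <- function(fishing_level = c("none", "moderate", "high"),
                          bleaching_level = c("none", "once-per-decade",
                                              "twice-per-decade"),
                          water_quality = c("regulated", "unregulated"),
                          label = NULL) {
  fishing_level <- match.arg(fishing_level)
  bleaching_level <- match.arg(bleaching_level)
  water_quality <- match.arg(water_quality)
  if (is.null(label))
    label <- paste(paste0("F:", fishing_level),
                   paste0("B:", bleaching_level),
                   paste0("WQ:", water_quality), sep = "|")
  structure(list(fishing_level = fishing_level,
                 bleaching_level = bleaching_level,
                 water_quality = water_quality, label = label),
            class = "reef_scenario")
}

#' Coerce to a scenario
#'
#' Accepts a `reef_scenario`, or a one-row data frame / list with elements
#' `fishing_level`, `bleaching_level`, `water_quality` (e.g. one row of
#' [scenario_grid()]).
#'
#' @param x object to coerce.
#' @return A `reef_scenario`.
#' @export
as_scenario <- function(x) {
  if (inherits(x, "reef_scenario")) return(x)
  if (is.data.frame(x)) {
    if (nrow(x) != 1) stop("need exactly one scenario row")
    x <- as.list(x)
  }
  reef_scenario(fishing_level = as.character(x$fishing_level),
                bleaching_level = as.character(x$bleaching_level),
                water_quality = as.character(x$water_quality),
                label = if (!is.null(x$label)) as.character(x$label))
}

#' Full factorial scenario grid
#'
#' All combinations of the supplied levels in a stable, deterministic order
#' (water quality varying slowest, fishing fastest). The default levels give
#' the 18-scenario grid: 3 fishing x 3 bleaching x 2 water-quality levels.
#'
#' @param fishing_levels,bleaching_levels,water_levels character vectors of
#'   levels (non-empty, no duplicates).
#' @return A data frame with one row per scenario and columns
#'   `scenario` (index), `label`, `fishing_level`, `bleaching_level`,
#'   `water_quality`.
#' @examples
#' nrow(scenario_grid())  # 18
#' @export
scenario_grid <- function(fishing_levels = c("none", "moderate", "high"),
                          bleaching_levels = c("none", "once-per-decade",
                                               "twice-per-decade"),
                          water_levels = c("regulated", "unregulated")) {
  for (lv in list(fishing_levels, bleaching_levels, water_levels)) {
    if (length(lv) == 0) stop("level lists must be non-empty")
    if (anyDuplicated(lv)) stop("duplicate levels are not allowed")
  }
  g <- expand.grid(fishing_level = fishing_levels,
                   bleaching_level = bleaching_levels,
                   water_quality = water_levels,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$label <- paste(paste0("F:", g$fishing_level),
                   paste0("B:", g$bleaching_level),
                   paste0("WQ:", g$water_quality), sep = "|")
  data.frame(scenario = seq_len(nrow(g)), g[, c("label", "fishing_level",
                                                "bleaching_level",
                                                "water_quality")],
             stringsAsFactors = FALSE)
}

#' Deterministic child seed for one replicate
#'
#' Pure function of (master seed, scenario index, replicate index), so any
#' single replicate can be reproduced without rerunning the grid. The primes
#' keep distinct replicates/scenarios on distinct seeds and the arithmetic
#' stays exact in double precision; the result is a valid 32-bit seed.
#'
#' @param master_seed integer master seed.
#' @param scenario_index integer scenario index (>= 1).
#' @param replicate integer replicate index (>= 1).
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(master_seed, scenario_index, replicate) {
  s <- (as.double(master_seed) %% 2147483647 +
          15485863 * as.double(scenario_index) +
          104729 * as.double(replicate)) %% 2147483647
  as.integer(s) + 1L
}

#' Run a Monte-Carlo ensemble for one scenario at one site
#'
#' Runs `n_replicates` simulations of one scenario at one site archetype.
#' Replicate `i` draws its own forcing set from the deterministic child seed
#' [child_seed()]`(master_seed, scenario_index, i)`, so reruns with the same
#' master seed are bit-identical.
#'
#' @param scenario a [reef_scenario()] or one row of [scenario_grid()].
#' @param site a [make_site()] archetype (or any list with `initial`,
#'   `params`, `label`).
#' @param n_replicates number of replicate runs (default 20).
#' @param master_seed integer master seed.
#' @param horizon_years simulation horizon (default 40).
#' @param scenario_index index of the scenario within its grid (used in the
#'   child-seed derivation; default 1).
#' @param fixed_bleaching optional fixed bleaching schedule passed to
#'   [draw_forcings()] (overrides the scenario's stochastic regime).
#' @return An object of class `"reef_ensemble"`: list with `scenario`,
#'   `site_label`, `urchins_present`, `trajectories` (list of
#'   `reef_trajectory`), `seeds`, `forcings` (realised per replicate),
#'   `horizon_years`.
#' @export
run_ensemble <- function(scenario, site, n_replicates = 20, master_seed = 1,
                         horizon_years = 40, scenario_index = 1,
                         fixed_bleaching = NULL) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  scenario <- as_scenario(scenario)
  seeds <- vapply(seq_len(n_replicates), function(i)
    child_seed(master_seed, scenario_index, i), integer(1))
  trajs <- vector("list", n_replicates)
  fsets <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    fs <- draw_forcings(scenario, seeds[i], horizon_years = horizon_years,
                        fixed_bleaching = fixed_bleaching)
    fsets[[i]] <- fs
    trajs[[i]] <- reef_simulate(site$initial, site$params, fs,
                                horizon_years = horizon_years,
                                seed = seeds[i])
  }
  structure(list(scenario = scenario, site_label = site$label,
                 urchins_present = site$params$urchins_present,
                 trajectories = trajs, seeds = seeds, forcings = fsets,
                 horizon_years = horizon_years),
            class = "reef_ensemble")
}

#' @export
print.reef_ensemble <- function(x, ...) {
  cat(sprintf("Reef ensemble: %s at %s\n  %d replicates x %d years\n",
              x$scenario$label, x$site_label, length(x$trajectories),
              x$horizon_years))
  invisible(x)
}

#' Ensemble-mean trajectory
#'
#' Element-wise mean of the replicate state matrices (a daily mean
#' trajectory, as plotted in ensemble trajectory figures).
#'
#' @param ensemble a `reef_ensemble`.
#' @return Matrix (days + 1) x 7 of mean states.
#' @export
ensemble_mean_trajectory <- function(ensemble) {
  acc <- ensemble$trajectories[[1]]$states
  n <- length(ensemble$trajectories)
  if (n > 1)
    for (i in 2:n) acc <- acc + ensemble$trajectories[[i]]$states
  acc / n
}

#' Audit table of realised forcings
#'
#' One row per replicate: seed, realised water-quality scalars, fishing
#' total, and the bleaching schedule (as `year:severity` pairs).
#'
#' @param ensemble a `reef_ensemble`.
#' @return A data frame.
#' @export
forcing_audit <- function(ensemble) {
  rows <- lapply(seq_along(ensemble$forcings), function(i) {
    fs <- ensemble$forcings[[i]]
    sched <- if (length(fs$bleaching_schedule))
      paste(vapply(fs$bleaching_schedule,
                   function(e) sprintf("%g:%.4f", e$year, e$severity),
                   character(1)), collapse = ";") else ""
    data.frame(replicate = i, seed = ensemble$seeds[i],
               turf_growth_scale = if (fs$water_quality_active)
                 fs$nutrients$turf_growth_scale else NA_real_,
               macroalgae_growth_scale = if (fs$water_quality_active)
                 fs$nutrients$macroalgae_growth_scale else NA_real_,
               coral_growth_reduction = if (fs$water_quality_active)
                 fs$sediments$coral_growth_reduction else NA_real_,
               coral_recruit_reduction = if (fs$water_quality_active)
                 fs$sediments$coral_recruit_reduction else NA_real_,
               coral_mortality_increase = if (fs$water_quality_active)
                 fs$sediments$coral_mortality_increase else NA_real_,
               fishing_total = fs$realised_fishing_total,
               bleaching_schedule = sched,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Snapshot community matrix
#'
#' Extracts the modelled reef state of every replicate of every ensemble at
#' one snapshot year, as the runs x variables matrix on which all
#' multivariate analysis operates. Benthic covers are reported in percent,
#' consumer biomasses in g m-2; the urchin column is omitted for sites
#' without urchins. Scenario factor labels are carried as grouping columns.
#'
#' @param ensembles a `reef_ensemble` or list of them (same site).
#' @param year snapshot year (0 = start; year `y` is day `y * 365`).
#' @return A data frame of class `"community_matrix"` with grouping columns
#'   `scenario`, `fishing`, `bleaching`, `water`, `replicate` and the state
#'   variable columns; attributes `site`, `year`, `variables`,
#'   `normalised = FALSE`.
#' @export
snapshot_matrix <- function(ensembles, year) {
  if (inherits(ensembles, "reef_ensemble")) ensembles <- list(ensembles)
  sites <- unique(vapply(ensembles, `[[`, character(1), "site_label"))
  if (length(sites) != 1)
    stop("all ensembles must come from the same site (got: ",
         paste(sites, collapse = ", "), ")")
  urch <- unique(vapply(ensembles, `[[`, logical(1), "urchins_present"))
  vars <- c("coral", "eac", "macroturf", "macroalgae", "herbivore",
            "piscivore", if (urch) "urchin")
  rows <- lapply(ensembles, function(en) {
    if (year > en$horizon_years)
      stop("snapshot year beyond ensemble horizon")
    st <- t(vapply(en$trajectories, function(tr)
      trajectory_at_years(tr, year)[1, ], numeric(7)))
    st <- st[, vars, drop = FALSE]
    st[, 1:4] <- st[, 1:4] * 100   # covers in percent
    data.frame(scenario = en$scenario$label,
               fishing = en$scenario$fishing_level,
               bleaching = en$scenario$bleaching_level,
               water = en$scenario$water_quality,
               replicate = seq_len(nrow(st)), st,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "site") <- sites
  attr(out, "year") <- year
  attr(out, "variables") <- vars
  attr(out, "normalised") <- FALSE
  class(out) <- c("community_matrix", "data.frame")
  out
}

#' Variable columns of a community matrix
#'
#' @param cm a `community_matrix`.
#' @return Numeric matrix of the state-variable columns.
#' @export
community_vars <- function(cm) {
  as.matrix(cm[, attr(cm, "variables"), drop = FALSE])
}
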