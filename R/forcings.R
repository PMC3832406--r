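#' Nutrification forcing
#'
#' Nutrient enrichment elevates algal growth: macroturf growth is scaled by
#' a factor in `[1.3, 2]` and macroalgal growth by a factor in `[2, 7]`.
#' The two-element ranges are the admissible draw ranges; a realised forcing
#' carries single values within them.
#'
#' @param turf_growth_scale scaling of macroturf growth, in `[1.3, 2]`.
#' @param macroalgae_growth_scale scaling of macroalgal growth, in `[2, 7]`.
#' @return A list of class `"nutrient_forcing"`.
#' @export
nutrient_forcing <- function(turf_growth_scale = 1.3,
                             macroalgae_growth_scale = 2) {
  if (turf_growth_scale < 1.3 || turf_growth_scale > 2)
    stop("turf_growth_scale must be in [1.3, 2]")
  if (macroalgae_growth_scale < 2 || macroalgae_growth_scale > 7)
    stop("macroalgae_growth_scale must be in [2, 7]")
  structure(list(turf_growth_scale = turf_growth_scale,
                 macroalgae_growth_scale = macroalgae_growth_scale),
            class = "nutrient_forcing")
}

#' Sedimentation forcing
#'
#' Sediment deposition reduces coral growth by a fraction in `[0, 0.3]` and
#' coral recruitment by a fraction in `[0, 0.6]`, increases coral mortality
#' by up to 0.2 yr-1, and prevents recruitment of coral onto macroturf.
#'
#' @param coral_growth_reduction fractional reduction of coral growth,
#'   in `[0, 0.3]`.
#' @param coral_recruit_reduction fractional reduction of coral recruitment,
#'   in `[0, 0.6]`.
#' @param coral_mortality_increase additive increase of coral mortality
#'   (yr-1), in `[0, 0.2]`.
#' @return A list of class `"sediment_forcing"` (with
#'   `block_recruitment_on_macroturf = TRUE`, always active).
#' @export
sediment_forcing <- function(coral_growth_reduction = 0,
                             coral_recruit_reduction = 0,
                             coral_mortality_increase = 0) {
  if (coral_growth_reduction < 0 || coral_growth_reduction > 0.3)
    stop("coral_growth_reduction must be in [0, 0.3]")
  if (coral_recruit_reduction < 0 || coral_recruit_reduction > 0.6)
    stop("coral_recruit_reduction must be in [0, 0.6]")
  if (coral_mortality_increase < 0 || coral_mortality_increase > 0.2)
    stop("coral_mortality_increase must be in [0, 0.2]")
  structure(list(coral_growth_reduction = coral_growth_reduction,
                 coral_recruit_reduction = coral_recruit_reduction,
                 coral_mortality_increase = coral_mortality_increase,
                 block_recruitment_on_macroturf = TRUE),
            class = "sediment_forcing")
}

#' Fishing regime
#'
#' Total extraction in t km-2 yr-1 (1 t km-2 = 1 g m-2), split between
#' herbivorous (68.3%) and piscivorous (31.7%) fish, the observed catch
#' composition on Bolinao-type reefs. The rate is a two-element range for a
#' per-run uniform draw (a degenerate range fixes it).
#'
#' @param total_rate_range numeric length-2 range of total extraction
#'   (t km-2 yr-1), e.g. `c(2.6, 2.8)` for current yield, `c(1.3, 1.4)` for
#'   half the current yield, `c(0, 0)` for no fishing.
#' @param herbivore_share,piscivore_share catch shares; must sum to 1.
#' @return A list of class `"fishing_regime"`.
#' @export
fishing_regime <- function(total_rate_range = c(2.6, 2.8),
                           herbivore_share = 0.683,
                           piscivore_share = 0.317) {
  if (length(total_rate_range) != 2 || any(total_rate_range < 0) ||
      diff(total_rate_range) < 0)
    stop("total_rate_range must be a non-negative increasing length-2 range")
  if (abs(herbivore_share + piscivore_share - 1) > 1e-12)
    stop("herbivore_share and piscivore_share must sum to 1")
  structure(list(total_rate_range = total_rate_range,
                 herbivore_share = herbivore_share,
                 piscivore_share = piscivore_share),
            class = "fishing_regime")
}

#' Bleaching regime
#'
#' Thermal bleaching events remove a fraction of live coral cover
#' instantaneously. In stochastic mode each simulated year is an event with
#' probability `frequency_per_decade / 10`, with per-event severity drawn
#' uniformly from `severity_range`. In fixed mode the supplied schedule is
#' used verbatim (the fixed schedule used for trajectory analysis is events
#' at years 20 and 38 with severities 0.30 and 0.15).
#'
#' @param frequency_per_decade long-term event frequency: 0, 1 or 2 per
#'   decade.
#' @param severity_range fractional coral loss range per event (default
#'   `c(0.1, 0.6)`).
#' @param mode `"stochastic"` or `"fixed"`.
#' @param fixed_schedule for fixed mode, a list of `list(year=, severity=)`
#'   events.
#' @return A list of class `"bleaching_regime"`.
#' @export
bleaching_regime <- function(frequency_per_decade = 0,
                             severity_range = c(0.1, 0.6),
                             mode = c("stochastic", "fixed"),
                             fixed_schedule = list()) {
  mode <- match.arg(mode)
  if (!frequency_per_decade %in% c(0, 1, 2))
    stop("frequency_per_decade must be 0, 1 or 2")
  if (mode == "stochastic" &&
      (any(severity_range < 0.1) || any(severity_range > 0.6)))
    stop("stochastic severities must lie in [0.1, 0.6]")
  structure(list(frequency_per_decade = frequency_per_decade,
                 severity_range = severity_range, mode = mode,
                 fixed_schedule = fixed_schedule),
            class = "bleaching_regime")
}

#' The reference fixed bleaching schedule
#'
#' Events at years 20 and 38 reducing coral cover by 30% and 15%, the
#' schedule used for trajectory and recovery analysis.
#'
#' @return A list of two events suitable for `bleaching_regime(mode="fixed")`.
#' @export
fixed_bleaching_schedule <- function() {
  list(list(year = 20, severity = 0.30),
       list(year = 38, severity = 0.15))
}

#' Apply the water-quality (nutrification + sedimentation) forcing
#'
#' Returns a parameter set with macroturf growth multiplied by
#' `turf_growth_scale`, macroalgal growth (both vegetative spread and coral
#' overgrowth) multiplied by `macroalgae_growth_scale`, coral growth
#' multiplied by `1 - coral_growth_reduction`, coral recruitment (external
#' and endogenous) multiplied by `1 - coral_recruit_reduction`, and coral
#' mortality increased additively by `coral_mortality_increase`. All other
#' parameters are untouched. Recruitment of coral onto macroturf is disabled
#' separately by the simulator whenever the forcing is active.
#'
#' The returned parameter set carries attribute `water_quality_applied`
#' so the forcing cannot be applied twice in one run.
#'
#' @param params a [site_params()].
#' @param nf a [nutrient_forcing()].
#' @param sf a [sediment_forcing()].
#' @return Modified [site_params()].
#' @export
apply_water_quality <- function(params, nf, sf) {
  stopifnot(inherits(nf, "nutrient_forcing"), inherits(sf, "sediment_forcing"))
  if (isTRUE(attr(params, "water_quality_applied")))
    stop("water-quality forcing already applied to this parameter set")
  p <- params
  p$turf_growth <- p$turf_growth * nf$turf_growth_scale
  p$ma_growth <- p$ma_growth * nf$macroalgae_growth_scale
  p$ma_overgrowth <- p$ma_overgrowth * nf$macroalgae_growth_scale
  p$coral_growth <- p$coral_growth * (1 - sf$coral_growth_reduction)
  p$coral_recruit_ext <- p$coral_recruit_ext * (1 - sf$coral_recruit_reduction)
  p$coral_recruit_endo <- p$coral_recruit_endo *
    (1 - sf$coral_recruit_reduction)
  p$coral_mortality <- p$coral_mortality + sf$coral_mortality_increase
  attr(p, "water_quality_applied") <- TRUE
  p
}

#' Schedule bleaching events
#'
#' Stochastic mode: each year `1..horizon_years` is an event with probability
#' `frequency_per_decade / 10` (independent Bernoulli trials, giving the
#' stated long-run frequency); each event's severity is drawn uniformly from
#' the regime's severity range. Fixed mode returns the regime's schedule
#' verbatim. An empty schedule results when the frequency is zero.
#'
#' @param regime a [bleaching_regime()].
#' @param horizon_years non-negative simulation horizon.
#' @param rng_seed integer seed for the draws.
#' @return A list of `list(year=, severity=)` events, ordered by year.
#' @export
schedule_bleaching <- function(regime, horizon_years, rng_seed = NULL) {
  stopifnot(inherits(regime, "bleaching_regime"))
  if (horizon_years < 0) stop("horizon_years must be >= 0")
  if (regime$mode == "fixed") {
    yrs <- vapply(regime$fixed_schedule, `[[`, numeric(1), "year")
    if (length(yrs) && any(yrs > horizon_years))
      stop("fixed schedule contains an event beyond the horizon")
    return(regime$fixed_schedule[order(yrs)])
  }
  if (regime$frequency_per_decade == 0 || horizon_years < 1) return(list())
  if (!is.null(rng_seed)) set.seed(rng_seed)
  p_year <- regime$frequency_per_decade / 10
  hit <- runif(horizon_years) < p_year
  yrs <- which(hit)
  sev <- runif(length(yrs), regime$severity_range[1], regime$severity_range[2])
  mapply(function(y, s) list(year = y, severity = s), yrs, sev,
         SIMPLIFY = FALSE)
}

#' Apply one bleaching event to a reef state
#'
#' Coral cover is multiplied by `1 - severity`; the lost cover becomes EAC
#' (dead coral skeleton colonised by fine turf), so total benthic cover is
#' conserved exactly. All other state variables are untouched.
#'
#' @param state a [reef_state()].
#' @param severity fractional coral loss in `[0, 1]`.
#' @return The bleached [reef_state()].
#' @export
apply_bleaching_event <- function(state, severity) {
  if (severity < 0 || severity > 1) stop("severity must be in [0, 1]")
  loss <- state[["coral"]] * severity
  out <- state
  out[["coral"]] <- state[["coral"]] - loss
  out[["eac"]] <- state[["eac"]] + loss
  out
}

#' Per-group fishing extraction rates
#'
#' Splits a realised total catch rate between herbivorous (68.3%) and
#' piscivorous (31.7%) fish. With the unit identity 1 t km-2 = 1 g m-2, the
#' annual rates are directly in g m-2 yr-1; daily removals are the annual
#' rates divided by 365.
#'
#' @param regime a [fishing_regime()].
#' @param realised_total realised total rate (t km-2 yr-1), within the
#'   regime's range.
#' @return A list with `annual` (named vector, g m-2 yr-1) and `daily`
#'   (named vector, g m-2 day-1).
#' @export
extraction_rates <- function(regime, realised_total) {
  stopifnot(inherits(regime, "fishing_regime"))
  if (realised_total < 0) stop("extraction rate must be >= 0")
  if (realised_total < regime$total_rate_range[1] - 1e-12 ||
      realised_total > regime$total_rate_range[2] + 1e-12)
    stop("realised_total outside the regime's range")
  annual <- c(herbivore = regime$herbivore_share * realised_total,
              piscivore = regime$piscivore_share * realised_total)
  list(annual = annual, daily = annual / 365)
}

#' Construct a realised forcing set
#'
#' Low-level constructor; most users will call [draw_forcings()] on a
#' scenario instead. Nutrification and sedimentation are jointly present or
#' absent: they represent the single water-quality stressor (both originate
#' from aquaculture).
#'
#' @param nutrients a [nutrient_forcing()] or `NULL`.
#' @param sediments a [sediment_forcing()] or `NULL` (must be given together
#'   with `nutrients`).
#' @param fishing a [fishing_regime()].
#' @param realised_fishing_total realised total extraction (t km-2 yr-1).
#' @param bleaching_schedule list of `list(year=, severity=)` events.
#' @param seed the seed the draws were made from (recorded for audit).
#' @return A list of class `"forcing_set"`.
#' @export
forcing_set <- function(nutrients = NULL, sediments = NULL,
                        fishing = fishing_regime(c(0, 0)),
                        realised_fishing_total = 0,
                        bleaching_schedule = list(), seed = NULL) {
  if (xor(is.null(nutrients), is.null(sediments)))
    stop("nutrification and sedimentation must be jointly present or absent")
  ex <- extraction_rates(fishing, realised_fishing_total)
  structure(list(water_quality_active = !is.null(nutrients),
                 nutrients = nutrients, sediments = sediments,
                 fishing = fishing,
                 realised_fishing_total = realised_fishing_total,
                 extraction = ex$annual,
                 bleaching_schedule = bleaching_schedule,
                 seed = seed),
            class = "forcing_set")
}

#' @export
print.forcing_set <- function(x, ...) {
  cat("Realised forcing set\n")
  if (x$water_quality_active) {
    cat(sprintf("  water quality: poor (turf x%.3f, macroalgae x%.3f, coral growth -%.1f%%, recruitment -%.1f%%, mortality +%.3f yr-1)\n",
                x$nutrients$turf_growth_scale,
                x$nutrients$macroalgae_growth_scale,
                100 * x$sediments$coral_growth_reduction,
                100 * x$sediments$coral_recruit_reduction,
                x$sediments$coral_mortality_increase))
  } else cat("  water quality: regulated (no impact)\n")
  cat(sprintf("  fishing: %.3f t km-2 yr-1 (herbivore %.4f, piscivore %.4f g m-2 yr-1)\n",
              x$realised_fishing_total, x$extraction[["herbivore"]],
              x$extraction[["piscivore"]]))
  if (length(x$bleaching_schedule)) {
    ev <- vapply(x$bleaching_schedule,
                 function(e) sprintf("year %g: -%.0f%%", e$year,
                                     100 * e$severity), character(1))
    cat("  bleaching:", paste(ev, collapse = "; "), "\n")
  } else cat("  bleaching: none\n")
  invisible(x)
}

## scenario level -> regime mappings (Table-3-style levels)
fishing_range_for_level <- function(level) {
  switch(level,
         none = c(0, 0),
         moderate = c(1.3, 1.4),
         high = c(2.6, 2.8),
         stop("unknown fishing level: ", level))
}

bleaching_freq_for_level <- function(level) {
  switch(level,
         none = 0,
         `once-per-decade` = 1,
         `twice-per-decade` = 2,
         stop("unknown bleaching level: ", level))
}

#' Draw a realised forcing set for one replicate run
#'
#' Each ranged quantity is drawn uniformly once per replicate: the total
#' fishing rate from its level's range; when water quality is unregulated,
#' the two nutrification growth scalings and the three sedimentation effects
#' from their ranges; and (stochastic bleaching) the event years and
#' per-event severities. Under regulated water quality no nutrient or
#' sediment scalars are present. Draws are reproducible from `rng_seed`.
#'
#' @param scenario a [reef_scenario()] (one row of [scenario_grid()] works
#'   via [as_scenario()]).
#' @param rng_seed integer seed for this replicate's draws.
#' @param horizon_years horizon used to realise the bleaching schedule.
#' @param fixed_bleaching optional fixed schedule (list of
#'   `list(year=, severity=)`) overriding the scenario's stochastic
#'   bleaching regime, as in the trajectory analysis.
#' @return A [forcing_set()].
#' @export
draw_forcings <- function(scenario, rng_seed, horizon_years = 40,
                          fixed_bleaching = NULL) {
  scenario <- as_scenario(scenario)
  set.seed(rng_seed)
  ## draw order is fixed: fishing, water quality, bleaching
  frange <- fishing_range_for_level(scenario$fishing_level)
  freg <- fishing_regime(frange)
  ftot <- if (diff(frange) > 0) runif(1, frange[1], frange[2]) else frange[1]

  nf <- NULL; sf <- NULL
  if (scenario$water_quality == "unregulated") {
    nf <- nutrient_forcing(turf_growth_scale = runif(1, 1.3, 2),
                           macroalgae_growth_scale = runif(1, 2, 7))
    sf <- sediment_forcing(coral_growth_reduction = runif(1, 0, 0.3),
                           coral_recruit_reduction = runif(1, 0, 0.6),
                           coral_mortality_increase = runif(1, 0, 0.2))
  }

  if (!is.null(fixed_bleaching)) {
    breg <- bleaching_regime(mode = "fixed", fixed_schedule = fixed_bleaching)
    sched <- schedule_bleaching(breg, horizon_years)
  } else {
    breg <- bleaching_regime(
      frequency_per_decade =
        bleaching_freq_for_level(scenario$bleaching_level))
    sched <- schedule_bleaching(breg, horizon_years, rng_seed = NULL)
  }

  forcing_set(nutrients = nf, sediments = sf, fishing = freg,
              realised_fishing_total = ftot, bleaching_schedule = sched,
              seed = rng_seed)
}
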