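#' Coral-cover-dependent fish recruitment multiplier
#'
#' Reef fish recruitment depends on the availability of live coral habitat.
#' Recruitment of both fish groups is scaled by a piecewise-linear multiplier
#' of coral cover: it equals `r_min` at zero cover, rises linearly, and
#' saturates at 1 once cover reaches `c_ref`.
#'
#' @param coral_cover proportional coral cover in `[0, 1]`.
#' @param r_min multiplier floor at zero coral cover, in `[0, 1]`.
#' @param c_ref saturation cover in `(0, 1]`: cover at and above which
#'   recruitment is unconstrained.
#' @return Multiplier in `[r_min, 1]`, monotone non-decreasing in
#'   `coral_cover`. Vectorised over `coral_cover`.
#' @examples
#' fish_recruitment_multiplier(0.15, r_min = 0.1, c_ref = 0.3)  # 0.55
#' @export
fish_recruitment_multiplier <- function(coral_cover, r_min = 0.1,
                                        c_ref = 0.3) {
  if (length(c_ref) != 1 || !is.finite(c_ref) || c_ref <= 0)
    stop("c_ref must be a single value > 0 (scaling undefined at 0)")
  if (c_ref > 1) stop("c_ref must be <= 1")
  if (r_min < 0 || r_min > 1) stop("r_min must be in [0, 1]")
  if (any(coral_cover < 0 | coral_cover > 1))
    stop("coral_cover must be in [0, 1]")
  pmin(1, r_min + (1 - r_min) * coral_cover / c_ref)
}

#' One daily update of the reef dynamics
#'
#' Advances the reef state by one time step of `dt` days using the
#' difference-equation dynamics: benthic cover transfers (coral lateral
#' growth and recruitment onto colonisable substrate, coral mortality,
#' macroalgal vegetative growth and overgrowth of coral, turf formation,
#' mass-action grazing) and consumer biomass updates (coral-dependent
#' recruitment, assimilated grazing/predation intake, natural mortality,
#' piscivory, fishing extraction). Annual rates are divided by 365.
#'
#' Benthic transfers are zero-sum: cover lost by one group is gained by
#' another, so the four covers keep summing to one. If the transfers leaving
#' a benthic pool would exceed the pool within the step, all of that pool's
#' outflows are scaled down proportionally so the pool empties but never goes
#' negative. Consumer removals (mortality, predation, extraction) are applied
#' after growth terms and truncated so biomass never goes negative.
#'
#' @param state a [reef_state()].
#' @param params a [site_params()] (possibly already modified by
#'   [apply_water_quality()]).
#' @param extraction_herb,extraction_pisc fishing extraction rates in
#'   g m-2 yr-1 (see [extraction_rates()]); applied as constant daily
#'   removals, capped at the available biomass.
#' @param block_turf_recruitment logical; when `TRUE` (sedimentation active)
#'   coral cannot recruit onto macroturf.
#' @param dt step length in days (default 1).
#' @param validate validate the input state first (default `TRUE`; the
#'   simulator disables this internally after validating the initial state).
#' @return The updated [reef_state()].
#' @export
reef_step <- function(state, params, extraction_herb = 0,
                      extraction_pisc = 0, block_turf_recruitment = FALSE,
                      dt = 1, validate = TRUE) {
  if (validate) {
    validate_reef_state(state)
    validate_site_params(params)
  }
  if (extraction_herb < 0 || extraction_pisc < 0)
    stop("extraction rates must be >= 0")
  p <- params
  dty <- dt / 365

  C <- state[["coral"]]; E <- state[["eac"]]
  Tt <- state[["macroturf"]]; Mm <- state[["macroalgae"]]
  H <- state[["herbivore"]]; P <- state[["piscivore"]]
  U <- if (p$urchins_present) state[["urchin"]] else 0

  phi <- fish_recruitment_multiplier(min(C, 1), p$recruit_floor,
                                     p$recruit_saturation)

  ## benthic fluxes (annual rates x cover terms)
  rec_rate <- p$coral_recruit_ext + p$coral_recruit_endo * C
  f_growth <- p$coral_growth * C * E              # E -> C
  f_rec_e  <- rec_rate * E                        # E -> C
  f_rec_t  <- if (block_turf_recruitment) 0 else rec_rate * Tt  # T -> C
  f_mort   <- p$coral_mortality * C               # C -> E
  f_over   <- p$ma_overgrowth * Mm * C            # C -> M
  f_turf   <- p$turf_growth * E                   # E -> T
  f_ma     <- p$ma_growth * Mm * E                # E -> M
  f_grz_t  <- (p$herb_graze_turf * H + p$urchin_graze_turf * U) * Tt  # T -> E
  f_grz_m  <- (p$herb_graze_ma * H + p$urchin_graze_ma * U) * Mm      # M -> E

  ## per-pool outflow scaling so no cover goes negative within the step
  out_E <- (f_growth + f_rec_e + f_turf + f_ma) * dty
  out_C <- (f_mort + f_over) * dty
  out_T <- (f_rec_t + f_grz_t) * dty
  out_M <- f_grz_m * dty
  sE <- if (out_E > E) E / out_E else 1
  sC <- if (out_C > C) C / out_C else 1
  sT <- if (out_T > Tt) Tt / out_T else 1
  sM <- if (out_M > Mm) Mm / out_M else 1

  C2 <- C - out_C * sC + (f_growth + f_rec_e) * dty * sE + f_rec_t * dty * sT
  E2 <- E - out_E * sE + f_mort * dty * sC + f_grz_t * dty * sT +
    f_grz_m * dty * sM
  T2 <- Tt - out_T * sT + f_turf * dty * sE
  M2 <- Mm - out_M * sM + f_over * dty * sC + f_ma * dty * sE

  ## consumers: growth terms, then truncated removals
  herb_gain <- p$herb_recruit * phi +
    H * (p$herb_assim * (p$herb_graze_eac * E + p$herb_graze_turf * Tt) +
           p$herb_assim_ma * p$herb_graze_ma * Mm)
  herb_loss <- H * p$herb_mortality + p$piscivory * P * H + extraction_herb
  H2 <- max(H + (herb_gain - herb_loss) * dty, 0)

  pisc_gain <- p$pisc_recruit * phi + p$pisc_assim * p$piscivory * P * H
  pisc_loss <- P * p$pisc_mortality + extraction_pisc
  P2 <- max(P + (pisc_gain - pisc_loss) * dty, 0)

  if (p$urchins_present) {
    u_gain <- p$urchin_recruit +
      U * p$urchin_assim * (p$urchin_graze_eac * E +
                              p$urchin_graze_turf * Tt +
                              p$urchin_graze_ma * Mm)
    U2 <- max(U + (u_gain - U * p$urchin_mortality) * dty, 0)
  } else {
    U2 <- 0
  }

  out <- c(coral = C2, eac = E2, macroturf = T2, macroalgae = M2,
           herbivore = H2, piscivore = P2, urchin = U2)
  class(out) <- "reef_state"
  out
}

#' Simulate a reef trajectory
#'
#' Runs the daily reef dynamics over a multi-year horizon under one realised
#' forcing set. Bleaching events in the forcing schedule are applied
#' instantaneously on their event day (day `year * 365`), before that day's
#' update. The dynamics themselves are deterministic: all stochasticity
#' enters through the realised forcing draws ([draw_forcings()]), so
#' identical inputs give bit-identical trajectories.
#'
#' @param initial a [reef_state()].
#' @param params a [site_params()] (unforced; water-quality scalings in
#'   `forcings` are applied internally, exactly once).
#' @param forcings a [forcing_set()]; `NULL` means no stressors.
#' @param horizon_years non-negative number of years to simulate.
#' @param seed optional integer recorded with the trajectory (the dynamics
#'   draw no random numbers; the seed documents the forcing realisation).
#' @return An object of class `"reef_trajectory"`: a list with `states`
#'   (a `(365 * horizon_years + 1) x 7` matrix, row `d + 1` holding the state
#'   at day `d`), `days`, `forcings`, `params` (effective, post-forcing),
#'   and `seed`.
#' @export
reef_simulate <- function(initial, params, forcings = NULL,
                          horizon_years = 40, seed = NULL) {
  if (horizon_years < 0) stop("horizon_years must be >= 0")
  validate_reef_state(initial)
  validate_site_params(params)
  p <- params
  xh <- 0; xp <- 0; block <- FALSE
  events <- matrix(numeric(0), ncol = 2)
  if (!is.null(forcings)) {
    stopifnot(inherits(forcings, "forcing_set"))
    if (forcings$water_quality_active) {
      p <- apply_water_quality(p, forcings$nutrients, forcings$sediments)
      block <- TRUE
    }
    xh <- forcings$extraction[["herbivore"]]
    xp <- forcings$extraction[["piscivore"]]
    if (length(forcings$bleaching_schedule)) {
      events <- do.call(rbind, lapply(forcings$bleaching_schedule,
                                      function(e) c(e$year, e$severity)))
      if (any(events[, 1] > horizon_years))
        stop("bleaching schedule contains an event beyond the horizon")
    }
  }

  n_days <- round(horizon_years * 365)
  states <- matrix(NA_real_, nrow = n_days + 1, ncol = 7,
                   dimnames = list(NULL, c("coral", "eac", "macroturf",
                                           "macroalgae", "herbivore",
                                           "piscivore", "urchin")))
  ## unpack parameters once; the loop body mirrors reef_step() (their
  ## agreement is asserted in the test suite)
  gC <- p$coral_growth; mC <- p$coral_mortality
  rExt <- p$coral_recruit_ext; rEndo <- p$coral_recruit_endo
  gT <- p$turf_growth; gM <- p$ma_growth; oM <- p$ma_overgrowth
  hE <- p$herb_graze_eac; hT <- p$herb_graze_turf; hM <- p$herb_graze_ma
  uE <- p$urchin_graze_eac; uT <- p$urchin_graze_turf; uM <- p$urchin_graze_ma
  eH <- p$herb_assim; eHM <- p$herb_assim_ma; eP <- p$pisc_assim
  eU <- p$urchin_assim
  rH <- p$herb_recruit; rP <- p$pisc_recruit; rU <- p$urchin_recruit
  mH <- p$herb_mortality; mP <- p$pisc_mortality; mU <- p$urchin_mortality
  pr <- p$piscivory
  rmin <- p$recruit_floor; cref <- p$recruit_saturation
  urch <- p$urchins_present
  dty <- 1 / 365

  C <- initial[["coral"]]; E <- initial[["eac"]]
  Tt <- initial[["macroturf"]]; Mm <- initial[["macroalgae"]]
  H <- initial[["herbivore"]]; P <- initial[["piscivore"]]
  U <- if (urch) initial[["urchin"]] else 0

  ev_day <- if (nrow(events)) as.integer(round(events[, 1] * 365)) else integer(0)
  ev_sev <- if (nrow(events)) events[, 2] else numeric(0)

  ## events scheduled at day 0 modify the initial state
  if (length(ev_day)) {
    for (k in which(ev_day == 0L)) {
      loss <- C * ev_sev[k]
      C <- C - loss; E <- E + loss
    }
  }
  states[1, ] <- c(C, E, Tt, Mm, H, P, U)

  d <- 1L
  while (d <= n_days) {
    phi <- rmin + (1 - rmin) * C / cref
    if (phi > 1) phi <- 1

    rec_rate <- rExt + rEndo * C
    f_growth <- gC * C * E
    f_rec_e <- rec_rate * E
    f_rec_t <- if (block) 0 else rec_rate * Tt
    f_mort <- mC * C
    f_over <- oM * Mm * C
    f_turf <- gT * E
    f_ma <- gM * Mm * E
    f_grz_t <- (hT * H + uT * U) * Tt
    f_grz_m <- (hM * H + uM * U) * Mm

    out_E <- (f_growth + f_rec_e + f_turf + f_ma) * dty
    out_C <- (f_mort + f_over) * dty
    out_T <- (f_rec_t + f_grz_t) * dty
    out_M <- f_grz_m * dty
    sE <- if (out_E > E) E / out_E else 1
    sC <- if (out_C > C) C / out_C else 1
    sT <- if (out_T > Tt) Tt / out_T else 1
    sM <- if (out_M > Mm) Mm / out_M else 1

    C2 <- C - out_C * sC + (f_growth + f_rec_e) * dty * sE +
      f_rec_t * dty * sT
    E2 <- E - out_E * sE + f_mort * dty * sC + f_grz_t * dty * sT +
      f_grz_m * dty * sM
    T2 <- Tt - out_T * sT + f_turf * dty * sE
    M2 <- Mm - out_M * sM + f_over * dty * sC + f_ma * dty * sE

    herb_gain <- rH * phi + H * (eH * (hE * E + hT * Tt) + eHM * hM * Mm)
    herb_loss <- H * mH + pr * P * H + xh
    H2 <- H + (herb_gain - herb_loss) * dty
    if (H2 < 0) H2 <- 0

    pisc_gain <- rP * phi + eP * pr * P * H
    pisc_loss <- P * mP + xp
    P2 <- P + (pisc_gain - pisc_loss) * dty
    if (P2 < 0) P2 <- 0

    if (urch) {
      u_gain <- rU + U * eU * (uE * E + uT * Tt + uM * Mm)
      U2 <- U + (u_gain - U * mU) * dty
      if (U2 < 0) U2 <- 0
      U <- U2
    }

    C <- C2; E <- E2; Tt <- T2; Mm <- M2; H <- H2; P <- P2

    ## instantaneous bleaching applied before the update of its event day:
    ## state recorded at day d is post-event
    if (length(ev_day)) {
      for (k in which(ev_day == d)) {
        loss <- C * ev_sev[k]
        C <- C - loss; E <- E + loss
      }
    }
    states[d + 1L, ] <- c(C, E, Tt, Mm, H, P, U)
    d <- d + 1L
  }

  out <- list(states = states, days = 0:n_days, forcings = forcings,
              params = p, seed = seed, horizon_years = horizon_years)
  class(out) <- "reef_trajectory"
  out
}

#' @export
print.reef_trajectory <- function(x, ...) {
  cat(sprintf("Reef trajectory: %d years (%d daily states)\n",
              x$horizon_years, nrow(x$states)))
  fin <- x$states[nrow(x$states), ]
  cat(sprintf("  final coral %.1f%%, macroalgae %.1f%%, herbivores %.2f g m-2\n",
              100 * fin[["coral"]], 100 * fin[["macroalgae"]],
              fin[["herbivore"]]))
  invisible(x)
}

#' Extract states at given years from a trajectory
#'
#' @param traj a `reef_trajectory`.
#' @param years vector of years (0 = start); year `y` maps to day `y * 365`.
#' @return Matrix of states (rows = years).
#' @export
trajectory_at_years <- function(traj, years) {
  idx <- round(years * 365) + 1
  if (any(idx < 1 | idx > nrow(traj$states)))
    stop("requested year(s) outside the simulated horizon")
  out <- traj$states[idx, , drop = FALSE]
  rownames(out) <- as.character(years)
  out
}

#' Write a trajectory as long-format delimited text
#'
#' Columns: `replicate`, `day`, `variable`, `value` (tab-separated).
#'
#' @param traj a `reef_trajectory`.
#' @param path output file.
#' @param replicate replicate label stored in the first column.
#' @param thin write every `thin`-th day (default 1 = all days).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, replicate = 1L, thin = 1L) {
  keep <- seq(1, nrow(traj$states), by = thin)
  st <- traj$states[keep, , drop = FALSE]
  long <- data.frame(
    replicate = replicate,
    day = rep(traj$days[keep], times = ncol(st)),
    variable = rep(colnames(st), each = nrow(st)),
    value = as.vector(st))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
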