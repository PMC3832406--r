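#' Reef community state
#'
#' Construct the seven-variable state of the modelled reef at one time point:
#' four benthic covers that partition the substrate (hard coral, grazed
#' epilithic algal community (EAC), macroturf and macroalgae, as proportions
#' summing to one) and the biomasses of up to three consumer groups
#' (herbivorous fish, piscivorous fish and grazing sea urchins, in g m-2).
#' The EAC compartment doubles as the colonisable free space onto which coral
#' and algae expand.
#'
#' @param coral,eac,macroturf,macroalgae proportional covers in `[0, 1]`;
#'   must sum to one (tolerance `1e-9`).
#' @param herbivore,piscivore,urchin consumer biomasses in g m-2
#'   (1 g m-2 = 1 t km-2). `urchin` is zero (and stays zero) at sites
#'   where urchins are absent.
#' @return A named numeric vector of class `"reef_state"` with elements
#'   `coral`, `eac`, `macroturf`, `macroalgae`, `herbivore`, `piscivore`,
#'   `urchin`.
#' @examples
#' reef_state(coral = 0.3, eac = 0.55, macroturf = 0.1, macroalgae = 0.05,
#'            herbivore = 4, piscivore = 1, urchin = 8)
#' @export
reef_state <- function(coral, eac, macroturf, macroalgae,
                       herbivore = 0, piscivore = 0, urchin = 0) {
  s <- c(coral = coral, eac = eac, macroturf = macroturf,
         macroalgae = macroalgae, herbivore = herbivore,
         piscivore = piscivore, urchin = urchin)
  class(s) <- "reef_state"
  validate_reef_state(s)
  s
}

#' Validate a reef state
#'
#' Checks the state invariants: covers sum to one within `tol`, and every
#' cover and biomass is non-negative.
#'
#' @param state a [reef_state()] (or named numeric vector with the same
#'   elements).
#' @param tol tolerance on the cover sum (default `1e-9`).
#' @return `state`, invisibly, if valid; otherwise an error naming the
#'   violated invariant.
#' @export
validate_reef_state <- function(state, tol = 1e-9) {
  need <- c("coral", "eac", "macroturf", "macroalgae",
            "herbivore", "piscivore", "urchin")
  if (!all(need %in% names(state)))
    stop("reef state is missing elements: ",
         paste(setdiff(need, names(state)), collapse = ", "))
  s <- unclass(state)[need]
  if (any(!is.finite(s)))
    stop("reef state contains non-finite values")
  if (any(s < 0)) {
    bad <- need[s < 0]
    stop("negative state variable(s): ", paste(bad, collapse = ", "))
  }
  cs <- sum(s[1:4])
  if (abs(cs - 1) > tol)
    stop(sprintf("benthic covers sum to %.12f, not 1 (tolerance %g)", cs, tol))
  invisible(state)
}

#' @export
print.reef_state <- function(x, digits = 4, ...) {
  cat("Reef state\n")
  cat("  covers   :",
      paste(sprintf("%s=%.*f", names(x)[1:4], digits, x[1:4]),
            collapse = "  "), "\n")
  cat("  biomass  :",
      paste(sprintf("%s=%.*f", names(x)[5:7], digits, x[5:7]),
            collapse = "  "), "g m-2\n")
  invisible(x)
}

#' Site-level model parameters
#'
#' All intrinsic rates of the reef dynamics, expressed as annual rates; the
#' daily update divides them by 365. Defaults are the package's Bolinao-like
#' reference parameterisation (see the methods vignette for the calibration
#' rationale). Grazing rates are per unit grazer biomass (m2 g-1 yr-1, i.e.
#' cover fraction removed per year per g m-2 of grazer); fish recruitment
#' base rates are absolute fluxes in g m-2 yr-1.
#'
#' @param coral_growth lateral extension of coral onto EAC (yr-1).
#' @param coral_mortality natural coral mortality (yr-1); dead coral becomes
#'   EAC.
#' @param coral_recruit_ext external (larval-supply) coral recruitment onto
#'   colonisable substrate (yr-1).
#' @param coral_recruit_endo endogenous coral recruitment, proportional to
#'   local coral cover (yr-1).
#' @param turf_growth constant growth pressure of fine turf: conversion of
#'   EAC to macroturf (yr-1).
#' @param ma_growth macroalgal vegetative growth onto EAC (yr-1).
#' @param ma_overgrowth macroalgal overgrowth of live coral (yr-1).
#' @param herb_graze_eac,herb_graze_turf,herb_graze_ma herbivorous-fish
#'   grazing rates on EAC, macroturf and macroalgae (m2 g-1 yr-1). Grazing on
#'   EAC maintains it in the cropped state (no cover transfer); grazing on
#'   macroturf and macroalgae returns their cover to EAC.
#' @param urchin_graze_eac,urchin_graze_turf,urchin_graze_ma the same three
#'   rates for sea urchins.
#' @param herb_assim assimilation efficiency of herbivorous fish on EAC and
#'   macroturf intake (dimensionless).
#' @param herb_assim_ma assimilation efficiency on macroalgal intake; low,
#'   reflecting the poor palatability of structurally complex macroalgae.
#' @param pisc_assim piscivore assimilation efficiency on herbivore prey.
#' @param urchin_assim urchin assimilation efficiency.
#' @param herb_recruit,pisc_recruit base recruitment fluxes of herbivorous
#'   and piscivorous fish (g m-2 yr-1), scaled by the coral-cover-dependent
#'   multiplier [fish_recruitment_multiplier()].
#' @param urchin_recruit urchin recruitment flux (g m-2 yr-1), not
#'   coral-dependent.
#' @param herb_mortality,pisc_mortality,urchin_mortality natural mortality
#'   rates (yr-1).
#' @param piscivory mass-action predation rate of piscivores on herbivorous
#'   fish (m2 g-1 yr-1).
#' @param recruit_floor minimum value of the fish recruitment multiplier
#'   (reached at zero coral cover).
#' @param recruit_saturation coral cover at and above which fish recruitment
#'   is unconstrained (multiplier 1).
#' @param urchins_present logical; when `FALSE` urchin biomass is frozen at
#'   zero and urchin terms drop out of the dynamics.
#' @return A list of class `"site_params"`.
#' @export
site_params <- function(coral_growth = 0.15,
                        coral_mortality = 0.10,
                        coral_recruit_ext = 0.003,
                        coral_recruit_endo = 0.05,
                        turf_growth = 0.5,
                        ma_growth = 0.4,
                        ma_overgrowth = 0.8,
                        herb_graze_eac = 0.15,
                        herb_graze_turf = 0.15,
                        herb_graze_ma = 0.12,
                        urchin_graze_eac = 0.08,
                        urchin_graze_turf = 0.10,
                        urchin_graze_ma = 0.03,
                        herb_assim = 2.2,
                        herb_assim_ma = 0.02,
                        pisc_assim = 0.2,
                        urchin_assim = 1.2,
                        herb_recruit = 3.2,
                        pisc_recruit = 1.25,
                        urchin_recruit = 0.7,
                        herb_mortality = 0.6,
                        pisc_mortality = 0.4,
                        urchin_mortality = 0.16,
                        piscivory = 0.02,
                        recruit_floor = 0.1,
                        recruit_saturation = 0.3,
                        urchins_present = TRUE) {
  p <- list(coral_growth = coral_growth,
            coral_mortality = coral_mortality,
            coral_recruit_ext = coral_recruit_ext,
            coral_recruit_endo = coral_recruit_endo,
            turf_growth = turf_growth,
            ma_growth = ma_growth,
            ma_overgrowth = ma_overgrowth,
            herb_graze_eac = herb_graze_eac,
            herb_graze_turf = herb_graze_turf,
            herb_graze_ma = herb_graze_ma,
            urchin_graze_eac = urchin_graze_eac,
            urchin_graze_turf = urchin_graze_turf,
            urchin_graze_ma = urchin_graze_ma,
            herb_assim = herb_assim,
            herb_assim_ma = herb_assim_ma,
            pisc_assim = pisc_assim,
            urchin_assim = urchin_assim,
            herb_recruit = herb_recruit,
            pisc_recruit = pisc_recruit,
            urchin_recruit = urchin_recruit,
            herb_mortality = herb_mortality,
            pisc_mortality = pisc_mortality,
            urchin_mortality = urchin_mortality,
            piscivory = piscivory,
            recruit_floor = recruit_floor,
            recruit_saturation = recruit_saturation,
            urchins_present = isTRUE(urchins_present))
  class(p) <- "site_params"
  validate_site_params(p)
  p
}

#' Validate site parameters
#'
#' @param params a [site_params()] list.
#' @return `params`, invisibly, if valid.
#' @export
validate_site_params <- function(params) {
  rates <- params[setdiff(names(params), "urchins_present")]
  v <- unlist(rates)
  if (any(!is.finite(v))) stop("non-finite parameter value")
  if (any(v < 0)) {
    stop("negative parameter(s): ",
         paste(names(v)[v < 0], collapse = ", "))
  }
  if (params$recruit_floor > 1)
    stop("recruit_floor must be <= 1")
  if (params$recruit_saturation <= 0)
    stop("recruit_saturation must be > 0")
  if (params$recruit_saturation > 1)
    stop("recruit_saturation must be <= 1")
  invisible(params)
}

#' @export
print.site_params <- function(x, ...) {
  cat("Reef site parameters (annual rates)\n")
  cat("  urchins present:", x$urchins_present, "\n")
  nm <- setdiff(names(x), "urchins_present")
  v <- unlist(x[nm])
  for (i in seq_along(v))
    cat(sprintf("  %-20s %g\n", nm[i], v[i]))
  invisible(x)
}

# zero-rate parameter set: every process switched off (fixed-point checks)
zero_params <- function(urchins_present = TRUE) {
  p <- site_params(urchins_present = urchins_present)
  for (nm in setdiff(names(p), c("urchins_present", "recruit_floor",
                                 "recruit_saturation")))
    p[[nm]] <- 0
  p
}
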