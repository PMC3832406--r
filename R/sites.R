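## Archetype default compositions: covers (sum to 1), biomasses in g m-2.
## Plausible Bolinao-like 2008 reconstructions: two less-degraded sites with
## urchins, two degraded macroalgae-dominated sites without urchins.
site_archetype_defaults <- function() {
  list(
    lucero_like = list(
      urchins = TRUE,
      covers = c(coral = 0.30, eac = 0.55, macroturf = 0.10,
                 macroalgae = 0.05),
      biomass = c(herbivore = 4.0, piscivore = 1.0, urchin = 8.0)),
    malilnep_like = list(
      urchins = TRUE,
      covers = c(coral = 0.28, eac = 0.53, macroturf = 0.12,
                 macroalgae = 0.07),
      biomass = c(herbivore = 3.5, piscivore = 0.9, urchin = 6.0)),
    cangaluyan_like = list(
      urchins = FALSE,
      covers = c(coral = 0.12, eac = 0.45, macroturf = 0.18,
                 macroalgae = 0.25),
      biomass = c(herbivore = 1.5, piscivore = 0.4, urchin = 0)),
    tomasa_like = list(
      urchins = FALSE,
      covers = c(coral = 0.03, eac = 0.40, macroturf = 0.22,
                 macroalgae = 0.35),
      biomass = c(herbivore = 0.35, piscivore = 0.10, urchin = 0)))
}

#' Site archetype labels
#'
#' @return Character vector of the four archetype labels.
#' @export
site_archetypes <- function() names(site_archetype_defaults())

#' Generate a synthetic site archetype
#'
#' Produces a site parameterisation + initial state emulating one of four
#' Bolinao-like archetypes: two less-degraded sites with sea urchins
#' (`lucero_like`, coral 30%; `malilnep_like`, 28%) and two degraded,
#' macroalgae-dominated sites without urchins (`cangaluyan_like`, 12%;
#' `tomasa_like`, 3%). The modelled area note is 500 m x 500 m, the scale at
#' which marine reserves are implemented locally. Optional jitter perturbs
#' covers and biomasses multiplicatively (log-uniform factors in
#' `[1/(1+jitter), 1+jitter]`), after which covers are renormalised to sum
#' to one; at the same seed the archetype coral ordering is preserved for
#' any jitter amplitude up to 0.5.
#'
#' @param archetype one of [site_archetypes()].
#' @param seed integer seed for the jitter draws.
#' @param jitter multiplicative jitter amplitude in `[0, 0.5]` (0 = exact
#'   defaults).
#' @param params optional [site_params()] overriding the default rates
#'   (`urchins_present` is forced to the archetype's value).
#' @return An object of class `"site_archetype"`: list with `label`,
#'   `urchins_present`, `initial` ([reef_state()]), `params`
#'   ([site_params()]), `area_note`, `seed`, `jitter`.
#' @examples
#' make_site("tomasa_like")$initial
#' @export
make_site <- function(archetype = site_archetypes(), seed = 1, jitter = 0,
                      params = NULL) {
  archetype <- match.arg(archetype)
  if (jitter < 0 || jitter > 0.5) stop("jitter must be in [0, 0.5]")
  a <- site_archetype_defaults()[[archetype]]
  covers <- a$covers
  biomass <- a$biomass
  if (jitter > 0) {
    set.seed(seed)
    lo <- -log1p(jitter); hi <- log1p(jitter)
    covers <- covers * exp(runif(4, lo, hi))
    fb <- exp(runif(3, lo, hi))
    if (!a$urchins) fb[3] <- 1
    biomass <- biomass * fb
  }
  covers <- covers / sum(covers)
  if (is.null(params)) params <- site_params()
  params$urchins_present <- a$urchins
  initial <- reef_state(coral = covers[["coral"]], eac = covers[["eac"]],
                        macroturf = covers[["macroturf"]],
                        macroalgae = covers[["macroalgae"]],
                        herbivore = biomass[["herbivore"]],
                        piscivore = biomass[["piscivore"]],
                        urchin = if (a$urchins) biomass[["urchin"]] else 0)
  structure(list(label = archetype, urchins_present = a$urchins,
                 initial = initial, params = params,
                 area_note = "500 m x 500 m", seed = seed, jitter = jitter),
            class = "site_archetype")
}

#' @export
print.site_archetype <- function(x, ...) {
  cat(sprintf("Site archetype '%s' (urchins %s; area %s)\n", x$label,
              if (x$urchins_present) "present" else "absent", x$area_note))
  print(x$initial)
  invisible(x)
}

#' The four default site fixtures
#'
#' @param seed,jitter passed to [make_site()] for every archetype.
#' @return Named list of the four [make_site()] archetypes.
#' @export
default_sites <- function(seed = 1, jitter = 0) {
  sites <- lapply(site_archetypes(), make_site, seed = seed, jitter = jitter)
  names(sites) <- site_archetypes()
  sites
}

#' Generate a series of sites across a degradation gradient
#'
#' Supports sensitivity sweeps across initial condition: `n_sites` sites
#' with initial coral cover evenly spaced across `coral_range`, all other
#' variables filled by interpolating the archetype rules between the most
#' degraded (`tomasa_like`) and least degraded (`lucero_like`) compositions.
#' Urchins are absent throughout the series.
#'
#' @param n_sites number of sites (>= 1); a single site sits at the range
#'   midpoint.
#' @param coral_range length-2 increasing range inside `(0, 1)`.
#' @param seed recorded seed (the series itself is deterministic).
#' @return List of `site_archetype` objects labelled `gradient_01`, ...
#' @export
make_degradation_series <- function(n_sites, coral_range = c(0.05, 0.25),
                                    seed = 1) {
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (length(coral_range) != 2 || diff(coral_range) < 0 ||
      coral_range[1] <= 0 || coral_range[2] >= 1)
    stop("coral_range must be an increasing range inside (0, 1)")
  if (coral_range[1] == coral_range[2] && n_sites > 1)
    stop("empty coral_range")
  corals <- if (n_sites == 1) mean(coral_range) else
    seq(coral_range[1], coral_range[2], length.out = n_sites)
  ad <- site_archetype_defaults()
  lo <- ad$tomasa_like; hi <- ad$lucero_like
  lo_w <- lo$covers[c("eac", "macroturf", "macroalgae")] /
    sum(lo$covers[c("eac", "macroturf", "macroalgae")])
  hi_w <- hi$covers[c("eac", "macroturf", "macroalgae")] /
    sum(hi$covers[c("eac", "macroturf", "macroalgae")])
  c_lo <- lo$covers[["coral"]]; c_hi <- hi$covers[["coral"]]
  lapply(seq_len(n_sites), function(i) {
    cc <- corals[i]
    t <- min(1, max(0, (cc - c_lo) / (c_hi - c_lo)))
    w <- (1 - t) * lo_w + t * hi_w
    rest <- (1 - cc) * w / sum(w)
    bio <- (1 - t) * lo$biomass + t * hi$biomass
    params <- site_params(urchins_present = FALSE)
    initial <- reef_state(coral = cc, eac = rest[["eac"]],
                          macroturf = rest[["macroturf"]],
                          macroalgae = rest[["macroalgae"]],
                          herbivore = bio[["herbivore"]],
                          piscivore = bio[["piscivore"]], urchin = 0)
    structure(list(label = sprintf("gradient_%02d", i),
                   urchins_present = FALSE, initial = initial,
                   params = params, area_note = "500 m x 500 m",
                   seed = seed, jitter = 0),
              class = "site_archetype")
  })
}
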