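---
title: "Simulating coral reef futures under multiple stressors: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating coral reef futures under multiple stressors: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefcast)
```

# The model

`reefcast` simulates a shallow (~5–20 m) coral reef community as a
mean-field difference-equation system updated daily. The state has seven
variables: four benthic covers that partition the substrate — hard coral
($C$), grazed epilithic algal community (EAC, $E$), macroturf ($T$) and
macroalgae ($M$), with $C + E + T + M = 1$ — and the biomasses (g m$^{-2}$)
of up to three consumer groups: herbivorous fish ($H$), piscivorous fish
($P$) and grazing sea urchins ($U$). EAC doubles as the colonisable "free
space": dead coral skeleton kept in a cropped state by grazing, onto which
coral and algae expand.

All rates are annual and divided by 365 at each daily step. The benthic
transfers are:

* coral lateral growth onto EAC, $g_C \, C E$, and coral recruitment onto
  colonisable substrate, $(r_{ext} + r_{endo} C)(E + T)$ — an external
  larval-supply term plus an endogenous term proportional to local cover
  (recruitment onto macroturf is blocked under sedimentation);
* coral natural mortality $m_C \, C$, returning cover to EAC;
* macroalgal overgrowth of live coral, $o_M \, M C$;
* macroturf formation from EAC under a constant turf growth pressure
  $g_T E$, and macroalgal vegetative spread $g_M \, M E$;
* mass-action grazing, linear in grazer biomass and resource cover:
  grazing on macroturf and macroalgae returns their cover to EAC, while
  grazing on EAC maintains the cropped state without a cover transfer.

Every transfer debits one pool and credits another, so total cover is
conserved exactly; if a pool's outflows would exceed the pool within one
step, all of its outflows are scaled proportionally so it empties but never
goes negative.

Consumers gain biomass from recruitment and assimilated intake and lose it
to natural mortality, piscivory (mass-action, $p_r P H$) and fishing
extraction. Removals are applied after growth and truncated at zero, so
extraction exceeding the standing stock empties it without producing
negative biomass. Fish recruitment is scaled by a coral-cover feedback

$$\phi(C) = \min\!\left(1,\; r_{min} + (1 - r_{min})\, C / c_{ref}\right),$$

with defaults $r_{min} = 0.1$ and $c_{ref} = 0.3$: recruitment is
unconstrained at or above 30% coral cover and falls to a 10% floor on a
dead reef. The defaults are consistent with recruitment at a heavily
degraded site (<3% coral) being strongly constrained while the healthier
sites (~20–30%) are not. Urchin recruitment is not coral-dependent, and
where urchins are absent their biomass is frozen at zero.

Two assimilation choices deserve note. First, herbivores assimilate
macroalgal intake with a much lower efficiency than EAC/turf intake
(default 0.02 vs 2.2): structurally complex, chemically defended macroalgae
are grazed (removing cover) but contribute little fish production. Second,
the maximum per-capita assimilation growth rate at any food composition
(0.33 yr$^{-1}$ with the defaults) is deliberately kept below natural
mortality (0.6 yr$^{-1}$), so fish biomass is recruitment-limited rather
than food-limited. This is what lets the coral-recruitment feedback
propagate bottom-up: when coral collapses, fish recruitment collapses, and
fish biomass settles at a low recruitment/mortality balance instead of
blooming on the abundant algae.

# Stressor forcings

Four forcings modify the dynamics; ranged quantities are drawn uniformly
once per replicate run, which is the model's stochastic element.

* **Nutrification** scales macroturf growth by 1.3–2 and macroalgal growth
  by 2–7. The macroalgal scaling is applied to both vegetative spread
  ($g_M$) and coral overgrowth ($o_M$): both are macroalgal growth
  processes and splitting them would make the forcing weaker than its
  description.
* **Sedimentation** multiplies coral growth by $1-u$, $u \sim U[0, 0.3]$,
  coral recruitment by $1-v$, $v \sim U[0, 0.6]$, adds 0–0.2 yr$^{-1}$ to
  coral mortality, and blocks coral recruitment onto macroturf.
  Nutrification and sedimentation are always applied together (both
  originate from aquaculture-driven poor water quality) and exactly once
  per run, guarded by a flag.
* **Fishing** removes a fixed tonnage (t km$^{-2}$ yr$^{-1}$, numerically
  equal to g m$^{-2}$ yr$^{-1}$), split 68.3% / 31.7% between herbivorous
  and piscivorous fish following the observed catch composition. The
  current-yield level draws from 2.6–2.8, the managed level from 1.3–1.4
  (50% of current), and marine-reserve management is zero extraction.
  Constant-rate extraction (not proportional harvest) matches management
  levers expressed as yields.
* **Bleaching** removes a fraction of live coral instantaneously on its
  event day, before that day's update; the lost cover becomes EAC, so
  total cover is conserved. In stochastic mode each year is an event with
  probability (frequency per decade)/10 — a Bernoulli scheme that delivers
  the stated long-run frequency with minimal structure — and severity is
  drawn from 10–60% per event. Trajectory and recovery analyses instead use
  a fixed schedule: −30% at year 20 and −15% at year 38.

# Site archetypes (the synthetic parameterisation)

No deposited site data exist, so `make_site()` generates four archetypes
emulating the structure of the Bolinao reef system: two less-degraded
sites with sea urchins (`lucero_like`, 30% initial coral; `malilnep_like`,
28%) and two degraded, macroalgae-dominated sites without urchins
(`cangaluyan_like`, 12%; `tomasa_like`, 3%), each over a 500 m × 500 m
area. Optional jitter perturbs covers and biomasses with multiplicative
log-uniform factors (preserving positivity) and renormalises covers; at a
common seed the archetype coral ordering is preserved at any admissible
amplitude.

The rate defaults are a calibrated reconstruction, not empirical values.
They were chosen, once, so that the simulated system reproduces the
qualitative outcomes the scenario analysis rests on:

* an unstressed healthy site is persistent over 40 years (coral ~30–40%,
  macroalgae grazed to near zero, urchin biomass stable);
* under poor water quality the ensemble-mean coral cover of every
  archetype falls below 0.5% within at most ~10 years (well inside the
  12-year envelope), through the cascade: sedimentation depresses coral →
  fish recruitment falls → grazing fails → boosted macroalgae escape and
  overgrow the remaining coral. The collapse is robust across the whole
  drawn forcing range, including its weak end;
* under poor water quality, year-40 herbivore and piscivore biomass stays
  below 1400 kg km$^{-2}$ at every fishing level, including zero fishing
  (the recruitment-limitation design above);
* with good water quality and the fixed bleaching schedule, post-bleaching
  recovery increases as fishing decreases at the healthy sites (~+10
  points of cover between events), is weak at `cangaluyan_like` and
  essentially absent at `tomasa_like`, where only external recruitment
  trickles in — the initial-state dependence that motivates site-specific
  management.

What the generator does *not* emulate: empirical 2008 covers (the
supplementary validation data are not reproduced), within-site spatial
structure, size/age structure, species diversity within functional groups,
connectivity, acidification and storms. Passing tests therefore show that
the pipeline and its statistics behave correctly on a system with this
structure, not that the parameter values are those of any real
site.

# Scenario engine

`scenario_grid()` builds the full factorial of 3 fishing × 3 bleaching ×
2 water-quality levels (18 scenarios). `run_ensemble()` runs Monte-Carlo
ensembles (default 20 replicates over 40 years); replicate $i$ of scenario
$s$ uses the pure child seed `child_seed(master, s, i)`, so any replicate
is reproducible in isolation and a whole run is byte-identical given one
master seed. `snapshot_matrix()` extracts the runs × variables community
matrix at the a-priori snapshot years (5, 10, 20, 40; year $y$ = day
$365y$), with covers in % and biomasses in g m$^{-2}$; the urchin column is
omitted at sites without urchins (it would be constant and cannot be
normalised).

# Multivariate analysis

All analyses operate on normalised variables (z-scores, denominator
$n-1$) and Euclidean distances, since covers and biomasses are on
different scales.

**PERMANOVA** (`reef_permanova()`) partitions the sum of squared
distances over the crossed fixed-factor design following Anderson's
geometric construction; for Euclidean distances this is computed in
principal-coordinate space, where the term projections reproduce classical
ANOVA exactly (the tests assert equality with `aov` to 1e-9 and with
`vegan::adonis2` as an independent cross-check). Designs must be balanced,
which makes the term subspaces orthogonal so SS partitions add to the
total. Significance uses permutation of residuals under a reduced model
(Freedman–Lane): for each term, the residuals of the model containing all
*other* terms are permuted, added back to that reduced fit, and the full
model is refit. p-values use $(b+1)/(m+1)$, so $p \ge 1/(m+1)$ and a null
term's size stays at the nominal level (verified over 500 null datasets).
Degenerate input (all points coincident) is reported as such with no
p-values. A-posteriori pairwise tests report $t = \sqrt{F}$ alongside
pseudo-$F$ with no multiplicity adjustment, the convention for these
comparisons.

**PERMDISP** (`reef_permdisp()`) computes each point's distance to its
group centroid in principal-coordinate space — axes with negative
eigenvalues (impossible for Euclidean input but supported for generality)
enter as subtracted squared components, clamped at zero — then forms the
classical one-way F on those distances and permutes their least-squares
residuals. Centroids, not spatial medians, are used.

**CAP** (`reef_cap()`) truncates the principal-coordinate decomposition to
$m$ axes and fits canonical discriminant axes on them; `m = "auto"`
maximises leave-one-out allocation success with ties broken toward smaller
$m$. **nMDS** (`reef_nmds()`) delegates to `vegan`'s monotone-regression
engine with seeded random restarts, reporting Kruskal stress-1 on the 0–1
scale. Both ordinations accept the raw variable matrix to produce Spearman
correlation vector overlays (display threshold $|r| > 0.20$).

**Effect sizes** are mean between-group Euclidean distances, and
`classify_interaction()` compares a combined effect with the sum of the
individual effects within a tolerance band: below = antagonistic (the
dominant-stressor mechanism: one stressor degrades the system so far the
other adds little), above = synergistic, else additive.

# Trajectory metrics

`coral_recovery()` reads cover the day after the first bleaching event and
the day before the second (the identity relative = 100 × absolute / post
reproduces every tabulated recovery row), flagging non-recovery rather
than reporting negative change. `time_to_collapse()` returns the first
year cover reaches a threshold; the default 0.5% is the cover that rounds
to 0% at the whole-percent resolution management tables use — literal zero
is unreachable because external larval supply keeps cover strictly
positive (equilibrium of order 10$^{-4}$ under poor water quality).
`ensemble_summary()` reports per-year means and SDs including the combined
algae (macroturf + macroalgae) series.

# Numerical choices and degenerate inputs

* Daily forward-Euler stepping of annual rates (rate/365); at the default
  rates the step is far inside the stability region, and conservation and
  non-negativity are enforced structurally (proportional outflow scaling,
  truncated removals), not by renormalisation. Cover sums drift by less
  than 1e-9 over 10$^5$ random steps.
* Eigenvalues below `1e-9` × the spectral radius are treated as zero in
  principal-coordinate decompositions.
* Permutation tests never report p = 0 (the $(b+1)/(m+1)$ convention);
  ties in permuted statistics count as exceedances (`>=` with a 1e-12
  slack) for conservatism.
* Pairwise tests with a group of fewer than two members are skipped with a
  warning; constant columns abort normalisation with instructions to drop
  the variable.
* `child_seed()` uses small prime multipliers so the arithmetic is exact
  in doubles and the result is a valid 32-bit seed.

# Problem sizes used in the checks

The packaged tests and the acceptance script run the full study design
where it is cheap (20 replicates × 40 years × 4 sites for the trajectory
claims; the 18-scenario grid for counting identities) and reduced designs
for permutation-heavy properties (e.g. type-I error over 500 null datasets
at 199 permutations; pairwise tests on small synthetic clusters). A single
40-year replicate takes ~0.1 s, a 20-replicate ensemble ~1.5 s.

# Known limitations

Mean-field, spatially implicit dynamics; one coral functional group;
no hysteresis/phase-shift formalism (the machinery can produce the
trajectories but does not analyse alternative stable states); linear
(type-I) grazing responses; piecewise-linear recruitment feedback;
fishing as constant tonnage with perfect compliance; stressor magnitudes
uniform across sites; historical validation against survey time series is
out of scope.
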