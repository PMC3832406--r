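# reefcast

Scenario analysis of coral reef futures under multiple local and climatic
stressors.

Coral reefs degrade under the *combined* impact of locally manageable
stressors — fishing and poor water quality (nutrification and
sedimentation from aquaculture) — and climate-driven thermal bleaching.
Managers need to know which interventions will matter, where, and on what
time scale, which requires understanding how these stressors interact
(additively, synergistically, or antagonistically) rather than studying
them one at a time. `reefcast` is a decision-support toolkit for exactly
that question, aimed at reef ecologists and marine-resource modellers.

The package provides three connected layers:

1. **A stochastic reef simulator** — a daily difference-equation model of
   four benthic covers (hard coral *C*, epilithic algal community *E*,
   macroturf *T*, macroalgae *M*, with *C*+*E*+*T*+*M* = 1) and three
   consumer biomasses (herbivorous fish, piscivorous fish, sea urchins).
   Benthic transfers (lateral coral growth g<sub>C</sub>·C·E, recruitment
   (r<sub>ext</sub>+r<sub>endo</sub>C)(E+T), mortality m<sub>C</sub>C,
   macroalgal overgrowth o<sub>M</sub>·M·C, turf pressure g<sub>T</sub>E,
   mass-action grazing) are zero-sum; fish recruitment is scaled by the
   coral-cover feedback φ(C) = min(1, r<sub>min</sub> +
   (1−r<sub>min</sub>)·C/c<sub>ref</sub>). Forcings implement
   nutrification/sedimentation (parameter scalings drawn uniformly from
   published ranges), fishing (fixed tonnage split 68.3%/31.7% between
   herbivores and piscivores) and bleaching (instantaneous fractional
   coral loss).
2. **A factorial Monte-Carlo scenario engine** — the full 3 fishing × 3
   bleaching × 2 water-quality grid (18 scenarios), seeded replicate
   ensembles (20 × 40 years by default), and snapshot community matrices
   at a-priori years (5, 10, 20, 40).
3. **The permutational multivariate statistics** used to analyse simulated
   reef states: PERMANOVA on normalised Euclidean distances with
   permutation of residuals under a reduced model, a-posteriori pairwise
   tests, PERMDISP (distance-to-centroid dispersion), CAP and nMDS
   ordinations with Spearman vector overlays, mean-distance effect sizes
   with antagonism/synergy classification, and management-facing
   trajectory metrics (post-bleaching coral recovery, time-to-collapse).

Four synthetic site archetypes (`lucero_like`, `malilnep_like`,
`cangaluyan_like`, `tomasa_like`) emulate the structure of the Bolinao
(Philippines) reef system the analysis was designed around: two healthier
sites with urchins, two degraded macroalgae-dominated sites without.

## Worked example

Does managing water quality or fishing matter for a healthy reef over 20
years, and do the two stressors interact?

```r
library(reefcast)

lucero <- make_site("lucero_like")

grid <- scenario_grid(fishing_levels = c("none", "high"),
                      bleaching_levels = "once-per-decade",
                      water_levels = c("regulated", "unregulated"))

ens <- lapply(seq_len(nrow(grid)), function(i)
  run_ensemble(grid[i, ], lucero, n_replicates = 20, master_seed = 1,
               horizon_years = 20, scenario_index = i))

cm <- snapshot_matrix(ens, year = 20)
d  <- community_dist(cm)

reef_permanova(d, attr(d, "groups")[, c("fishing", "water")],
               nperm = 999, seed = 1)
#> PERMANOVA (permutation of residuals under a reduced model, 999 permutations)
#>           term Df SumOfSqs MeanSqs pseudoF p_perm
#>        fishing  1    55.93   55.93   22.96  0.001
#>          water  1   267.20  267.20  109.70  0.001
#>  fishing:water  1    44.83   44.83   18.41  0.001
#> Residual: Df 76, SS 185.1;  Total SS 553

reef_permdisp(d, cm$scenario, nperm = 999, seed = 1)
#> PERMDISP: F = 5.401 on 3 and 76 df, p(perm) = 0.004 (999 permutations)
```

Both stressors shift mean reef state (small PERMANOVA p-values), they
interact, and dispersion differs too — replicate futures are *least*
variable (most predictable) under poor water quality with fishing, because
those runs converge on the same collapsed, algae-dominated state. Effect
sizes (mean Euclidean distance from the no-impact scenario) classify the
interaction:

```r
ref <- grid$label[1]
e_f  <- effect_size(d, cm$scenario, ref, grid$label[2])   # fishing alone
e_ns <- effect_size(d, cm$scenario, ref, grid$label[3])   # poor water alone
e_b  <- effect_size(d, cm$scenario, ref, grid$label[4])   # both
c(e_f, e_ns, e_b)
#> [1] 3.41 4.82 5.07
classify_interaction(e_f, e_ns, e_b)
#> [1] "antagonistic"

time_to_collapse(ensemble_mean_trajectory(ens[[4]]))
#> [1] 7
```

The combined effect (5.07) is far below the sum of the individual effects
(8.23): an antagonistic interaction through a dominant-stressor mechanism —
poor water quality alone degrades the reef so thoroughly (ensemble-mean
coral cover reaches 0% within 7 years here) that fishing can add little.
`coral_recovery()` and `recovery_table()` summarise post-bleaching recovery
under the fixed year-20/38 bleaching schedule, and `run_pipeline()` drives
the whole grid from a YAML configuration with a digest manifest for
byte-identical reruns.

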