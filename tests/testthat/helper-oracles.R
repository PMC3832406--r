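## Straight-line, term-by-term recomputation of one daily update, written
## independently of reef_step(): every process flux is computed and applied
## one at a time, so any disagreement localises the defective term.
oracle_step <- function(state, p, xh = 0, xp = 0, block = FALSE) {
  C <- state[["coral"]]; E <- state[["eac"]]
  Tt <- state[["macroturf"]]; Mm <- state[["macroalgae"]]
  H <- state[["herbivore"]]; P <- state[["piscivore"]]
  U <- if (p$urchins_present) state[["urchin"]] else 0
  dty <- 1 / 365

  phi <- min(1, p$recruit_floor +
               (1 - p$recruit_floor) * C / p$recruit_saturation)

  term_growth <- p$coral_growth * C * E * dty
  term_rec_e <- (p$coral_recruit_ext + p$coral_recruit_endo * C) * E * dty
  term_rec_t <- if (block) 0 else
    (p$coral_recruit_ext + p$coral_recruit_endo * C) * Tt * dty
  term_mort <- p$coral_mortality * C * dty
  term_over <- p$ma_overgrowth * Mm * C * dty
  term_turf <- p$turf_growth * E * dty
  term_ma <- p$ma_growth * Mm * E * dty
  term_grz_t <- (p$herb_graze_turf * H + p$urchin_graze_turf * U) * Tt * dty
  term_grz_m <- (p$herb_graze_ma * H + p$urchin_graze_ma * U) * Mm * dty

  out_E <- term_growth + term_rec_e + term_turf + term_ma
  out_C <- term_mort + term_over
  out_T <- term_rec_t + term_grz_t
  out_M <- term_grz_m
  sE <- if (out_E > E) E / out_E else 1
  sC <- if (out_C > C) C / out_C else 1
  sT <- if (out_T > Tt) Tt / out_T else 1
  sM <- if (out_M > Mm) Mm / out_M else 1

  C2 <- C
  C2 <- C2 - term_mort * sC - term_over * sC
  C2 <- C2 + term_growth * sE + term_rec_e * sE + term_rec_t * sT
  E2 <- E
  E2 <- E2 - term_growth * sE - term_rec_e * sE - term_turf * sE -
    term_ma * sE
  E2 <- E2 + term_mort * sC + term_grz_t * sT + term_grz_m * sM
  T2 <- Tt
  T2 <- T2 - term_rec_t * sT - term_grz_t * sT
  T2 <- T2 + term_turf * sE
  M2 <- Mm
  M2 <- M2 - term_grz_m * sM
  M2 <- M2 + term_over * sC + term_ma * sE

  term_h_recruit <- p$herb_recruit * phi * dty
  term_h_assim <- H * (p$herb_assim * (p$herb_graze_eac * E +
                                         p$herb_graze_turf * Tt) +
                         p$herb_assim_ma * p$herb_graze_ma * Mm) * dty
  term_h_mort <- H * p$herb_mortality * dty
  term_h_pred <- p$piscivory * P * H * dty
  term_h_extr <- xh * dty
  H2 <- max(H + term_h_recruit + term_h_assim - term_h_mort - term_h_pred -
              term_h_extr, 0)

  term_p_recruit <- p$pisc_recruit * phi * dty
  term_p_assim <- p$pisc_assim * p$piscivory * P * H * dty
  term_p_mort <- P * p$pisc_mortality * dty
  term_p_extr <- xp * dty
  P2 <- max(P + term_p_recruit + term_p_assim - term_p_mort - term_p_extr, 0)

  if (p$urchins_present) {
    term_u_recruit <- p$urchin_recruit * dty
    term_u_assim <- U * p$urchin_assim * (p$urchin_graze_eac * E +
                                            p$urchin_graze_turf * Tt +
                                            p$urchin_graze_ma * Mm) * dty
    term_u_mort <- U * p$urchin_mortality * dty
    U2 <- max(U + term_u_recruit + term_u_assim - term_u_mort, 0)
  } else U2 <- 0

  c(coral = C2, eac = E2, macroturf = T2, macroalgae = M2,
    herbivore = H2, piscivore = P2, urchin = U2)
}

healthy_state <- function() {
  reef_state(coral = 0.3, eac = 0.55, macroturf = 0.1, macroalgae = 0.05,
             herbivore = 4, piscivore = 1, urchin = 8)
}

## random valid state: covers from a Dirichlet-like normalised draw
random_state <- function() {
  cv <- runif(4)
  cv <- cv / sum(cv)
  reef_state(cv[1], cv[2], cv[3], cv[4],
             herbivore = runif(1, 0, 20), piscivore = runif(1, 0, 10),
             urchin = runif(1, 0, 20))
}

## random parameter set: every rate scaled by an independent factor
random_params <- function(urchins = TRUE) {
  p <- site_params(urchins_present = urchins)
  for (nm in setdiff(names(p), c("urchins_present", "recruit_floor",
                                 "recruit_saturation")))
    p[[nm]] <- p[[nm]] * runif(1, 0, 3)
  p
}

## small separable clusters for ordination tests
make_clusters <- function(k = 3, n_per = 10, p = 4, sep = 10, sd = 1) {
  centers <- matrix(rnorm(k * p, sd = sep), k, p)
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(rnorm(n_per * p, mean = rep(centers[i, ], each = n_per),
                 sd = sd), n_per, p)))
  list(x = x, groups = factor(rep(seq_len(k), each = n_per)))
}
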