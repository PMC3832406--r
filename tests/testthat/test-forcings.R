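test_that("forcing constructors enforce the documented ranges", {
  expect_error(nutrient_forcing(turf_growth_scale = 1.1), "1.3")
  expect_error(nutrient_forcing(macroalgae_growth_scale = 8), "2, 7")
  expect_error(sediment_forcing(coral_growth_reduction = 0.4), "0.3")
  expect_error(sediment_forcing(coral_recruit_reduction = 0.7), "0.6")
  expect_error(sediment_forcing(coral_mortality_increase = 0.3), "0.2")
  expect_error(fishing_regime(c(2, 1)), "range")
  expect_error(fishing_regime(herbivore_share = 0.5, piscivore_share = 0.4),
               "sum to 1")
  expect_error(bleaching_regime(frequency_per_decade = 3), "0, 1 or 2")
  expect_true(sediment_forcing()$block_recruitment_on_macroturf)
})

test_that("degenerate ranges collapse to their lower bounds", {
  nf <- nutrient_forcing(1.3, 2)
  expect_equal(nf$turf_growth_scale, 1.3)
  expect_equal(nf$macroalgae_growth_scale, 2)
})

test_that("no-impact water quality means no nutrient/sediment scalars", {
  sc <- reef_scenario("high", "none", "regulated")
  fs <- draw_forcings(sc, 1)
  expect_false(fs$water_quality_active)
  expect_null(fs$nutrients)
  expect_null(fs$sediments)
})

test_that("macroalgal growth draws are uniform on [2, 7]", {
  draws <- vapply(1:10000, function(s) {
    fs <- draw_forcings(reef_scenario("none", "none", "unregulated"), s)
    fs$nutrients$macroalgae_growth_scale
  }, numeric(1))
  expect_true(all(draws >= 2 & draws <= 7))
  se <- (5 / sqrt(12)) / sqrt(10000)
  expect_lt(abs(mean(draws) - 4.5), 3 * se)
})

test_that("all stochastic draws sit within their closed ranges", {
  sc <- reef_scenario("high", "twice-per-decade", "unregulated")
  for (s in seq(1, 20000, by = 7)) {
    fs <- draw_forcings(sc, s, horizon_years = 40)
    stopifnot(fs$realised_fishing_total >= 2.6,
              fs$realised_fishing_total <= 2.8,
              fs$nutrients$turf_growth_scale >= 1.3,
              fs$nutrients$turf_growth_scale <= 2,
              fs$nutrients$macroalgae_growth_scale >= 2,
              fs$nutrients$macroalgae_growth_scale <= 7,
              fs$sediments$coral_growth_reduction >= 0,
              fs$sediments$coral_growth_reduction <= 0.3,
              fs$sediments$coral_recruit_reduction >= 0,
              fs$sediments$coral_recruit_reduction <= 0.6,
              fs$sediments$coral_mortality_increase >= 0,
              fs$sediments$coral_mortality_increase <= 0.2,
              all(vapply(fs$bleaching_schedule, `[[`, numeric(1),
                         "severity") >= 0.1),
              all(vapply(fs$bleaching_schedule, `[[`, numeric(1),
                         "severity") <= 0.6))
  }
  succeed()
})

test_that("water-quality application scales exactly the stated parameters", {
  p <- site_params()
  # identity scalars leave every parameter untouched
  id <- apply_water_quality(p, nutrient_forcing(1.3, 2) , sediment_forcing())
  expect_equal(id$turf_growth, p$turf_growth * 1.3)
  q <- apply_water_quality(p, nutrient_forcing(1.5, 7),
                           sediment_forcing(0.3, 0.6, 0.2))
  expect_equal(q$ma_growth, p$ma_growth * 7)        # 0.4 * 7 = 2.8
  expect_equal(q$ma_overgrowth, p$ma_overgrowth * 7)
  expect_equal(q$turf_growth, p$turf_growth * 1.5)
  expect_equal(q$coral_growth, p$coral_growth * 0.7)
  expect_equal(q$coral_recruit_ext, p$coral_recruit_ext * 0.4)
  expect_equal(q$coral_recruit_endo, p$coral_recruit_endo * 0.4)
  expect_equal(q$coral_mortality, p$coral_mortality + 0.2)
  # untouched parameters stay bit-identical
  for (nm in c("herb_graze_eac", "herb_recruit", "piscivory",
               "urchin_assim", "recruit_floor"))
    expect_identical(q[[nm]], p[[nm]])
  # a 0.6 recruitment reduction on rate 0.05 gives 0.02
  p2 <- site_params(coral_recruit_ext = 0.05)
  q2 <- apply_water_quality(p2, nutrient_forcing(),
                            sediment_forcing(coral_recruit_reduction = 0.6))
  expect_equal(q2$coral_recruit_ext, 0.02)
})

test_that("water-quality forcing cannot be applied twice", {
  p <- apply_water_quality(site_params(), nutrient_forcing(),
                           sediment_forcing())
  expect_error(apply_water_quality(p, nutrient_forcing(),
                                   sediment_forcing()), "already applied")
})

test_that("disabling a forcing reproduces the unforced setup bit-exactly", {
  sc_on <- reef_scenario("high", "none", "unregulated")
  sc_off <- reef_scenario("high", "none", "regulated")
  p <- site_params()
  fs_off <- draw_forcings(sc_off, 9)
  expect_false(fs_off$water_quality_active)
  s <- healthy_state()
  t_off <- reef_simulate(s, p, fs_off, 1)
  t_plain <- reef_simulate(s, p, forcing_set(
    fishing = fishing_regime(c(2.6, 2.8)),
    realised_fishing_total = fs_off$realised_fishing_total), 1)
  expect_identical(t_off$states, t_plain$states)
})

test_that("bleaching schedules: empty, fixed, and stochastic frequency", {
  expect_length(schedule_bleaching(bleaching_regime(0), 40, 1), 0)
  fx <- bleaching_regime(mode = "fixed",
                         fixed_schedule = fixed_bleaching_schedule())
  sched <- schedule_bleaching(fx, 40)
  expect_equal(vapply(sched, `[[`, numeric(1), "year"), c(20, 38))
  expect_equal(vapply(sched, `[[`, numeric(1), "severity"), c(0.30, 0.15))
  expect_error(schedule_bleaching(fx, 30), "beyond the horizon")
  # binomial mean: 40 years at p = 1/10 -> 4 expected events
  counts <- vapply(1:5000, function(s)
    length(schedule_bleaching(bleaching_regime(1), 40, s)), numeric(1))
  se <- sqrt(40 * 0.1 * 0.9 / 5000)
  expect_lt(abs(mean(counts) - 4), 3 * se)
})

test_that("bleaching events conserve benthic cover exactly", {
  s <- reef_state(0.30, 0.40, 0.20, 0.10, 2, 1, 0)
  b <- apply_bleaching_event(s, 0.30)
  expect_equal(b[["coral"]], 0.21)
  expect_equal(b[["eac"]], 0.49)
  expect_identical(sum(b[1:4]), sum(s[1:4]))
  expect_identical(b[5:7], s[5:7])
  expect_identical(unclass(apply_bleaching_event(s, 0)), unclass(s))
  s0 <- reef_state(0, 0.5, 0.3, 0.2)
  expect_identical(unclass(apply_bleaching_event(s0, 0.6)), unclass(s0))
  expect_error(apply_bleaching_event(s, 1.2), "severity")
})

test_that("extraction split follows the 68.3/31.7 catch composition", {
  reg <- fishing_regime(c(2.6, 2.8))
  ex0 <- extraction_rates(fishing_regime(c(0, 0)), 0)
  expect_equal(unname(ex0$annual), c(0, 0))
  ex <- extraction_rates(reg, 2.7)
  expect_equal(ex$annual[["herbivore"]], 1.8441)
  expect_equal(ex$annual[["piscivore"]], 0.8559)
  expect_equal(ex$daily[["herbivore"]], 1.8441 / 365)  # 0.0050523 g m-2 d-1
  expect_equal(sum(ex$annual), 2.7)
  expect_error(extraction_rates(reg, 3.0), "range")
  expect_error(extraction_rates(reg, -1), ">= 0")
})

test_that("nutrification and sedimentation must co-occur", {
  expect_error(forcing_set(nutrients = nutrient_forcing(), sediments = NULL),
               "jointly")
})
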