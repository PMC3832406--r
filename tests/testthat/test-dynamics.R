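test_that("recruitment multiplier: floor, saturation, interpolation", {
  expect_equal(fish_recruitment_multiplier(0.0, 0.1, 0.3), 0.1)
  expect_equal(fish_recruitment_multiplier(0.3, 0.1, 0.3), 1.0)
  expect_equal(fish_recruitment_multiplier(1.0, 0.1, 0.3), 1.0)
  # linear interpolation r_min + (1 - r_min) * C / c_ref
  expect_equal(fish_recruitment_multiplier(0.15, 0.1, 0.3), 0.55)
  # monotone non-decreasing, bounded in [r_min, 1]
  cc <- seq(0, 1, length.out = 101)
  m <- fish_recruitment_multiplier(cc, 0.2, 0.4)
  expect_true(all(diff(m) >= 0))
  expect_true(all(m >= 0.2 & m <= 1))
  expect_error(fish_recruitment_multiplier(0.5, 0.1, 0), "c_ref")
})

test_that("state validation rejects broken invariants with diagnostics", {
  expect_error(reef_state(0.5, 0.5, 0.1, 0.0), "sum")
  expect_error(reef_state(0.5, 0.6, -0.1, 0.0), "negative")
  expect_error(reef_state(0.5, 0.4, 0.1, 0.0, herbivore = -1), "negative")
  s <- healthy_state()
  expect_silent(validate_reef_state(s))
})

test_that("a coral monoculture with no consumers conserves cover exactly", {
  s <- reef_state(1, 0, 0, 0)
  out <- reef_step(s, site_params())
  expect_identical(sum(out[1:4]), 1)
  expect_true(all(out >= 0))
})

test_that("zero rates give a fixed point of the daily update", {
  p <- zp <- reefcast:::zero_params()
  s <- healthy_state()
  out <- reef_step(s, p)
  expect_equal(unclass(out), unclass(s), tolerance = 0)
  tr <- reef_simulate(s, p, NULL, horizon_years = 1)
  expect_true(all(apply(tr$states, 1, function(r) all(r == unclass(s)))))
})

test_that("one step equals the independent term-by-term oracle to 1e-12", {
  p <- site_params()
  s <- healthy_state()
  expect_equal(unclass(reef_step(s, p)), oracle_step(s, p),
               tolerance = 1e-12)
  # with extraction and blocked turf recruitment
  expect_equal(unclass(reef_step(s, p, extraction_herb = 1.8441,
                                 extraction_pisc = 0.8559,
                                 block_turf_recruitment = TRUE)),
               oracle_step(s, p, xh = 1.8441, xp = 0.8559, block = TRUE),
               tolerance = 1e-12)
  # across random states and parameter sets
  set.seed(11)
  for (i in 1:25) {
    s <- random_state()
    pr <- random_params(urchins = i %% 2 == 0)
    xh <- runif(1, 0, 3); xp <- runif(1, 0, 2)
    blk <- i %% 3 == 0
    expect_equal(unclass(reef_step(s, pr, extraction_herb = xh,
                                   extraction_pisc = xp,
                                   block_turf_recruitment = blk,
                                   validate = FALSE)),
                 oracle_step(s, pr, xh = xh, xp = xp, block = blk),
                 tolerance = 1e-12)
  }
})

test_that("cover conservation and non-negativity hold over random steps", {
  set.seed(42)
  n <- 20000
  worst <- 0
  for (i in seq_len(n)) {
    s <- random_state()
    p <- random_params(urchins = i %% 2 == 0)
    out <- reef_step(s, p, extraction_herb = runif(1, 0, 10),
                     extraction_pisc = runif(1, 0, 10),
                     block_turf_recruitment = i %% 4 == 0,
                     validate = FALSE)
    if (any(out < 0)) fail(sprintf("negative state at iteration %d", i))
    worst <- max(worst, abs(sum(out[1:4]) - 1))
  }
  expect_lt(worst, 1e-9)
})

test_that("simulate: empty horizon returns exactly the initial state", {
  s <- healthy_state()
  tr <- reef_simulate(s, site_params(), NULL, horizon_years = 0)
  expect_equal(nrow(tr$states), 1)
  expect_equal(tr$states[1, ], unclass(s))
  expect_error(reef_simulate(s, site_params(), NULL, horizon_years = -1),
               "horizon")
})

test_that("simulate is deterministic: identical inputs, identical output", {
  s <- make_site("lucero_like")
  sc <- reef_scenario("high", "twice-per-decade", "unregulated")
  fs <- draw_forcings(sc, 123, horizon_years = 5)
  t1 <- reef_simulate(s$initial, s$params, fs, 5, seed = 123)
  t2 <- reef_simulate(s$initial, s$params, fs, 5, seed = 123)
  expect_identical(t1$states, t2$states)
})

test_that("simulate agrees with reef_step day by day", {
  s <- healthy_state()
  p <- site_params()
  tr <- reef_simulate(s, p, NULL, horizon_years = 1)
  cur <- s
  for (d in 1:365) {
    cur <- reef_step(cur, p, validate = FALSE)
    if (d %in% c(1, 100, 365))
      expect_equal(tr$states[d + 1, ], unclass(cur), tolerance = 1e-14)
  }
})

test_that("an unstressed healthy reef persists over 40 years", {
  s <- make_site("lucero_like")
  tr <- reef_simulate(s$initial, s$params, NULL, horizon_years = 40)
  expect_equal(nrow(tr$states), 14601)
  expect_gt(tr$states[14601, "coral"], 0)
  sums <- rowSums(tr$states[, 1:4])
  expect_lt(max(abs(sums - 1)), 1e-9)
  expect_true(all(tr$states >= 0))
})

test_that("urchin biomass stays frozen at zero where urchins are absent", {
  s <- make_site("tomasa_like")
  expect_false(s$params$urchins_present)
  expect_identical(s$initial[["urchin"]], 0)
  sc <- reef_scenario("high", "once-per-decade", "unregulated")
  fs <- draw_forcings(sc, 5, horizon_years = 3)
  tr <- reef_simulate(s$initial, s$params, fs, 3)
  expect_true(all(tr$states[, "urchin"] == 0))
})

test_that("bleaching events in the schedule hit on their event day", {
  s <- make_site("lucero_like")
  fs <- forcing_set(bleaching_schedule = list(list(year = 1,
                                                   severity = 0.5)))
  tr <- reef_simulate(s$initial, s$params, fs, 2)
  pre <- tr$states[365, "coral"]   # day 364
  post <- tr$states[366, "coral"]  # day 365: post-event
  expect_lt(post / pre, 0.52)
  expect_gt(post / pre, 0.48)
  # conservation across the event
  expect_lt(max(abs(rowSums(tr$states[, 1:4]) - 1)), 1e-9)
  expect_error(reef_simulate(s$initial, s$params,
                             forcing_set(bleaching_schedule =
                                           list(list(year = 5,
                                                     severity = 0.2))), 2),
               "beyond the horizon")
})

test_that("trajectory long-format export round-trips", {
  s <- healthy_state()
  tr <- reef_simulate(s, site_params(), NULL, horizon_years = 0)
  f <- tempfile(fileext = ".tsv")
  write_trajectory(tr, f)
  got <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(got), 7)
  expect_equal(got$value[got$variable == "coral"], 0.3)
  unlink(f)
})
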