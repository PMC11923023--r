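test_that("the empty plant stays empty and symmetric strains stay identical", {
  reg <- mite_params_registry()
  z <- simulate_mites(reg, scenario_schedule("constant32"),
                      init = model_state(), grid_step = 1)
  expect_equal(max(abs(c(z$NI1, z$NI2, z$NS1, z$NS2))), 0)
  expect_equal(crossover_day(z), NA_real_)
  expect_equal(unname(persistence(z)), c(FALSE, FALSE))

  # identical parameters, b = 1, identical stage vectors: trajectories match
  sym <- symmetric_registry(b = 1)
  tr <- simulate_mites(sym, scenario_schedule("hw2"),
                       init = model_state(NI2 = 50, NS2 = 50))
  expect_equal(tr$NI1, tr$NS1, tolerance = 1e-7)
  expect_equal(tr$NI2, tr$NS2, tolerance = 1e-7)
})

test_that("crossover detection handles trivial and absent crossings", {
  reg <- mite_params_registry()
  # suppressors already ahead at t = 0
  tr0 <- simulate_mites(reg, scenario_schedule("constant25"),
                        init = model_state(NI2 = 10, NS2 = 90), grid_step = 1)
  expect_equal(crossover_day(tr0), 0)
  # at 25C suppressors stay rarer all season
  tr25 <- simulate_mites(reg, scenario_schedule("constant25"))
  expect_true(is.na(crossover_day(tr25)))
  # consistency: NA exactly when inducers lead at every grid point
  for (tr in list(tr0, tr25)) {
    lead_everywhere <- min(tr$NI_total - tr$NS_total) > 0
    expect_equal(is.na(crossover_day(tr)), lead_everywhere)
  }
})

test_that("state is continuous across temperature switches", {
  tr <- simulate_mites(mite_params_registry(), scenario_schedule("hw2"),
                       grid_step = 0.1)
  expect_true(all(diff(tr$time_day) > 0))  # boundary rows are not duplicated
  # density is numerically continuous through each switch day
  for (boundary in c(14, 28, 42, 56, 70, 84)) {
    k <- which(abs(tr$time_day - boundary) < 1e-9)
    expect_length(k, 1)
    jump_in <- abs(tr$NI_total[k] - tr$NI_total[k - 1])
    jump_out <- abs(tr$NI_total[k + 1] - tr$NI_total[k])
    expect_lt(jump_in, 0.05 * max(tr$NI_total[k], 1))
    expect_lt(jump_out, 0.05 * max(tr$NI_total[k], 1))
  }
  # the switch day takes the new temperature
  expect_equal(tr$temperature[tr$time_day == 14], "32C")
})

test_that("the output grid does not affect accuracy and replays are bit-identical", {
  reg <- mite_params_registry()
  a <- simulate_mites(reg, scenario_schedule("constant32"), grid_step = 0.1)
  b <- simulate_mites(reg, scenario_schedule("constant32"), grid_step = 0.05)
  fa <- unlist(a[nrow(a), c("NI1", "NI2", "NS1", "NS2")])
  fb <- unlist(b[nrow(b), c("NI1", "NI2", "NS1", "NS2")])
  expect_lt(max(abs(fa - fb) / pmax(abs(fb), 1e-12)), 1e-4)

  a2 <- simulate_mites(reg, scenario_schedule("constant32"), grid_step = 0.1)
  expect_identical(as.data.frame(a), as.data.frame(a2))
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_trajectory(a, p1); write_trajectory(a2, p2)
  expect_identical(readLines(p1), readLines(p2))
  unlink(c(p1, p2))
})

test_that("adaptive trajectories agree with a fixed-step Euler oracle", {
  reg <- mite_params_registry()
  for (scen in c("constant25", "constant32")) {
    sched <- scenario_schedule(scen)
    tr <- simulate_mites(reg, sched)
    oracle <- euler_oracle(reg, sched, h = 1e-3)
    final <- unlist(tr[nrow(tr), c("NI1", "NI2", "NS1", "NS2")])
    rel <- abs(final - oracle$final) / pmax(abs(oracle$final), 1e-9)
    expect_lt(max(rel), 0.005)
  }
})

test_that("raising suppressor reproduction never delays the takeover", {
  reg <- mite_params_registry()
  days <- vapply(c(14, 15, 15.798, 17), function(rS) {
    reg$suppressor$`32C`$r <- rS
    crossover_day(simulate_mites(reg, scenario_schedule("constant32")))
  }, numeric(1))
  expect_true(all(diff(days) <= 0))
})

test_that("persistence and the run summary report the season's outcome", {
  reg <- mite_params_registry()
  tr <- simulate_mites(reg, scenario_schedule("constant32"))
  s <- summarize_trajectory(tr)
  expect_true(s$suppressor_persists)
  expect_equal(s$suppressor_final, tr$NS_total[nrow(tr)])
  expect_true(s$peak_inducer_day < s$crossover_day)  # inducers peak early, then lose
  # threshold is a pure reporting rule: changing it flips flags, not densities
  expect_false(persistence(tr, threshold = s$inducer_final + 1)[["inducer"]])
  expect_true(persistence(tr, threshold = s$inducer_final / 2)[["inducer"]])
})
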