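test_that("daily female survival handles no-death, all-death and mixed leaflets", {
  expect_equal(female_survival_per_day(leaflet_counts(14, 0, 0)), 1)
  expect_equal(female_survival_per_day(leaflet_counts(0, 14, 0)), 0.5)
  expect_equal(female_survival_per_day(leaflet_counts(10, 4, 0)), 6 / 7)
  # survival is exactly 1 iff no female died (2-day assay)
  for (d in 0:5) {
    s <- female_survival_per_day(leaflet_counts(10, d, 0))
    expect_identical(s == 1, d == 0)
  }
  expect_error(leaflet_counts(0, 0, 0), "empty leaflet")
  expect_error(leaflet_counts(10, 0, 0, assay_days = 0.5), "assay_days")
})

test_that("per-capita fecundity and damage use the half-exposure convention for dead females", {
  expect_equal(eggs_per_alive_female_per_day(leaflet_counts(14, 0, 0)), 0)
  expect_equal(eggs_per_alive_female_per_day(leaflet_counts(14, 0, 140)), 5)
  expect_equal(eggs_per_alive_female_per_day(leaflet_counts(10, 4, 60)), 2.5)
  expect_equal(damage_per_alive_female(leaflet_counts(10, 8, 0, damage_area = 30)),
               30 / 14)
  expect_equal(damage_per_alive_female(leaflet_counts(14, 0, 0, damage_area = 14)), 1)
  expect_equal(damage_per_alive_female(leaflet_counts(10, 8, 0, damage_area = 0)), 0)
  expect_error(damage_per_alive_female(leaflet_counts(10, 8, 0)), "missing")
})

test_that("fecundity and damage metrics are homogeneous in their numerators", {
  base <- leaflet_counts(9, 3, 57, damage_area = 12.5)
  doubled <- leaflet_counts(9, 3, 114, damage_area = 25)
  expect_identical(eggs_per_alive_female_per_day(doubled),
                   2 * eggs_per_alive_female_per_day(base))
  expect_identical(damage_per_alive_female(doubled),
                   2 * damage_per_alive_female(base))
})

test_that("pixel areas convert to mm^2 through the mite-length calibration", {
  cal <- damage_calibration(mite_length_px = 50)
  expect_equal(px_to_mm2(50^2, cal), 0.16)
  expect_equal(px_to_mm2(2500, cal), 0.16)
  expect_equal(px_to_mm2(0, cal), 0)
  expect_error(damage_calibration(0), "positive")
})

test_that("delta-Ct normalisation and per-gene scaling behave as documented", {
  expect_equal(normalized_expression(21.5, 21.5), 1)
  expect_equal(normalized_expression(20, 21), 2)
  expect_equal(normalized_expression(23.32, 20), 0.1001, tolerance = 1e-3)
  expect_error(normalized_expression(20, 21, efficiency_base = 1), "base")

  vals <- c(1.5, 2.5, 3.5, 4.5)           # group means {2, 4}
  grp <- c("a", "a", "b", "b")
  sc <- scale_to_lowest_group_mean(vals, rep("g1", 4), grp)
  expect_equal(as.vector(tapply(sc, grp, mean)), c(1, 2))

  vals2 <- c(0.4, 0.6, 1.0, 2.0, 4.0, 6.0) # group means {0.5, 1.5, 5}
  grp2 <- rep(c("a", "b", "c"), each = 2)
  sc2 <- scale_to_lowest_group_mean(vals2, rep("g1", 6), grp2)
  expect_equal(as.vector(tapply(sc2, grp2, mean)), c(1, 3, 10))
  # the minimum-mean group has scaled mean exactly 1
  expect_identical(min(as.vector(tapply(sc2, grp2, mean))), 1)
  # idempotent: rescaling scaled values changes nothing
  expect_equal(scale_to_lowest_group_mean(sc2, rep("g1", 6), grp2), sc2)
  expect_error(scale_to_lowest_group_mean(c(0, 0, 1), rep("g", 3),
                                          c("a", "a", "b")),
               "not positive")
})

test_that("table-wise metrics match a row-by-row scalar oracle to machine precision", {
  spec <- generator_spec(n_leaflets = 60, seed = 7)
  df <- generate_leaflets(spec)
  df$damage_area[c(3, 17)] <- NA  # unphotographed leaflets are tolerated
  got <- compute_leaflet_metrics(df)
  want <- metrics_by_row_oracle(df)
  expect_equal(got$survival_per_day, want$survival, tolerance = 0)
  expect_equal(got$eggs_per_female_day, want$eggs, tolerance = 0)
  expect_equal(got$damage_per_female, want$damage, tolerance = 0)
})

test_that("leaflet tables round-trip through CSV with computed columns appended", {
  df <- generate_leaflets(generator_spec(n_leaflets = 12, seed = 3))
  out <- compute_leaflet_metrics(df)
  path <- tempfile(fileext = ".csv")
  write_leaflets(out, path)
  back <- read_leaflets(path)
  expect_equal(names(back), names(out))
  expect_equal(back$survival_per_day, out$survival_per_day, tolerance = 1e-12)
  unlink(path)
})
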