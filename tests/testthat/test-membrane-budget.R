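# Membrane budget arithmetic against the published worked numbers.

test_that("sphere areas reproduce the rounded per-vesicle constants", {
  expect_equal(sphere_area(29.3, "sig2"), 2700)
  expect_equal(sphere_area(37, "sig2"), 4300)
  expect_equal(sphere_area(46, "sig2"), 6600)
  expect_equal(sphere_area(2), 4 * pi, tolerance = 1e-12)
  # scaling law and monotonicity (unrounded)
  d <- c(20, 29.3, 35, 46, 60)
  expect_equal(sphere_area(2 * d), 4 * sphere_area(d), tolerance = 1e-12)
  expect_true(all(diff(sphere_area(d)) > 0))
  expect_error(sphere_area(0), "> 0")
})

test_that("exocytosed area covers the released-vesicle range", {
  exo <- exocytosed_area(22, 6, 7, 2700, area_rounding = "nearest_thousand")
  expect_equal(exo$vesicles_low, 132)
  expect_equal(exo$vesicles_high, 154)
  expect_equal(exo$vesicles_mean, 143)
  expect_equal(exo$area_mean, 386000)
  exo0 <- exocytosed_area(22, 0, 0)
  expect_equal(exo0$area_mean, 0)
})

test_that("departure correction inflates observed counts to totals", {
  d <- correct_for_departure(14, 0.47)
  expect_equal(d$total, 26)
  expect_equal(d$departed, 12)
  d2 <- correct_for_departure(25, 0.50)
  expect_equal(d2$total, 50)
  expect_equal(d2$departed, 25)
  expect_equal(correct_for_departure(10, 0)$total, 10)
  expect_error(correct_for_departure(10, 1), "departure_fraction")
})

test_that("dense-projection recovery splits 70/30 with truncation", {
  r <- dp_recovered_area(26)
  expect_equal(r$n_small, 18)
  expect_equal(r$n_large, 8)
  expect_equal(r$area, 130200)
  r2 <- dp_recovered_area(50)
  expect_equal(r2$n_small, 35)
  expect_equal(r2$n_large, 15)
  expect_equal(r2$area, 249500)
  expect_equal(dp_recovered_area(0)$area, 0)
})

test_that("joint and split dense-projection areas differ only by truncation", {
  p <- budget_params()
  for (a in c(5, 13, 26)) {
    for (b in c(3, 11, 24)) {
      joint <- dp_recovered_area(a + b, p)$area
      split <- dp_recovered_area(a, p)$area + dp_recovered_area(b, p)$area
      # truncating the 70% class separately can shift at most one vesicle
      # between the two diameter classes
      expect_lte(abs(joint - split),
                 p$dp_large_area - p$dp_small_area + 1e-9)
    }
  }
})

test_that("adherens-junction recovery supports both area conventions", {
  expect_equal(aj_recovered_area(29, area_mode = "stated_constant"), 174000)
  expect_equal(aj_recovered_area(24, area_mode = "exact_formula",
                                 rounding = "sig2"), 140000)
  # the stated constant is itself a rounding of the exact sphere area
  expect_equal(signif(sphere_area(43.2), 2), 5900)
  expect_equal(aj_recovered_area(0), 0)
})

test_that("the two worked budgets reproduce the published totals", {
  b3 <- worked_budget(300)
  expect_equal(b3$exo_low, 356000)
  expect_equal(b3$exo_high, 416000)
  expect_equal(b3$exo_mean, 386000)
  expect_equal(b3$endo_dp, 130200)
  expect_equal(b3$endo_aj, 174000)
  expect_equal(b3$endo_total, 304200)
  expect_equal(b3$sv_equivalents, 112)

  b1 <- worked_budget(1000)
  expect_equal(b1$endo_dp, 249500)
  expect_equal(b1$endo_aj, 140000)
  expect_equal(b1$endo_total, 389500)
  expect_equal(round(b1$endo_total, -4), 390000)
  expect_equal(b1$sv_equivalents, 144)
})

test_that("budget conservation invariants hold across random inputs", {
  set.seed(17)
  p <- budget_params()
  for (i in 1:50) {
    b <- budget_report(
      timepoint = 300, n_synapses = sample(5:30, 1),
      release_low = sample(0:6, 1), release_high = sample(6:9, 1),
      dp_observed = sample(0:30, 1),
      departure_fraction = runif(1, 0, 0.9),
      aj_n_structures = sample(0:40, 1)
    )
    expect_equal(b$endo_total, b$endo_dp + b$endo_aj)
    expect_lte(b$sv_equivalents * p$sv_area, b$endo_total)
    expect_lt(b$endo_total, (b$sv_equivalents + 1) * p$sv_area)
  }
})

test_that("with no departure and one structure class the budget is count * sphere area", {
  p <- budget_params(dp_small_fraction = 0, dp_large_area = sphere_area(46))
  b <- budget_report(300, n_synapses = 10, release_low = 0, release_high = 0,
                     dp_observed = 7, departure_fraction = 0,
                     aj_n_structures = 0, params = p)
  expect_equal(b$endo_total, 7 * sphere_area(46), tolerance = 1e-12)
  b0 <- budget_report(300, 10, 0, 0, 0, 0, 0)
  expect_equal(b0$endo_total, 0)
  expect_equal(b0$sv_equivalents, 0)
})

test_that("tidy method flattens a budget to one row", {
  td <- tidy(worked_budget(300))
  expect_equal(nrow(td), 1)
  expect_equal(td$sv_equivalents, 112)
})
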