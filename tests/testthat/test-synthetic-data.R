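# Generator contracts: determinism, calibration, geometric consistency
# with the classifier, freeze-timing arithmetic.

test_that("the same seed reproduces a dataset exactly", {
  a <- generate_condition(300, 5, seed = 91)
  b <- generate_condition(300, 5, seed = 91)
  expect_identical(a$vesicles, b$vesicles)
  expect_identical(a$pits, b$pits)
  expect_identical(a$profiles$membrane, b$profiles$membrane)
  c <- generate_condition(300, 5, seed = 92)
  expect_false(identical(a$vesicles, c$vesicles))
})

test_that("generator output always validates cleanly", {
  for (tp in list(NA, 20, 300, 10000)) {
    ds <- generate_condition(tp, 8, seed = 100 + (tp %||% 7) %% 50)
    expect_equal(nrow(validate_dataset(ds)), 0)
  }
})

test_that("reconstructions have 4-6 contiguous profiles sharing one label", {
  dss <- generate_dataset(c(NA, 50), c(6, 6), seed = 111)
  expect_named(dss, c("unstimulated", "stim_50ms"))
  for (ds in dss) {
    per_syn <- dplyr::count(ds$profiles, synapse_id)
    expect_true(all(per_syn$n >= 4 & per_syn$n <= 6))
    for (sid in per_syn$synapse_id) {
      idx <- sort(ds$profiles$section_index[ds$profiles$synapse_id == sid])
      expect_equal(idx, seq_along(idx))
    }
  }
  empty <- generate_condition(50, 0, seed = 1)
  expect_equal(nrow(empty$synapses), 0)
  expect_equal(nrow(validate_dataset(empty)), 0)
})

test_that("pool means are calibrated to the configured time course", {
  ds <- generate_condition(NA, 50, seed = 121)
  pc <- pool_counts_per_profile(ds)
  n <- nrow(pc)
  # docked includes the constant perisynaptic pool (0.5)
  expect_lt(abs(mean(pc$docked) - 3.0), 3 * sd(pc$docked) / sqrt(n))
  expect_lt(abs(mean(pc$tethered) - 3.1), 3 * sd(pc$tethered) / sqrt(n))
  expect_lt(abs(mean(pc$cytoplasmic) - 25), 3 * sd(pc$cytoplasmic) / sqrt(n))
})

test_that("paired-pulse series follow the double-exponential with noise", {
  pp0 <- generate_paired_pulse(params = generator_params(pp_noise_sd = 0),
                               seed = 131)
  expect_equal(pp0$y, pp0$y_true)
  # full recovery in the long-interval limit
  far <- generate_paired_pulse(intervals = c(100, 50000, 100000),
                               params = generator_params(pp_noise_sd = 0))
  expect_equal(far$y[3], 1, tolerance = 1e-6)
  # determinism
  expect_identical(generate_paired_pulse(seed = 132),
                   generate_paired_pulse(seed = 132))
})

test_that("diameter samples respect truncation and the configured mean", {
  d <- generate_diameters(400, seed = 141)
  expect_true(all(d > 35))
  # oracle: mean of the >35-truncated 0.7/0.3 mixture of N(38,2) and
  # N(46,2), computed by numeric integration
  f <- function(x) {
    0.7 * dnorm(x, 38, 2) + 0.3 * dnorm(x, 46, 2)
  }
  z <- integrate(f, 35, Inf)$value
  m_true <- integrate(function(x) x * f(x), 35, Inf)$value / z
  expect_lt(abs(mean(d) - m_true), 3 * sd(d) / sqrt(length(d)))
  expect_gt(m_true, 39); expect_lt(m_true, 43)
  # zero-spread component collapses to its mean
  d0 <- generate_diameters(20, means = 40, sds = 1e-12, seed = 1,
                           large_vesicles = FALSE)
  expect_equal(d0, rep(40, 20), tolerance = 1e-6)
  expect_identical(generate_diameters(50, seed = 7),
                   generate_diameters(50, seed = 7))
})

test_that("per-synapse pit counts track the junction decay curve", {
  pc <- generate_pit_counts(seed = 151)
  expect_equal(pc$t, c(300, 1000, 3000, 10000))
  expect_equal(pc$n, c(20, 23, 19, 26))
  # the 1 s mean of the default curve reproduces the counted 20/23
  expect_equal(aj_pit_mean_at(1000), 1.45 * exp(-700 / 1400), tolerance = 1e-9)
  expect_equal(aj_pit_mean_at(1000), 20 / 23, tolerance = 0.02)
})

test_that("freeze-timing arithmetic reproduces the trigger offsets", {
  p0 <- freeze_timing_params(delay_jitter_halfwidth = 0)
  ft <- simulate_freeze_timing(1000, p0)
  expect_equal(ft$trigger_offset, 822)
  expect_equal(ft$realized, 1000)
  ft100 <- simulate_freeze_timing(100, p0)
  expect_equal(ft100$trigger_offset, -78)  # freezer starts before the light
  expect_equal(ft100$realized, 100)
})

test_that("jittered freeze intervals span commanded +/- 20 ms uniformly", {
  ft <- simulate_freeze_timing(100, seed = 161, n = 4000)
  expect_true(all(ft$realized >= 80 - 1e-9 & ft$realized <= 120 + 1e-9))
  ks <- suppressWarnings(ks.test(ft$realized, "punif", 80, 120))
  expect_gt(ks$p.value, 0.01)
  # very short commanded intervals can freeze before the light
  ft_short <- simulate_freeze_timing(10, seed = 162, n = 200)
  expect_true(any(ft_short$light_after_freeze))
})

test_that("generated docked vesicles sit within contact tolerance", {
  ds <- generate_condition(1000, 10, seed = 171)
  v <- ds$vesicles
  prof <- ds$profiles
  key <- paste(prof$synapse_id, prof$section_index)
  for (i in which(v$true_pool %in% c("docked", "tethered", "pool30"))) {
    mem <- prof$membrane[[match(paste(v$synapse_id[i], v$section_index[i]),
                                key)]]
    ed <- edge_distance_to_membrane(v$x[i], v$y[i], v$diameter[i], mem)
    if (v$true_pool[i] == "docked") {
      expect_lte(ed, 2)
    } else {
      expect_gt(ed, 2)
      expect_lte(ed, 30)
    }
  }
})
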