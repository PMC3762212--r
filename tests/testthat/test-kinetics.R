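# Kinetic fits: exact recovery on noiseless model data, degenerate-input
# flags, nesting, unit invariance, bootstrap coverage.

freeze_timepoints <- c(20, 50, 100, 300, 1000, 3000, 10000)

test_that("noiseless recovery curve is fitted to optimizer precision", {
  y <- 2.6 - (2.6 - 1) * exp(-freeze_timepoints / 2400)
  f <- fit_exponential_recovery(tibble::tibble(t = freeze_timepoints, y = y))
  expect_true(f$converged)
  expect_equal(f$tau, 2400, tolerance = 1e-6)
  expect_equal(unname(f$coefficients["y_inf"]), 2.6, tolerance = 1e-6)
  expect_equal(unname(f$coefficients["y_0"]), 1, tolerance = 1e-6)
  expect_gt(f$r_squared, 0.999999)
})

test_that("constant series is flagged unidentifiable, not an error", {
  f <- fit_exponential_recovery(tibble::tibble(t = 1:6 * 100, y = rep(2, 6)))
  expect_false(f$converged)
  expect_true("unidentifiable_constant_series" %in% f$flags)
  expect_error(fit_exponential_recovery(tibble::tibble(t = 1:3, y = 1:3)),
               "at least 4")
  expect_error(fit_exponential_recovery(tibble::tibble(t = c(1, 1, 2, 3),
                                                       y = 1:4)),
               "strictly increasing")
})

test_that("noiseless decay from the peak recovers tau exactly", {
  t <- c(300, 1000, 3000, 10000)
  y <- 0.1 + (1.45 - 0.1) * exp(-(t - 300) / 1400)
  f <- fit_exponential_decay(tibble::tibble(t = t, y = y))
  expect_true(f$converged)
  expect_equal(f$tau, 1400, tolerance = 1e-6)
  expect_equal(unname(f$coefficients["t_peak"]), 300)
})

test_that("an increasing series gets the negative-rate flag", {
  f <- fit_exponential_decay(tibble::tibble(t = c(300, 1000, 3000, 10000),
                                            y = c(0.2, 0.5, 0.9, 1.2)))
  expect_true("negative_rate" %in% f$flags)
})

test_that("noiseless double-exponential ratios are recovered to 1e-4", {
  t <- c(50, 100, 200, 300, 500, 1000, 2000, 3000, 5000, 10000, 15000)
  y <- 1 - 0.3 * exp(-t / 100) - 0.5 * exp(-t / 2200)
  f <- fit_double_exponential_recovery(tibble::tibble(t = t, y = y))
  expect_true(f$converged)
  expect_equal(f$tau[1], 100, tolerance = 1e-4)
  expect_equal(f$tau[2], 2200, tolerance = 1e-4)
  expect_equal(unname(f$coefficients["A_f"]), 0.3, tolerance = 1e-4)
  expect_equal(unname(f$coefficients["A_s"]), 0.5, tolerance = 1e-4)
  # components come back ordered fast < slow
  expect_lt(f$tau[1], f$tau[2])
})

test_that("single-exponential truth collapses one amplitude of the double fit", {
  t <- c(50, 100, 200, 300, 500, 1000, 2000, 3000, 5000, 10000, 15000)
  y <- 1 - 0.6 * exp(-t / 2000)
  f <- fit_double_exponential_recovery(tibble::tibble(t = t, y = y))
  expect_true(f$converged)
  amps <- sort(c(f$coefficients["A_f"], f$coefficients["A_s"]))
  expect_lt(amps[1], 1e-3)
  expect_equal(unname(amps[2]), 0.6, tolerance = 1e-3)
})

test_that("double-exponential RSS never exceeds the nested single fit", {
  set.seed(202)
  t <- c(50, 100, 200, 300, 500, 1000, 2000, 3000, 5000, 10000, 15000)
  for (i in 1:20) {
    y <- 1 - 0.3 * exp(-t / 100) - 0.5 * exp(-t / 2200) + rnorm(length(t), 0, 0.05)
    d <- tibble::tibble(t = t, y = y)
    double <- fit_double_exponential_recovery(d)
    single <- synmorph:::fit_ratio_recovery(d, k = 1)
    expect_lte(double$rss, single$rss + 1e-9)
  }
})

test_that("fits are invariant to time-unit rescaling up to parameter scale", {
  set.seed(33)
  t <- freeze_timepoints
  y <- 2.5 - 1.6 * exp(-t / 2400) + rnorm(length(t), 0, 0.05)
  f_ms <- fit_exponential_recovery(tibble::tibble(t = t, y = y))
  f_s <- fit_exponential_recovery(tibble::tibble(t = t / 1000, y = y))
  expect_equal(f_ms$tau / 1000, f_s$tau, tolerance = 1e-4)
  expect_equal(f_ms$r_squared, f_s$r_squared, tolerance = 1e-6)
})

test_that("SEM weights steer the fit toward precise points", {
  t <- c(100, 300, 1000, 3000, 10000)
  y_true <- 2.5 - 1.6 * exp(-t / 2400)
  y <- y_true; y[2] <- y[2] + 0.8  # one wild, imprecise point
  sem <- c(0.01, 1, 0.01, 0.01, 0.01)
  fw <- fit_exponential_recovery(tibble::tibble(t = t, y = y, sem = sem))
  fu <- fit_exponential_recovery(tibble::tibble(t = t, y = y))
  expect_lt(abs(fw$tau - 2400), abs(fu$tau - 2400))
})

test_that("bootstrap intervals cover the true tau at realistic noise", {
  set.seed(404)
  t <- freeze_timepoints
  covered <- 0; total <- 30
  for (i in seq_len(total)) {
    y <- 2.5 - 1.6 * exp(-t / 2400) + rnorm(length(t), 0, 0.08)
    f <- fit_exponential_recovery(tibble::tibble(t = t, y = y))
    ci <- bootstrap_ci(f, n_boot = 199, seed = i)
    tau_ci <- ci[ci$term == "tau", ]
    if (tau_ci$conf_low <= 2400 && 2400 <= tau_ci$conf_high) {
      covered <- covered + 1
    }
  }
  expect_gte(covered / total, 0.8)
})

test_that("tidy and glance expose coefficients and fit quality", {
  y <- 2.6 - 1.6 * exp(-freeze_timepoints / 2400)
  f <- fit_exponential_recovery(tibble::tibble(t = freeze_timepoints, y = y))
  td <- tidy(f)
  expect_setequal(td$term, c("y_0", "y_inf", "tau"))
  gl <- glance(f)
  expect_true(gl$converged)
  expect_equal(gl$n, length(freeze_timepoints))
})
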