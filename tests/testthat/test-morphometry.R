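# Distances, binning, normalization, aggregation, group comparison.

test_that("3D dense-projection distance follows the Pythagorean rule", {
  ds <- fixture_dataset(n_sections = 4)
  # same section, 40 nm to the side of the dense-projection edge
  v1 <- make_vesicle("v1", x = 120, y = 30, section = 1)
  # three sections away, directly above: z = 3 * 33 = 99
  v2 <- make_vesicle("v2", x = 0, y = 30, section = 4)
  # one section away, 44 nm in plane: 3-4-5 triangle scaled by 11
  v3 <- make_vesicle("v3", x = 124, y = 0, section = 2)
  ds$vesicles <- dplyr::bind_rows(v1, v2, v3)
  d <- distance_to_dense_projection_3d(ds)
  expect_equal(d$dp_distance_3d[1], 40, tolerance = 1e-9)
  expect_equal(d$dp_distance_3d[2], 99, tolerance = 1e-9)
  expect_equal(d$dp_distance_3d[3], 55, tolerance = 1e-9)
  # 3D distance is never below the in-plane distance
  expect_gte(d$dp_distance_3d[2], 0)
})

test_that("touching vesicles are flagged only in dense-projection sections", {
  ds <- fixture_dataset(n_sections = 2)
  v1 <- make_vesicle("v1", x = 95, y = 30, diameter = 30, section = 1)
  v2 <- make_vesicle("v2", x = 95, y = 30, diameter = 30, section = 2)
  ds$vesicles <- dplyr::bind_rows(v1, v2)
  d <- distance_to_dense_projection_3d(ds)
  expect_true(d$touching[1])   # edge within 2 nm of the polygon edge
  expect_false(d$touching[2])  # no dense projection in its own section
})

test_that("distance binning reserves bin 0 for touching structures", {
  h <- bin_by_distance(c(0, 0, 32.999, 33, 66, 100),
                       touching = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_s3_class(h, "syn_histogram")
  expect_equal(h$count[h$bin == 0], 1)  # only the touching structure
  expect_equal(h$count[h$bin == 1], 2)  # 0 (not touching) and 32.999
  expect_equal(h$count[h$bin == 2], 1)  # 33.0 falls in the next half-open bin
  expect_equal(h$count[h$bin == 3], 1)  # 66 in [66, 99)
  expect_equal(h$count[h$bin == 4], 1)  # 100 in [99, 132)
  # conservation: bins sum to the input count
  expect_equal(sum(h$count), 6)
  expect_error(bin_by_distance(1, bin_width = 0), "bin_width")
  expect_error(bin_by_distance(-1), ">= 0")
})

test_that("histogram conservation holds on generated data", {
  ds <- generate_condition(50, 15, seed = 61)
  d <- distance_to_dense_projection_3d(ds)
  h <- bin_by_distance(d$dp_distance_3d, d$touching)
  expect_equal(sum(h$count), nrow(ds$vesicles))
})

test_that("normalization rescales linearly to the reference", {
  refs <- normalization_refs()
  expect_equal(normalize_count(5, 670, refs, "active_zone_length"), 5)
  expect_equal(normalize_count(5, 335, refs, "active_zone_length"), 10)
  expect_equal(normalize_count(0, 123, refs, "active_zone_length"), 0)
  expect_equal(normalize_count(3, 60700, refs, "profile_area"), 3)
  # linear in count, inverse-linear in the observed measure
  expect_equal(normalize_count(10, 500, refs, "active_zone_length"),
               2 * normalize_count(5, 500, refs, "active_zone_length"))
  expect_equal(normalize_count(5, 250, refs, "active_zone_length"),
               2 * normalize_count(5, 500, refs, "active_zone_length"))
  expect_error(normalize_count(5, 0, refs), "> 0")
})

test_that("active-zone length sums both flanks outside the dense projection", {
  mem <- straight_membrane()
  dp <- rect_dp(hw = 80)
  aj <- cbind(c(-300, 300), c(0, 0))
  expect_equal(active_zone_length(mem, dp, aj), 2 * (300 - 80),
               tolerance = 1e-6)
})

test_that("single-profile aggregation gives mean with zero SEM", {
  v <- dplyr::bind_rows(
    make_vesicle("v1", x = 120, y = 15, diameter = 30),
    make_vesicle("v2", x = 150, y = 15, diameter = 30),
    make_vesicle("v3", x = -200, y = 15, diameter = 30)
  )
  ds <- fixture_dataset(vesicles = v)
  agg <- aggregate_pools(ds)
  docked <- dplyr::filter(agg$per_profile, pool == "docked", zone == "all")
  expect_equal(docked$mean_raw, 3)
  expect_equal(docked$sem_raw, 0)
  ds_empty <- fixture_dataset()
  ds_empty$profiles <- ds_empty$profiles[0, ]
  expect_error(aggregate_pools(ds_empty), "empty")
})

test_that("aggregates are invariant to profile and synapse order", {
  ds <- generate_condition(300, 8, seed = 71)
  agg1 <- aggregate_pools(ds)
  ds2 <- ds
  set.seed(1)
  ds2$vesicles <- ds2$vesicles[sample(nrow(ds2$vesicles)), ]
  ds2$synapses <- ds2$synapses[rev(seq_len(nrow(ds2$synapses))), ]
  agg2 <- aggregate_pools(ds2)
  expect_equal(agg1$per_profile, agg2$per_profile)
  expect_equal(agg1$per_synapse, agg2$per_synapse)
})

test_that("generated pool means land near their configured values", {
  # unstimulated docked pool
  ds <- generate_condition(NA, 40, seed = 81)
  pc <- pool_counts_per_profile(ds)
  # docked here includes the perisynaptic docked vesicles (mean 0.5)
  sem <- sd(pc$docked) / sqrt(nrow(pc))
  expect_lt(abs(mean(pc$docked) - 3.0), 3 * sem + 1e-9)
  # 50 ms: docked depleted
  ds50 <- generate_condition(50, 40, seed = 82)
  pc50 <- pool_counts_per_profile(ds50)
  sem50 <- sd(pc50$docked) / sqrt(nrow(pc50))
  expect_lt(abs(mean(pc50$docked) -
                  (docked_mean_at(50) + 0.5)), 3 * sem50 + 1e-9)
})

test_that("Mann-Whitney exact p comes from full enumeration", {
  r <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact_enumeration")
  expect_equal(r$statistic, 0)
  # identical samples: no separation
  r2 <- compare_groups(c(2, 4, 9), c(2, 4, 9))
  expect_gte(r2$p_value, 0.99)
  expect_error(compare_groups(numeric(0), 1:3), "non-empty")
})

test_that("exact p matches wilcox.test enumeration for all sizes up to 8x8", {
  set.seed(123)
  for (n1 in c(2, 4, 6, 8)) {
    for (n2 in c(2, 5, 8)) {
      a <- rnorm(n1)
      b <- rnorm(n2, 0.8)
      ours <- compare_groups(a, b)
      ref <- wilcox.test(a, b, exact = TRUE, correct = FALSE)
      expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12,
                   label = sprintf("p at n1=%d n2=%d", n1, n2))
      expect_equal(ours$statistic, unname(ref$statistic))
    }
  }
})

test_that("large samples use the tie-corrected normal approximation", {
  set.seed(5)
  a <- round(rnorm(30, 0, 2))  # heavy ties
  b <- round(rnorm(25, 1, 2))
  ours <- compare_groups(a, b)
  expect_equal(ours$method, "normal_approximation")
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-9)
})

test_that("Bonferroni threshold matches the study's seven-comparison level", {
  r <- compare_groups(c(1, 2, 3), c(4, 5, 6), n_comparisons = 7)
  expect_equal(r$adjusted_alpha, 0.05 / 7)
  expect_equal(round(r$adjusted_alpha, 3), 0.007)
})
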