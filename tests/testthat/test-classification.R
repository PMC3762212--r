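# Pool, zone, site and pit classification rules.

test_that("edge distance subtracts the vesicle radius and clamps at zero", {
  mem <- straight_membrane()
  expect_equal(edge_distance_to_membrane(0, 50, 30, mem), 35)
  expect_equal(edge_distance_to_membrane(0, 15, 30, mem), 0)
  # overlapping circle clamps rather than going negative
  expect_equal(edge_distance_to_membrane(0, 5, 30, mem), 0)
  expect_error(edge_distance_to_membrane(0, 5, 30, mem[1, , drop = FALSE]),
               "membrane")
})

test_that("edge distance matches a brute-force point-sampled minimum", {
  set.seed(99)
  # wiggly membrane, densely resampled as the oracle
  xs <- seq(-500, 500, length.out = 40)
  ys <- 30 * sin(xs / 150) + rnorm(40, 0, 5)
  mem <- cbind(xs, ys)
  dense <- cbind(
    approx(xs, ys, xout = seq(-500, 500, by = 0.05))$x,
    approx(xs, ys, xout = seq(-500, 500, by = 0.05))$y
  )
  for (i in 1:50) {
    px <- runif(1, -450, 450); py <- runif(1, 10, 200); d <- runif(1, 20, 40)
    got <- edge_distance_to_membrane(px, py, d, mem)
    oracle <- max(min(sqrt((dense[, 1] - px)^2 + (dense[, 2] - py)^2)) - d / 2, 0)
    expect_lt(abs(got - oracle), 0.1)
  }
})

test_that("pool and kind rules implement the category system", {
  mem <- straight_membrane()
  p <- classification_params()
  # docked synaptic vesicle: clear core, in contact
  lab <- classify_vesicle(0, 29.3 / 2, 29.3, "clear", FALSE, mem, p)
  expect_equal(lab$pool, "docked")
  expect_equal(lab$kind, "synaptic_vesicle")
  # tethered: within 30 nm with a tether
  lab <- classify_vesicle(0, 15 + 20, 30, "clear", TRUE, mem, p)
  expect_equal(lab$pool, "tethered")
  # same geometry, no tether: 30-nm pool
  lab <- classify_vesicle(0, 15 + 20, 30, "clear", FALSE, mem, p)
  expect_equal(lab$pool, "pool30")
  # large clear vesicle deep in the cytoplasm
  lab <- classify_vesicle(0, 220, 40, "clear", FALSE, mem, p)
  expect_equal(lab$pool, "cytoplasmic")
  expect_equal(lab$kind, "large_vesicle")
  # the 35 nm threshold is exclusive
  lab <- classify_vesicle(0, 220, 35, "clear", FALSE, mem, p)
  expect_equal(lab$kind, "synaptic_vesicle")
  # dense core trumps size
  lab <- classify_vesicle(0, 220, 40, "dense", FALSE, mem, p)
  expect_equal(lab$kind, "dense_core")
})

test_that("zone assignment splits the membrane at the adherens junctions", {
  mem <- straight_membrane()
  dp <- rect_dp()
  aj <- cbind(c(-300, 300), c(0, 0))
  # midway between dense projection and junction
  expect_equal(assign_zone(190, 40, mem, dp, aj)$zone, "active_zone")
  # beyond the junction mark
  expect_equal(assign_zone(350, 40, mem, dp, aj)$zone, "perisynaptic")
  # exactly at the junction: boundary assigned inward
  expect_equal(assign_zone(300, 40, mem, dp, aj)$zone, "active_zone")
  # missing junction on one side: bounded by the membrane end and flagged
  one_aj <- cbind(-300, 0)
  z <- assign_zone(400, 40, mem, dp, one_aj)
  expect_equal(z$zone, "active_zone")
  expect_true(z$zone_flagged)
})

test_that("site assignment applies radii with dense-projection precedence", {
  ds <- fixture_dataset()
  prof <- ds$profiles
  # 60 nm above the dense-projection top edge
  s <- assign_site(0, 120, 1, prof)
  expect_equal(s$site, "dense_projection")
  # near a junction, far from the dense projection
  s <- assign_site(290, 30, 1, prof)
  expect_equal(s$site, "adherens_junction")
  # far from both
  s <- assign_site(170, 200, 1, prof)
  expect_equal(s$site, "interior")
  # inside both radii: dense projection wins and the case is flagged
  ds2 <- fixture_dataset(aj_dist = 120)
  s <- assign_site(110, 20, 1, ds2$profiles)
  expect_equal(s$site, "dense_projection")
  expect_true(s$site_ambiguous)
})

test_that("site distances use the 3D section offset", {
  ds <- fixture_dataset(n_sections = 4)
  # over the dense-projection footprint, 3 sections away: z = 3 * 33 = 99
  s <- assign_site(0, 30, 4, ds$profiles)
  expect_equal(s$dp_distance, 99, tolerance = 1e-6)
  expect_equal(s$site, "dense_projection")
  # 4 sections away would exceed the 100 nm radius
  ds5 <- fixture_dataset(n_sections = 5)
  s5 <- assign_site(0, 30, 5, ds5$profiles)
  expect_equal(s5$dp_distance, 132, tolerance = 1e-6)
  expect_false(s5$site == "dense_projection")
})

test_that("pit classification separates exocytic from endocytic shapes", {
  # synaptic-vesicle-sized pit away from the junction
  expect_equal(classify_pit(28.4, 14, "dense_projection"), "exocytic")
  expect_equal(classify_pit(28.4, 14, "interior"), "exocytic")
  # wide shallow pit at the junction
  expect_equal(classify_pit(44, 10, "adherens_junction"), "shallow_endocytic")
  # deep pit: depth at least half the width
  expect_equal(classify_pit(44, 40, "adherens_junction"), "deep_endocytic")
  expect_equal(classify_pit(44, 22, "adherens_junction"), "deep_endocytic")
  # small pit at the junction is endocytic, not exocytic
  expect_equal(classify_pit(30, 10, "adherens_junction"), "shallow_endocytic")
})

test_that("lowering the tether threshold never promotes cytoplasmic vesicles", {
  mem <- straight_membrane()
  set.seed(7)
  for (i in 1:200) {
    ed_target <- runif(1, 0, 80)
    d <- runif(1, 20, 40)
    y <- ed_target + d / 2
    for (thr in c(30, 20, 10, 5)) {
      p <- classification_params(tether_max_distance = thr)
      pool_wide <- classify_vesicle(0, y, d, "clear", TRUE, mem,
                                    classification_params())$pool
      pool_narrow <- classify_vesicle(0, y, d, "clear", TRUE, mem, p)$pool
      if (pool_wide == "cytoplasmic") {
        expect_equal(pool_narrow, "cytoplasmic")
      }
    }
  }
})

test_that("every vesicle gets exactly one pool label (partition)", {
  ds <- generate_condition(300, 10, seed = 31)
  lab <- classify_dataset(ds)
  expect_equal(nrow(lab$vesicles), nrow(ds$vesicles))
  expect_true(all(lab$vesicles$pool %in%
                    c("docked", "tethered", "pool30", "cytoplasmic")))
})

test_that("classifier labels agree with generator truth on every structure", {
  for (tp in list(NA, 50, 300, 3000)) {
    ds <- generate_condition(tp, 12, seed = 40 + (tp %||% 0) %% 37)
    lab <- classify_dataset(ds)
    v <- lab$vesicles
    expect_equal(v$pool, v$true_pool)
    expect_equal(v$zone, v$true_zone)
    expect_equal(v$kind, v$true_kind)
    has_site <- !is.na(v$true_site)
    expect_equal(v$site[has_site], v$true_site[has_site])
    p <- lab$pits
    if (nrow(p) > 0) {
      expect_equal(p$pit_class, p$true_class)
      has_site <- !is.na(p$true_site)
      expect_equal(p$site[has_site], p$true_site[has_site])
    }
  }
})
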