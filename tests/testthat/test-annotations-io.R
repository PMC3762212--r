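# Data model, validation, and round-trip IO.

test_that("a minimal one-profile dataset builds and validates cleanly", {
  ds <- fixture_dataset()
  expect_s3_class(ds, "syn_dataset")
  expect_equal(nrow(ds$synapses), 1)
  expect_equal(nrow(ds$profiles), 1)
  expect_equal(nrow(ds$vesicles), 0)
  expect_equal(nrow(validate_dataset(ds)), 0)
})

test_that("validation reports each broken invariant as a named issue", {
  bad_ves <- make_vesicle(diameter = 0)
  ds <- fixture_dataset(vesicles = bad_ves)
  iss <- validate_dataset(ds)
  expect_equal(nrow(iss), 1)
  expect_equal(iss$field, "diameter")
  expect_equal(iss$rule, "positive")

  # adherens junction far off the membrane
  ds2 <- fixture_dataset()
  ds2$profiles$adherens_junctions[[1]] <- cbind(c(-300, 300), c(500, 0))
  iss2 <- validate_dataset(ds2)
  expect_equal(nrow(iss2), 1)
  expect_equal(iss2$field, "adherens_junctions")
  expect_equal(iss2$rule, "on_membrane")

  # non-contiguous sections
  ds3 <- fixture_dataset(n_sections = 3)
  ds3$profiles$section_index <- c(1L, 2L, 4L)
  iss3 <- validate_dataset(ds3)
  expect_true(any(iss3$rule == "contiguous"))

  # stimulated without an interval
  ds4 <- fixture_dataset(stimulated = TRUE, interval = NA_real_)
  iss4 <- validate_dataset(ds4)
  expect_true(any(iss4$rule == "positive_when_stimulated"))
})

test_that("JSON round-trip is the identity and rewriting is byte-stable", {
  skip_if_not_installed("withr")
  for (seed in c(11, 12, 13)) {
    ds <- generate_condition(300, 3, seed = seed)
    f1 <- withr::local_tempfile(fileext = ".json")
    f2 <- withr::local_tempfile(fileext = ".json")
    write_dataset(ds, f1)
    back <- read_dataset(f1)
    expect_equal(back$condition, ds$condition)
    expect_equal(back$synapses, ds$synapses)
    expect_equal(back$profiles$profile_area, ds$profiles$profile_area)
    expect_equal(back$profiles$membrane, ds$profiles$membrane,
                 tolerance = 1e-12)
    # the nested format orders structures by profile; compare sorted by id
    expect_equal(
      dplyr::arrange(dplyr::select(back$vesicles,
                                   dplyr::all_of(names(ds$vesicles))),
                     vesicle_id),
      dplyr::arrange(ds$vesicles, vesicle_id), tolerance = 1e-12
    )
    expect_equal(
      dplyr::arrange(dplyr::select(back$pits, dplyr::all_of(names(ds$pits))),
                     pit_id),
      dplyr::arrange(ds$pits, pit_id), tolerance = 1e-12
    )
    # canonical serialization: write(read(f)) reproduces f byte for byte
    write_dataset(back, f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
  }
})

test_that("CSV and JSON forms of the same dataset read back equal", {
  skip_if_not_installed("withr")
  ds <- generate_condition(1000, 3, seed = 21)
  fj <- withr::local_tempfile(fileext = ".json")
  fc <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, fj)
  write_dataset(ds, fc)
  from_json <- read_dataset(fj)
  from_csv <- read_dataset(fc)
  expect_equal(from_csv$condition, from_json$condition)
  expect_equal(from_csv$synapses, from_json$synapses)
  expect_equal(from_csv$profiles$membrane, from_json$profiles$membrane,
               tolerance = 1e-9)
  expect_equal(dplyr::arrange(from_csv$vesicles, vesicle_id),
               dplyr::arrange(from_json$vesicles, vesicle_id),
               tolerance = 1e-9)
  expect_equal(dplyr::arrange(from_csv$pits, pit_id),
               dplyr::arrange(from_json$pits, pit_id), tolerance = 1e-9)
})

test_that("an empty dataset survives a round trip", {
  skip_if_not_installed("withr")
  ds <- generate_condition(NA, 0, seed = 1)
  f <- withr::local_tempfile(fileext = ".json")
  write_dataset(ds, f)
  back <- read_dataset(f)
  expect_equal(nrow(back$synapses), 0)
  expect_equal(nrow(back$vesicles), 0)
})

test_that("missing required fields produce schema errors naming the field", {
  skip_if_not_installed("withr")
  f <- withr::local_tempfile(fileext = ".json")
  obj <- list(condition_label = "x", stimulated = FALSE,
              synapses = list(list(id = "s1", profiles = list(
                list(section_index = 1, membrane = list(c(0, 0), c(1, 0)))
              ))))
  jsonlite::write_json(obj, f, auto_unbox = TRUE)
  expect_error(read_dataset(f), "profile_area")
})

test_that("unknown vesicle fields are preserved through both formats", {
  skip_if_not_installed("withr")
  ds <- generate_condition(50, 2, seed = 5)
  expect_true(all(c("true_pool", "true_zone") %in% names(ds$vesicles)))
  for (ext in c(".json", ".csv")) {
    f <- withr::local_tempfile(fileext = ext)
    write_dataset(ds, f)
    back <- dplyr::arrange(read_dataset(f)$vesicles, vesicle_id)
    orig <- dplyr::arrange(ds$vesicles, vesicle_id)
    expect_equal(back$true_pool, orig$true_pool)
  }
})
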