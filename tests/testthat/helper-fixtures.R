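# Small hand-built fixtures used across test files.

# A straight horizontal membrane at y = 0 spanning [-x_half, x_half].
straight_membrane <- function(x_half = 600, n = 7) {
  cbind(seq(-x_half, x_half, length.out = n), rep(0, n))
}

# A rectangular dense-projection polygon sitting on the membrane,
# spanning x in [-hw, hw], height ht.
rect_dp <- function(hw = 80, ht = 60) {
  cbind(c(-hw, -hw, hw, hw), c(0, ht, ht, 0))
}

# One-profile synapse with configurable structures; membrane straight at
# y = 0, dense projection at the center, adherens junctions at +/- aj_dist.
fixture_dataset <- function(vesicles = NULL, pits = NULL, aj_dist = 300,
                            n_sections = 1, profile_area = 60700,
                            stimulated = FALSE, interval = NA_real_) {
  mem <- straight_membrane()
  profiles <- dplyr::bind_rows(lapply(seq_len(n_sections), function(i) {
    tibble::tibble(
      synapse_id = "s1", section_index = i, profile_area = profile_area,
      membrane = list(mem),
      dense_projection = list(if (i == 1) rect_dp() else NULL),
      adherens_junctions = list(cbind(c(-aj_dist, aj_dist), c(0, 0)))
    )
  }))
  syn_dataset(
    condition_label = "fixture", stimulated = stimulated,
    interval_to_freeze = interval,
    synapses = tibble::tibble(synapse_id = "s1", section_thickness = 33),
    profiles = profiles,
    vesicles = vesicles %||% synmorph:::empty_vesicles(),
    pits = pits %||% synmorph:::empty_pits()
  )
}

make_vesicle <- function(id = "v1", x = 0, y = 100, diameter = 30,
                         core = "clear", tether = FALSE, section = 1L) {
  tibble::tibble(
    synapse_id = "s1", section_index = as.integer(section), vesicle_id = id,
    x = x, y = y, diameter = diameter, core = core, tether_observed = tether
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
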