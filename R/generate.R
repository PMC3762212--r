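# Synthetic annotation generator. Emulates flash-and-freeze serial-section
# datasets with the statistical structure the analysis assumes: per-profile
# Poisson pool counts following the published time-course means, vesicle and
# pit geometry consistent with the classifier's thresholds (every generated
# docked vesicle really is within contact tolerance, and so on), truncated-
# normal diameter distributions, and the freeze-timing arithmetic. Generated
# vesicles and pits carry `true_*` truth columns for recovery tests.

#' Generator parameters
#'
#' Defaults encode the study conditions: docked pool 2.5 per profile
#' unstimulated falling to 0.9 after a stimulus and refilling with tau
#' 2400 ms; tethered pool 3.1 / 2.6 with the same refill constant;
#' synaptic-vesicle diameters around 29.3 nm; large-vesicle diameters a
#' 38 / 46 nm mixture (truncated above 35 nm); adherens junctions 250-350 nm
#' from the dense projection with an asymmetric long side up to ~1000 nm;
#' profile areas around 60,700 nm^2; junction pits peaking at 1.45 per
#' synapse at 300 ms (29 pits / 20 synapses) and decaying with tau 1400 ms;
#' dense-projection large vesicles peaking at 50 ms with knots anchored to
#' the counted 14/20 at 300 ms and 25/23 at 1 s; paired-pulse recovery taus
#' 100 and 2200 ms with amplitudes 0.3 / 0.5 and measurement noise sd 0.05.
#' Counts are Poisson around the timepoint means; between-knot time courses
#' are piecewise-linear in log-time (qualitative shapes, not published
#' numbers).
#'
#' @param ... Named overrides of any default listed above (see the function
#'   definition for the full field list).
#' @return List of class `syn_gen_params`.
#' @export
generator_params <- function(...) {
  p <- list(
    # pool means (per profile) and refill kinetics
    docked_unstim = 2.5, docked_stim = 0.9, docked_tau = 2400,
    tethered_unstim = 3.1, tethered_stim = 2.6, tethered_tau = 2400,
    pool30_mean = 1.5, cytoplasmic_mean = 25, dense_core_mean = 0.3,
    docked_peri_mean = 0.5,
    # diameters (nm); sv sd anchored to the printed 28.4 +/- 0.3 SEM over
    # 17 fusing vesicles (per-vesicle sd ~1.2); large-vesicle weights to the
    # printed 70/30 class split
    sv_diameter_mean = 29.3, sv_diameter_sd = 1.3, diameter_floor = 15,
    lv_means = c(38, 46), lv_sds = c(2, 2), lv_weights = c(0.7, 0.3),
    lv_threshold = 35,
    aj_lv_diameter_mean = 44, aj_lv_diameter_sd = 2,
    dcv_diameter_mean = 40, dcv_diameter_sd = 3,
    exo_pit_width_mean = 28.4, exo_pit_width_sd = 1.3,
    aj_pit_width_mean = 43.2, aj_pit_width_sd = 2,
    # endocytic time courses (per synapse)
    dp_lv_knots = list(t = c(20, 30, 50, 100, 300, 1000, 3000, 10000),
                       mean = c(0.7, 1.0, 1.5, 1.0, 0.70, 1.087, 0.3, 0.15)),
    dp_lv_baseline = 0.1,
    interior_lv_knots = list(t = c(20, 50, 100, 300, 1000, 3000, 10000),
                             mean = c(0.2, 0.5, 1.0, 1.0, 0.8, 0.2, 0.3)),
    interior_lv_baseline = 0.05,
    aj_pit_peak = 1.45, aj_pit_peak_time = 300, aj_pit_tau = 1400,
    aj_pit_baseline = 0.02, aj_pit_rise_start = 50,
    aj_lv_knots = list(t = c(100, 300, 1000, 3000, 10000),
                       mean = c(0.05, 0.1, 0.174, 0.6, 0.1)),
    aj_lv_baseline = 0.02,
    deep_pit_knots = list(t = c(300, 1000, 3000),
                          mean = c(0, 0.15, 0)),
    exo_pit_knots = list(t = c(10, 20, 30, 50),
                         mean = c(0, 0.34, 0.2, 0)),
    # geometry (nm)
    aj_short_range = c(250, 350), aj_long_range = c(350, 1000),
    membrane_overhang = 150, membrane_points = 12, membrane_noise_sd = 1.5,
    dp_halfwidth = 80, dp_height = 70,
    profile_area_mean = 60700, profile_area_sd = 8000,
    profiles_per_synapse = 4:6, section_thickness = 33,
    contact_tolerance = 2,
    # paired pulse
    pp_tau_fast = 100, pp_tau_slow = 2200,
    pp_amp_fast = 0.3, pp_amp_slow = 0.5, pp_noise_sd = 0.05
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0) {
    stop("unknown generator parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p[names(dots)] <- dots
  structure(p, class = "syn_gen_params")
}

# Piecewise-linear interpolation of a time-course in log10(t) between knots.
interp_knots <- function(t_ms, knots, baseline) {
  if (is.na(t_ms)) return(baseline)
  lt <- log10(t_ms + 10)
  stats::approx(log10(knots$t + 10), knots$mean, xout = lt, rule = 2)$y
}

#' Mean docked / tethered count per profile at a timepoint
#'
#' The docked pool follows `y_inf - (y_inf - y_0) * exp(-t / tau)` with
#' `y_0 = 0.9`, `y_inf = 2.5`, `tau = 2400 ms`; `t = NA` means unstimulated
#' (the asymptote). The tethered pool follows the same form with its own
#' levels.
#'
#' @param t_ms Timepoint in ms, or `NA` for unstimulated.
#' @param params [generator_params()].
#' @return Mean count per profile.
#' @export
docked_mean_at <- function(t_ms, params = generator_params()) {
  if (is.na(t_ms)) return(params$docked_unstim)
  params$docked_unstim - (params$docked_unstim - params$docked_stim) *
    exp(-t_ms / params$docked_tau)
}

#' @rdname docked_mean_at
#' @export
tethered_mean_at <- function(t_ms, params = generator_params()) {
  if (is.na(t_ms)) return(params$tethered_unstim)
  params$tethered_unstim - (params$tethered_unstim - params$tethered_stim) *
    exp(-t_ms / params$tethered_tau)
}

#' Mean adherens-junction shallow-pit count per synapse at a timepoint
#'
#' Near zero before `aj_pit_rise_start`, rising to `aj_pit_peak` at
#' `aj_pit_peak_time` (300 ms), then decaying as
#' `peak * exp(-(t - t_peak) / tau)` with tau 1400 ms — which puts the 1 s
#' mean at 0.88 per synapse, matching the counted 20 pits over 23 synapses.
#'
#' @inheritParams docked_mean_at
#' @export
aj_pit_mean_at <- function(t_ms, params = generator_params()) {
  if (is.na(t_ms) || t_ms < params$aj_pit_rise_start) return(params$aj_pit_baseline)
  if (t_ms <= params$aj_pit_peak_time) {
    fr <- (log10(t_ms) - log10(params$aj_pit_rise_start)) /
      (log10(params$aj_pit_peak_time) - log10(params$aj_pit_rise_start))
    return(params$aj_pit_baseline +
             fr * (params$aj_pit_peak - params$aj_pit_baseline))
  }
  params$aj_pit_peak * exp(-(t_ms - params$aj_pit_peak_time) / params$aj_pit_tau)
}

lv_mixture_draw <- function(n, params, floor_at) {
  if (n == 0) return(numeric(0))
  comp <- sample.int(length(params$lv_means), n, replace = TRUE,
                     prob = params$lv_weights)
  rtrunc_norm(n, params$lv_means[comp], params$lv_sds[comp],
              lo = floor_at, hi = Inf)
}

# Build one profile's membrane polyline, dense-projection polygon and
# adherens-junction marks. Returns a list with geometry and an interpolator
# for membrane height.
build_profile_geometry <- function(dist_left, dist_right, params) {
  x0 <- -(dist_left + params$membrane_overhang)
  x1 <- dist_right + params$membrane_overhang
  xs <- seq(x0, x1, length.out = params$membrane_points)
  ys <- stats::rnorm(params$membrane_points, 0, params$membrane_noise_sd)
  mem <- unname(cbind(xs, ys))
  memb_y <- function(x) stats::approx(xs, ys, xout = x, rule = 2)$y
  yb <- memb_y(0)
  hw <- params$dp_halfwidth; ht <- params$dp_height
  dp <- cbind(c(-hw, -hw, -hw / 2, hw / 2, hw, hw),
              yb + c(0, ht * 0.7, ht, ht, ht * 0.7, 0))
  aj <- cbind(c(-dist_left, dist_right),
              memb_y(c(-dist_left, dist_right)))
  list(membrane = mem, dp = dp, aj = aj, memb_y = memb_y,
       dist_left = dist_left, dist_right = dist_right,
       dp_top = yb + ht)
}

# Column collector for vesicle rows (avoids per-row tibble construction).
ves_collector <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env
}

push_vesicles <- function(coll, synapse_id, section_index, x, y, diameter,
                          core, tether, pool, zone, site, kind) {
  n <- length(x)
  if (n == 0) return(invisible())
  coll$rows[[length(coll$rows) + 1]] <- list(
    synapse_id = rep(synapse_id, n), section_index = rep(section_index, n),
    x = x, y = y, diameter = diameter, core = rep_len(core, n),
    tether_observed = rep_len(tether, n), true_pool = rep_len(pool, n),
    true_zone = rep_len(zone, n), true_site = rep_len(site, n),
    true_kind = rep_len(kind, n)
  )
}

collapse_vesicles <- function(coll) {
  if (length(coll$rows) == 0) return(NULL)
  cols <- names(coll$rows[[1]])
  out <- lapply(cols, function(cn) unlist(lapply(coll$rows, `[[`, cn),
                                          use.names = FALSE))
  names(out) <- cols
  tibble::as_tibble(out)
}

#' Generate one condition dataset at a timepoint
#'
#' Builds `n_synapses` reconstructions of 4-6 contiguous profiles. Each
#' profile gets a membrane polyline with mild curvature noise, a
#' dense-projection polygon and two adherens-junction marks at asymmetric
#' sampled distances; vesicles and pits are placed with Poisson counts
#' around the timepoint means at positions geometrically consistent with
#' their intended class (docked vesicle edges within contact tolerance,
#' tethered within 30 nm, junction pits within 50 nm 3D of a mark, ...).
#' Truth labels are recorded in `true_*` columns.
#'
#' @param timepoint ms after stimulation, or `NA` for unstimulated.
#' @param n_synapses Number of reconstructions.
#' @param params [generator_params()].
#' @param seed Integer seed; the same seed and parameters reproduce the
#'   dataset exactly. `NULL` continues the session RNG stream.
#' @param condition_label Label; derived from the timepoint by default.
#' @return A [syn_dataset].
#' @export
generate_condition <- function(timepoint, n_synapses,
                               params = generator_params(), seed = NULL,
                               condition_label = NULL) {
  with_local_seed(seed, {
    generate_condition_impl(timepoint, n_synapses, params, condition_label)
  })
}

generate_condition_impl <- function(timepoint, n_synapses, params,
                                    condition_label = NULL) {
  t_ms <- if (is.null(timepoint) || is.na(timepoint)) NA_real_ else timepoint
  label <- condition_label %||%
    if (is.na(t_ms)) "unstimulated" else sprintf("stim_%gms", t_ms)

  mu_docked <- docked_mean_at(t_ms, params)
  mu_teth <- tethered_mean_at(t_ms, params)
  mu_dp_lv <- interp_knots(t_ms, params$dp_lv_knots, params$dp_lv_baseline)
  mu_int_lv <- interp_knots(t_ms, params$interior_lv_knots,
                            params$interior_lv_baseline)
  mu_aj_pit <- aj_pit_mean_at(t_ms, params)
  mu_aj_lv <- interp_knots(t_ms, params$aj_lv_knots, params$aj_lv_baseline)
  mu_deep <- interp_knots(t_ms, params$deep_pit_knots, 0)
  mu_exo <- interp_knots(t_ms, params$exo_pit_knots, 0)

  syn_ids <- sprintf("syn%03d", seq_len(n_synapses))
  prof_sid <- list(); prof_idx <- list(); prof_area <- list()
  prof_mem <- list(); prof_dp <- list(); prof_aj <- list()
  coll <- ves_collector()
  pit_rows <- list()
  pid <- 0L
  tol <- params$contact_tolerance

  for (s in seq_len(n_synapses)) {
    sid <- syn_ids[s]
    k <- sample(params$profiles_per_synapse, 1)
    long_right <- stats::runif(1) < 0.5
    d_short <- stats::runif(1, params$aj_short_range[1], params$aj_short_range[2])
    d_long <- stats::runif(1, params$aj_long_range[1], params$aj_long_range[2])
    dist_right0 <- if (long_right) d_long else d_short
    dist_left0 <- if (long_right) d_short else d_long

    geoms <- vector("list", k)
    for (pi in seq_len(k)) {
      dl <- dist_left0 + stats::runif(1, -10, 10)
      dr <- dist_right0 + stats::runif(1, -10, 10)
      g <- build_profile_geometry(dl, dr, params)
      geoms[[pi]] <- g
      np <- length(prof_sid) + 1L
      prof_sid[[np]] <- sid; prof_idx[[np]] <- pi
      prof_area[[np]] <- rtrunc_norm(1, params$profile_area_mean,
                                     params$profile_area_sd, lo = 30000)
      prof_mem[[np]] <- g$membrane; prof_dp[[np]] <- g$dp
      prof_aj[[np]] <- g$aj

      # ---- membrane-proximal synaptic-vesicle pools (per profile) ----
      place_sv <- function(n, delta_lo, delta_hi, x_lo, x_hi, pool, zone,
                           tether) {
        if (n == 0) return(invisible())
        side <- sample(c(-1, 1), n, replace = TRUE)
        span_hi <- ifelse(side < 0, g$dist_left, g$dist_right) - x_hi
        xv <- side * stats::runif(n, x_lo, pmax(span_hi, x_lo + 1))
        dv <- rtrunc_norm(n, params$sv_diameter_mean, params$sv_diameter_sd,
                          lo = params$diameter_floor, hi = params$lv_threshold)
        delta <- stats::runif(n, delta_lo, delta_hi)
        yv <- g$memb_y(xv) + dv / 2 + delta
        push_vesicles(coll, sid, pi, xv, yv, dv, "clear", tether, pool, zone,
                      NA_character_, "synaptic_vesicle")
      }
      n_dock <- stats::rpois(1, mu_docked)
      place_sv(n_dock, 0, 0.8 * tol, 100, 20, "docked", "active_zone", FALSE)
      n_teth <- stats::rpois(1, mu_teth)
      place_sv(n_teth, tol + 1, 28, 100, 20, "tethered", "active_zone", TRUE)
      n_p30 <- stats::rpois(1, params$pool30_mean)
      place_sv(n_p30, tol + 1, 28, 100, 20, "pool30", "active_zone", FALSE)

      # perisynaptic docked vesicles (not released by the stimulus)
      n_peri <- stats::rpois(1, params$docked_peri_mean)
      if (n_peri > 0) {
        side <- sample(c(-1, 1), n_peri, replace = TRUE)
        base <- ifelse(side < 0, g$dist_left, g$dist_right)
        xv <- side * (base + stats::runif(n_peri, 20, params$membrane_overhang - 20))
        dv <- rtrunc_norm(n_peri, params$sv_diameter_mean, params$sv_diameter_sd,
                          lo = params$diameter_floor, hi = params$lv_threshold)
        yv <- g$memb_y(xv) + dv / 2 + stats::runif(n_peri, 0, 0.8 * tol)
        push_vesicles(coll, sid, pi, xv, yv, dv, "clear", FALSE, "docked",
                      "perisynaptic", NA_character_, "synaptic_vesicle")
      }

      # cytoplasmic synaptic vesicles and dense-core vesicles
      place_cyto <- function(n, dmean, dsd, core, kind) {
        if (n == 0) return(invisible())
        side <- sample(c(-1, 1), n, replace = TRUE)
        span <- ifelse(side < 0, g$dist_left, g$dist_right) - 30
        xv <- side * stats::runif(n, 100, pmax(span, 101))
        dv <- rtrunc_norm(n, dmean, dsd, lo = params$diameter_floor,
                          hi = if (core == "clear") params$lv_threshold else Inf)
        yv <- g$memb_y(xv) + dv / 2 + stats::runif(n, 35, 160)
        push_vesicles(coll, sid, pi, xv, yv, dv, core, FALSE, "cytoplasmic",
                      "active_zone", NA_character_, kind)
      }
      place_cyto(stats::rpois(1, params$cytoplasmic_mean),
                 params$sv_diameter_mean, params$sv_diameter_sd, "clear",
                 "synaptic_vesicle")
      place_cyto(stats::rpois(1, params$dense_core_mean),
                 params$dcv_diameter_mean, params$dcv_diameter_sd, "dense",
                 "dense_core")

      # exocytic pits (fusion intermediates; early timepoints only)
      n_exo <- stats::rpois(1, mu_exo)
      for (e in seq_len(n_exo)) {
        side <- sample(c(-1, 1), 1)
        span <- (if (side < 0) g$dist_left else g$dist_right) - 70
        xc <- side * stats::runif(1, 120, max(span, 121))
        w <- rtrunc_norm(1, params$exo_pit_width_mean, params$exo_pit_width_sd,
                         lo = params$diameter_floor, hi = params$lv_threshold)
        dep <- stats::runif(1, 0.4, 0.8) * w
        pid <- pid + 1L
        pit_rows[[length(pit_rows) + 1]] <- list(
          synapse_id = sid, section_index = pi, pit_id = sprintf("pit%05d", pid),
          apex_x = xc, apex_y = g$memb_y(xc) - dep,
          mouth_left_x = xc - w / 2, mouth_left_y = g$memb_y(xc - w / 2),
          mouth_right_x = xc + w / 2, mouth_right_y = g$memb_y(xc + w / 2),
          width = w, depth = dep,
          true_class = "exocytic", true_site = NA_character_
        )
      }
    }

    # ---- per-synapse endocytic structures, assigned to random sections ----
    place_lv <- function(n, where) {
      for (e in seq_len(n)) {
        pi <- sample.int(k, 1)
        g <- geoms[[pi]]
        if (where == "dp") {
          d <- lv_mixture_draw(1, params, params$lv_threshold)
          xv <- stats::runif(1, -params$dp_halfwidth / 2, params$dp_halfwidth / 2)
          yv <- g$dp_top + stats::runif(1, 10, 80)
          push_vesicles(coll, sid, pi, xv, yv, d, "clear", FALSE, "cytoplasmic",
                        "active_zone", "dense_projection", "large_vesicle")
        } else if (where == "aj") {
          # diameter and offsets bounded so the center stays within the
          # 50 nm junction radius while the edge stays > contact tolerance
          d <- rtrunc_norm(1, params$aj_lv_diameter_mean,
                           params$aj_lv_diameter_sd,
                           lo = params$lv_threshold, hi = 56)
          side <- sample(c(-1, 1), 1)
          base <- if (side < 0) g$dist_left else g$dist_right
          xv <- side * (base - stats::runif(1, 3, 10))
          yv <- g$memb_y(xv) + d / 2 + stats::runif(1, 5, 15)
          push_vesicles(coll, sid, pi, xv, yv, d, "clear", FALSE, "pool30",
                        "active_zone", "adherens_junction", "large_vesicle")
        } else {
          d <- lv_mixture_draw(1, params, params$lv_threshold)
          side <- sample(c(-1, 1), 1)
          span <- (if (side < 0) g$dist_left else g$dist_right) - 60
          xv <- side * stats::runif(1, 210, max(span, 211))
          yv <- g$memb_y(xv) + stats::runif(1, 120, 250)
          push_vesicles(coll, sid, pi, xv, yv, d, "clear", FALSE, "cytoplasmic",
                        "active_zone", "interior", "large_vesicle")
        }
      }
    }
    place_lv(stats::rpois(1, mu_dp_lv), "dp")
    place_lv(stats::rpois(1, mu_aj_lv), "aj")
    place_lv(stats::rpois(1, mu_int_lv), "interior")

    place_aj_pit <- function(n, deep) {
      for (e in seq_len(n)) {
        pi <- sample.int(k, 1)
        g <- geoms[[pi]]
        side <- sample(c(-1, 1), 1)
        base <- if (side < 0) g$dist_left else g$dist_right
        xc <- side * (base - stats::runif(1, 0, 25))
        # width capped so even a deep pit's apex stays within 50 nm 3D of
        # the junction mark
        w <- rtrunc_norm(1, params$aj_pit_width_mean, params$aj_pit_width_sd,
                         lo = params$lv_threshold, hi = 52)
        dep <- if (deep) stats::runif(1, 0.55, 0.8) * w
               else stats::runif(1, 0.25, 0.45) * w
        pid <<- pid + 1L
        pit_rows[[length(pit_rows) + 1]] <<- list(
          synapse_id = sid, section_index = pi, pit_id = sprintf("pit%05d", pid),
          apex_x = xc, apex_y = g$memb_y(xc) - dep,
          mouth_left_x = xc - w / 2, mouth_left_y = g$memb_y(xc - w / 2),
          mouth_right_x = xc + w / 2, mouth_right_y = g$memb_y(xc + w / 2),
          width = w, depth = dep,
          true_class = if (deep) "deep_endocytic" else "shallow_endocytic",
          true_site = "adherens_junction"
        )
      }
    }
    place_aj_pit(stats::rpois(1, mu_aj_pit), deep = FALSE)
    place_aj_pit(stats::rpois(1, mu_deep), deep = TRUE)
  }

  vesicles <- collapse_vesicles(coll)
  if (!is.null(vesicles) && nrow(vesicles) > 0) {
    vesicles$vesicle_id <- sprintf("ves%06d", seq_len(nrow(vesicles)))
    vesicles <- vesicles[, c("synapse_id", "section_index", "vesicle_id",
                             "x", "y", "diameter", "core", "tether_observed",
                             "true_pool", "true_zone", "true_site",
                             "true_kind")]
  } else {
    vesicles <- empty_vesicles()
  }
  pits <- if (length(pit_rows) > 0) {
    cols <- names(pit_rows[[1]])
    out <- lapply(cols, function(cn) {
      unlist(lapply(pit_rows, `[[`, cn), use.names = FALSE)
    })
    names(out) <- cols
    tibble::as_tibble(out)
  } else empty_pits()

  syn_dataset(
    condition_label = label,
    stimulated = !is.na(t_ms),
    interval_to_freeze = t_ms,
    synapses = tibble::tibble(
      synapse_id = syn_ids,
      section_thickness = rep(params$section_thickness, n_synapses)
    ),
    profiles = tibble::tibble(
      synapse_id = unlist(prof_sid, use.names = FALSE) %||% character(),
      section_index = as.integer(unlist(prof_idx, use.names = FALSE) %||% integer()),
      profile_area = unlist(prof_area, use.names = FALSE) %||% numeric(),
      membrane = prof_mem, dense_projection = prof_dp,
      adherens_junctions = prof_aj
    ),
    vesicles = vesicles, pits = pits
  )
}

#' Generate one annotated profile
#'
#' Convenience wrapper around [generate_condition()] producing a single
#' one-profile synapse.
#'
#' @inheritParams generate_condition
#' @return A [syn_dataset] with one synapse of one profile.
#' @export
generate_profile <- function(timepoint, params = generator_params(),
                             seed = NULL) {
  p <- params
  p$profiles_per_synapse <- 1L
  generate_condition(timepoint, 1, p, seed)
}

#' Generate datasets for a series of freeze timepoints
#'
#' One [syn_dataset] per timepoint, sharing a single seeded RNG stream so
#' the whole series is reproducible from one seed.
#'
#' @param timepoints Vector of ms values; `NA` means unstimulated.
#' @param n_synapses Synapses per timepoint (recycled).
#' @param params [generator_params()].
#' @param seed Integer seed.
#' @return Named list of [syn_dataset] objects.
#' @export
generate_dataset <- function(timepoints, n_synapses,
                             params = generator_params(), seed = NULL) {
  n_synapses <- rep_len(n_synapses, length(timepoints))
  with_local_seed(seed, {
    out <- purrr::map2(timepoints, n_synapses, function(tp, ns) {
      generate_condition_impl(tp, ns, params)
    })
    names(out) <- purrr::map_chr(out, ~ .x$condition$condition_label)
    out
  })
}

#' Generate a paired-pulse recovery series
#'
#' Ratios `1 - A_f exp(-t/tau_f) - A_s exp(-t/tau_s)` at the given
#' inter-pulse intervals plus Gaussian measurement noise.
#'
#' @param intervals Inter-pulse intervals in ms, positive increasing.
#'   Default: a log-spaced grid spanning 50 ms to 15 s.
#' @param params [generator_params()].
#' @param seed Integer seed.
#' @return Tibble with columns `t` (ms), `y` (ratio) and `y_true`
#'   (noise-free curve).
#' @export
generate_paired_pulse <- function(intervals = c(50, 100, 200, 300, 500, 1000,
                                                2000, 3000, 5000, 10000, 15000),
                                  params = generator_params(), seed = NULL) {
  stopifnot(all(intervals > 0), all(diff(intervals) > 0))
  with_local_seed(seed, {
    y_true <- 1 - params$pp_amp_fast * exp(-intervals / params$pp_tau_fast) -
      params$pp_amp_slow * exp(-intervals / params$pp_tau_slow)
    tibble::tibble(
      t = intervals,
      y = y_true + stats::rnorm(length(intervals), 0, params$pp_noise_sd),
      y_true = y_true
    )
  })
}

#' Generate a vesicle diameter sample from a Gaussian mixture
#'
#' @param n Number of diameters.
#' @param means,sds,weights Component parameters (nm). Defaults mirror the
#'   large-vesicle emulation: peaks 38 and 46 nm, sd 2 nm, 70/30 weights.
#' @param seed Integer seed.
#' @param large_vesicles Truncate below at the large-vesicle threshold
#'   (> 35 nm) instead of the biological floor (15 nm).
#' @return Numeric vector of diameters (nm).
#' @export
generate_diameters <- function(n, means = c(38, 46), sds = c(2, 2),
                               weights = c(0.7, 0.3), seed = NULL,
                               large_vesicles = TRUE) {
  stopifnot(n >= 1, length(means) == length(sds))
  if (missing(weights) && length(means) != 2) {
    weights <- rep(1 / length(means), length(means))
  }
  weights <- weights %||% rep(1 / length(means), length(means))
  stopifnot(length(weights) == length(means))
  with_local_seed(seed, {
    comp <- sample.int(length(means), n, replace = TRUE, prob = weights)
    rtrunc_norm(n, means[comp], sds[comp],
                lo = if (large_vesicles) 35 else 15, hi = Inf)
  })
}

#' Generate per-synapse junction pit counts along the resolution decay
#'
#' Poisson counts per synapse around the adherens-junction pit time course
#' ([aj_pit_mean_at()]), from the 300 ms peak onward — the input for the
#' pit-resolution decay fit.
#'
#' @param timepoints ms, starting at the peak. Default `c(300, 1000, 3000,
#'   10000)` with the study's per-timepoint synapse counts.
#' @param n_synapses Synapses per timepoint (recycled).
#' @param params [generator_params()].
#' @param seed Integer seed.
#' @return Tibble with one row per timepoint: `t`, `n`, `mean_count`, `sem`.
#' @export
generate_pit_counts <- function(timepoints = c(300, 1000, 3000, 10000),
                                n_synapses = c(20, 23, 19, 26),
                                params = generator_params(), seed = NULL) {
  n_synapses <- rep_len(n_synapses, length(timepoints))
  with_local_seed(seed, {
    purrr::map2_dfr(timepoints, n_synapses, function(tp, ns) {
      counts <- stats::rpois(ns, aj_pit_mean_at(tp, params))
      tibble::tibble(
        t = tp, n = ns, mean_count = mean(counts),
        sem = stats::sd(counts) / sqrt(ns)
      )
    })
  })
}

#' Freeze-timing parameters
#'
#' @param command_to_pressure_delay ms between the freezer start signal and
#'   the pressure rise (170).
#' @param delay_jitter_halfwidth Half-width of the uniform jitter on that
#'   delay (20 ms).
#' @param pressure_to_freeze ms between pressure application and freezing
#'   (8).
#' @return List of class `syn_freeze_params`.
#' @export
freeze_timing_params <- function(command_to_pressure_delay = 170,
                                 delay_jitter_halfwidth = 20,
                                 pressure_to_freeze = 8) {
  stopifnot(command_to_pressure_delay >= 0, delay_jitter_halfwidth >= 0,
            pressure_to_freeze >= 0)
  structure(list(command_to_pressure_delay = command_to_pressure_delay,
                 delay_jitter_halfwidth = delay_jitter_halfwidth,
                 pressure_to_freeze = pressure_to_freeze),
            class = "syn_freeze_params")
}

#' Simulate the stimulation-to-freeze interval
#'
#' The freezer is triggered `commanded_interval - (delay + pressure_to_freeze)`
#' ms after the light (178 ms lead with the defaults, so a commanded 1 s
#' interval triggers the freezer 822 ms after the light and a commanded
#' 100 ms interval triggers it 78 ms *before* the light). The realized
#' interval is then reconstructed post hoc from the actual delay, drawn
#' uniformly within the jitter half-width; negative realized intervals
#' (light after freezing) are flagged.
#'
#' @param commanded_interval Desired stimulation-to-freeze interval, ms (> 0).
#' @param params [freeze_timing_params()].
#' @param seed Integer seed.
#' @param n Number of simulated trials.
#' @return Tibble: `commanded`, `trigger_offset` (ms after the light; negative
#'   = before), `actual_delay`, `realized`, `light_after_freeze`.
#' @export
simulate_freeze_timing <- function(commanded_interval,
                                   params = freeze_timing_params(),
                                   seed = NULL, n = 1) {
  stopifnot(commanded_interval > 0)
  with_local_seed(seed, {
    nominal <- params$command_to_pressure_delay + params$pressure_to_freeze
    trigger <- commanded_interval - nominal
    actual <- stats::runif(n,
                           params$command_to_pressure_delay -
                             params$delay_jitter_halfwidth,
                           params$command_to_pressure_delay +
                             params$delay_jitter_halfwidth)
    realized <- trigger + actual + params$pressure_to_freeze
    tibble::tibble(
      commanded = commanded_interval, trigger_offset = trigger,
      actual_delay = actual, realized = realized,
      light_after_freeze = realized < 0
    )
  })
}
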