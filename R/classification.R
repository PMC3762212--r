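# Vesicle pool / zone / site classification.
#
# Pools: docked (edge in contact with the plasma membrane), tethered
# (within 30 nm with a visible tether), 30-nm pool (within 30 nm, no
# tether), cytoplasmic (everything else). Kinds: synaptic vesicle,
# dense-core vesicle, large vesicle (clear core, > 35 nm). Zones: active
# zone (membrane between the dense projection and the flanking adherens
# junctions) vs perisynaptic. Sites: dense projection (within 100 nm, 3D),
# adherens junction (within 50 nm, 3D), interior.

#' Classification thresholds
#'
#' @param contact_tolerance Edge distance (nm) at or below which a vesicle
#'   counts as in physical contact with the membrane, i.e. docked.
#'   Default 2 nm: annotated coordinates carry jitter, so contact is a
#'   tolerance, not exact zero.
#' @param tether_max_distance Maximum edge distance (nm) for the tethered /
#'   30-nm pools. Default 30.
#' @param large_vesicle_min_diameter Diameter (nm) above which a clear-core
#'   vesicle is a large vesicle. Strictly exclusive: exactly 35 nm is still
#'   a synaptic vesicle. Default 35.
#' @param dp_site_radius Radial 3D distance (nm) from the dense-projection
#'   edge within which a structure is dense-projection-associated.
#'   Default 100.
#' @param aj_site_radius Radial 3D distance (nm) from an adherens-junction
#'   mark within which a structure is junction-associated. Default 50.
#' @return A list of class `syn_class_params`.
#' @export
classification_params <- function(contact_tolerance = 2,
                                  tether_max_distance = 30,
                                  large_vesicle_min_diameter = 35,
                                  dp_site_radius = 100,
                                  aj_site_radius = 50) {
  stopifnot(contact_tolerance > 0, tether_max_distance > contact_tolerance,
            large_vesicle_min_diameter > 0, dp_site_radius > 0,
            aj_site_radius > 0)
  structure(
    list(contact_tolerance = contact_tolerance,
         tether_max_distance = tether_max_distance,
         large_vesicle_min_diameter = large_vesicle_min_diameter,
         dp_site_radius = dp_site_radius,
         aj_site_radius = aj_site_radius),
    class = "syn_class_params"
  )
}

#' Distance from a vesicle's outer edge to the plasma membrane
#'
#' Minimum distance from the circle of radius `diameter / 2` about the
#' vesicle center to the membrane polyline, clamped at 0 when the circle
#' overlaps the membrane trace.
#'
#' @param x,y Vesicle center coordinates (nm); vectors allowed.
#' @param diameter Vesicle diameter(s), nm.
#' @param membrane Two-column coordinate matrix of the membrane polyline.
#' @return Numeric vector of edge distances (nm, >= 0).
#' @export
edge_distance_to_membrane <- function(x, y, diameter, membrane) {
  if (is.null(membrane) || nrow(membrane) < 2) {
    stop("membrane polyline is empty", call. = FALSE)
  }
  d <- dist_to_polyline(x, y, membrane)$distance
  pmax(d - diameter / 2, 0)
}

vesicle_kind <- function(core, diameter, params) {
  dplyr::case_when(
    core == "dense" ~ "dense_core",
    diameter > params$large_vesicle_min_diameter ~ "large_vesicle",
    TRUE ~ "synaptic_vesicle"
  )
}

vesicle_pool <- function(edge_distance, tether_observed, params) {
  dplyr::case_when(
    edge_distance <= params$contact_tolerance ~ "docked",
    edge_distance <= params$tether_max_distance & tether_observed ~ "tethered",
    edge_distance <= params$tether_max_distance ~ "pool30",
    TRUE ~ "cytoplasmic"
  )
}

#' Classify a single vesicle into pool and kind
#'
#' @param x,y,diameter,core,tether_observed Vesicle annotation fields.
#' @param membrane Membrane polyline of the vesicle's profile.
#' @param params [classification_params()].
#' @return A one-row tibble with `pool`, `kind` and `edge_distance`.
#' @export
classify_vesicle <- function(x, y, diameter, core, tether_observed,
                             membrane, params = classification_params()) {
  ed <- edge_distance_to_membrane(x, y, diameter, membrane)
  tibble::tibble(
    pool = vesicle_pool(ed, tether_observed, params),
    kind = vesicle_kind(core, diameter, params),
    edge_distance = ed
  )
}

# Arc-length interval of the active zone on a profile's membrane:
# from the dense projection out to the flanking adherens-junction marks.
# Returns list(lo, hi, open_lo, open_hi) where open_* flags a side with no
# junction mark (zone bounded by the membrane end instead).
active_zone_interval <- function(membrane, dense_projection, adherens) {
  total <- polyline_length(membrane)
  dp_s <- if (!is.null(dense_projection) && nrow(dense_projection) > 0) {
    dist_to_polyline(dense_projection[, 1], dense_projection[, 2], membrane)$s
  } else total / 2
  dp_mid <- mean(range(dp_s))
  aj_s <- if (!is.null(adherens) && nrow(adherens) > 0) {
    dist_to_polyline(adherens[, 1], adherens[, 2], membrane)$s
  } else numeric(0)
  left <- aj_s[aj_s <= dp_mid]
  right <- aj_s[aj_s > dp_mid]
  list(
    lo = if (length(left)) max(left) else 0,
    hi = if (length(right)) min(right) else total,
    open_lo = length(left) == 0,
    open_hi = length(right) == 0
  )
}

#' Assign a vesicle to the active or perisynaptic zone
#'
#' The active zone is the membrane arc from the dense projection to the
#' flanking adherens-junction marks; a vesicle whose membrane foot-point
#' falls inside that arc (boundaries inclusive, assigned inward) is in the
#' active zone, otherwise perisynaptic. When a side has no junction mark the
#' zone is bounded by the membrane end and the result is flagged.
#'
#' @param x,y Vesicle center (nm); vectors allowed.
#' @param membrane Membrane polyline.
#' @param dense_projection Dense-projection polygon of this profile (or the
#'   nearest dense-projection-bearing profile in the reconstruction).
#' @param adherens Matrix of adherens-junction marks (0-2 rows).
#' @return Tibble with `zone` (`"active_zone"` / `"perisynaptic"`) and
#'   `zone_flagged` (`TRUE` when a junction mark was missing on one side).
#' @export
assign_zone <- function(x, y, membrane, dense_projection, adherens) {
  iv <- active_zone_interval(membrane, dense_projection, adherens)
  foot <- dist_to_polyline(x, y, membrane)$s
  tibble::tibble(
    zone = ifelse(foot >= iv$lo & foot <= iv$hi, "active_zone", "perisynaptic"),
    zone_flagged = iv$open_lo | iv$open_hi
  )
}

# 3D distance from points in a given section to the nearest dense-projection
# edge across all dense-projection-bearing sections of the synapse.
# profiles: the synapse's profile tibble; returns vector of distances.
dp_distance_3d <- function(x, y, section_index, profiles, section_thickness) {
  has_dp <- !vapply(profiles$dense_projection, is.null, logical(1))
  if (!any(has_dp)) {
    stop("no dense projection in the reconstruction", call. = FALSE)
  }
  dp_profiles <- profiles[has_dp, ]
  n <- length(x)
  best <- rep(Inf, n)
  for (j in seq_len(nrow(dp_profiles))) {
    dz <- (section_index - dp_profiles$section_index[j]) * section_thickness
    dxy <- dist_to_polygon_edge(x, y, dp_profiles$dense_projection[[j]])
    best <- pmin(best, sqrt(dxy^2 + dz^2))
  }
  best
}

# 3D distance to the nearest adherens-junction mark across sections.
aj_distance_3d <- function(x, y, section_index, profiles, section_thickness) {
  n <- length(x)
  best <- rep(Inf, n)
  for (j in seq_len(nrow(profiles))) {
    aj <- profiles$adherens_junctions[[j]]
    if (is.null(aj) || nrow(aj) == 0) next
    dz <- (section_index - profiles$section_index[j]) * section_thickness
    for (k in seq_len(nrow(aj))) {
      d <- sqrt((x - aj[k, 1])^2 + (y - aj[k, 2])^2 + dz^2)
      best <- pmin(best, d)
    }
  }
  best
}

#' Assign an endocytic structure to a site
#'
#' Site precedence is dense projection first: a structure within
#' `dp_site_radius` (3D) of the nearest dense-projection edge is
#' dense-projection-associated even if it is also within `aj_site_radius` of
#' a junction mark; such double-radius cases are flagged for audit.
#'
#' @param x,y Structure reference point (vesicle center or pit apex), nm.
#' @param section_index Section of the structure.
#' @param profiles Profile tibble of the synapse (as in a [syn_dataset]).
#' @param section_thickness nm per section (default 33).
#' @param params [classification_params()].
#' @return Tibble with `site` (`"dense_projection"`, `"adherens_junction"`,
#'   `"interior"`), `dp_distance`, `aj_distance`, and `site_ambiguous`
#'   (within both radii).
#' @export
assign_site <- function(x, y, section_index, profiles, section_thickness = 33,
                        params = classification_params()) {
  d_dp <- dp_distance_3d(x, y, section_index, profiles, section_thickness)
  d_aj <- aj_distance_3d(x, y, section_index, profiles, section_thickness)
  in_dp <- d_dp <= params$dp_site_radius
  in_aj <- d_aj <= params$aj_site_radius
  tibble::tibble(
    site = dplyr::case_when(
      in_dp ~ "dense_projection",
      in_aj ~ "adherens_junction",
      TRUE ~ "interior"
    ),
    dp_distance = d_dp,
    aj_distance = d_aj,
    site_ambiguous = in_dp & in_aj
  )
}

#' Classify a membrane pit as exocytic or endocytic
#'
#' A pit with a synaptic-vesicle-sized mouth (width <= 35 nm) away from the
#' adherens junction is a fusion intermediate (exocytic). Any other pit is
#' endocytic, split at the hemisphere: shallow when `depth < width / 2`,
#' deep when `depth >= width / 2`.
#'
#' @param width,depth Pit mouth span and invagination depth (nm).
#' @param site Site label from [assign_site()] for the pit.
#' @param params [classification_params()].
#' @return Character vector: `"exocytic"`, `"shallow_endocytic"` or
#'   `"deep_endocytic"`.
#' @export
classify_pit <- function(width, depth, site, params = classification_params()) {
  dplyr::case_when(
    width <= params$large_vesicle_min_diameter & site != "adherens_junction" ~
      "exocytic",
    depth < width / 2 ~ "shallow_endocytic",
    TRUE ~ "deep_endocytic"
  )
}

#' Classify every vesicle and pit in a dataset
#'
#' Runs the full rule set over a [syn_dataset]: pools and kinds from edge
#' distance, core and diameter; zones from the membrane arc between the
#' dense projection and the flanking adherens junctions (profiles without a
#' dense projection inherit the nearest one in the reconstruction, flagged
#' via `dp_inherited`); sites from 3D distances across sections; pit
#' categories from width, depth and site.
#'
#' @param dataset A [syn_dataset].
#' @param params [classification_params()].
#' @return A list with `vesicles` and `pits`: copies of the dataset tibbles
#'   with label columns (`pool`, `kind`, `zone`, `site`, `pit_class`, ...)
#'   appended.
#' @export
classify_dataset <- function(dataset, params = classification_params()) {
  stopifnot(inherits(dataset, "syn_dataset"))
  ves_out <- list(); pit_out <- list()
  for (si in seq_len(nrow(dataset$synapses))) {
    sid <- dataset$synapses$synapse_id[si]
    st <- dataset$synapses$section_thickness[si]
    prof <- dataset$profiles[dataset$profiles$synapse_id == sid, ]
    v <- dataset$vesicles[dataset$vesicles$synapse_id == sid, ]
    p <- dataset$pits[dataset$pits$synapse_id == sid, ]
    if (nrow(v) > 0) {
      labs <- vector("list", nrow(prof))
      for (pi in seq_len(nrow(prof))) {
        sel <- v$section_index == prof$section_index[pi]
        if (!any(sel)) next
        vv <- v[sel, ]
        mem <- prof$membrane[[pi]]
        dp <- prof$dense_projection[[pi]]
        dp_inherited <- FALSE
        if (is.null(dp)) {
          # inherit the dense projection of the nearest bearing section
          has_dp <- which(!vapply(prof$dense_projection, is.null, logical(1)))
          nearest <- has_dp[which.min(abs(prof$section_index[has_dp] -
                                            prof$section_index[pi]))]
          dp <- prof$dense_projection[[nearest]]
          dp_inherited <- TRUE
        }
        ed <- edge_distance_to_membrane(vv$x, vv$y, vv$diameter, mem)
        zn <- assign_zone(vv$x, vv$y, mem, dp, prof$adherens_junctions[[pi]])
        labs[[pi]] <- dplyr::bind_cols(
          vv,
          tibble::tibble(
            pool = vesicle_pool(ed, vv$tether_observed, params),
            kind = vesicle_kind(vv$core, vv$diameter, params),
            edge_distance = ed,
            dp_inherited = dp_inherited
          ),
          zn
        )
      }
      labs <- dplyr::bind_rows(labs)
      site <- assign_site(labs$x, labs$y, labs$section_index, prof, st, params)
      ves_out[[length(ves_out) + 1]] <- dplyr::bind_cols(labs, site)
    }
    if (nrow(p) > 0) {
      site <- assign_site(p$apex_x, p$apex_y, p$section_index, prof, st, params)
      pit_out[[length(pit_out) + 1]] <- dplyr::bind_cols(
        p, site,
        tibble::tibble(pit_class = classify_pit(p$width, p$depth, site$site,
                                                params))
      )
    }
  }
  list(
    vesicles = if (length(ves_out)) dplyr::bind_rows(ves_out) else
      dplyr::bind_cols(empty_vesicles(),
                       tibble::tibble(pool = character(), kind = character(),
                                      edge_distance = numeric(),
                                      dp_inherited = logical(),
                                      zone = character(),
                                      zone_flagged = logical(),
                                      site = character(),
                                      dp_distance = numeric(),
                                      aj_distance = numeric(),
                                      site_ambiguous = logical())),
    pits = if (length(pit_out)) dplyr::bind_rows(pit_out) else
      dplyr::bind_cols(empty_pits(),
                       tibble::tibble(site = character(),
                                      dp_distance = numeric(),
                                      aj_distance = numeric(),
                                      site_ambiguous = logical(),
                                      pit_class = character()))
  )
}
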