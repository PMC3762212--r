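# The annotation data model: one condition dataset holds serial-section
# synapse reconstructions as a set of linked tibbles.

#' Construct a condition dataset of annotated synapse profiles
#'
#' A `syn_dataset` bundles every annotation for one experimental condition
#' (one genotype/retinal status at one stimulation-to-freeze interval) as
#' four linked tibbles:
#'
#' * `condition`: one row — `condition_label`, `stimulated`,
#'   `interval_to_freeze` (ms; `NA` when unstimulated).
#' * `synapses`: one row per reconstruction — `synapse_id`,
#'   `section_thickness` (nm, default 33).
#' * `profiles`: one row per serial section — `synapse_id`, `section_index`,
#'   `profile_area` (nm^2), and three list-columns of two-column coordinate
#'   matrices (nm): `membrane` (open polyline tracing the presynaptic plasma
#'   membrane), `dense_projection` (closed polygon, or `NULL` when the
#'   section misses the dense projection), `adherens_junctions` (0-2 marks
#'   on the membrane).
#' * `vesicles`: one row per vesicle — `synapse_id`, `section_index`,
#'   `vesicle_id`, `x`, `y` (center, nm), `diameter` (nm), `core`
#'   (`"clear"` or `"dense"`), `tether_observed` (logical). Extra columns
#'   (e.g. generator truth labels) are preserved.
#' * `pits`: one row per membrane pit — `synapse_id`, `section_index`,
#'   `pit_id`, `apex_x`, `apex_y` (deepest point), `mouth_left_x/y`,
#'   `mouth_right_x/y` (where the pit meets the membrane), `width`, `depth`
#'   (nm).
#'
#' All lengths are nm, areas nm^2, times ms; records carry no unit fields.
#' The out-of-plane coordinate of a structure is implicit:
#' `section_index * section_thickness`.
#'
#' @param condition_label Character scalar naming the condition.
#' @param stimulated Logical scalar.
#' @param interval_to_freeze Stimulation-to-freeze interval in ms
#'   (`NA` for unstimulated).
#' @param synapses,profiles,vesicles,pits Tibbles as described above.
#' @return An object of class `syn_dataset`.
#' @seealso [validate_dataset()], [read_dataset()], [generate_dataset()]
#' @export
syn_dataset <- function(condition_label, stimulated, interval_to_freeze = NA_real_,
                        synapses, profiles, vesicles = empty_vesicles(),
                        pits = empty_pits()) {
  structure(
    list(
      condition = tibble::tibble(
        condition_label = as.character(condition_label),
        stimulated = as.logical(stimulated),
        interval_to_freeze = as.numeric(interval_to_freeze)
      ),
      synapses = tibble::as_tibble(synapses),
      profiles = tibble::as_tibble(profiles),
      vesicles = tibble::as_tibble(vesicles),
      pits = tibble::as_tibble(pits)
    ),
    class = "syn_dataset"
  )
}

empty_vesicles <- function() {
  tibble::tibble(
    synapse_id = character(), section_index = integer(),
    vesicle_id = character(), x = numeric(), y = numeric(),
    diameter = numeric(), core = character(), tether_observed = logical()
  )
}

empty_pits <- function() {
  tibble::tibble(
    synapse_id = character(), section_index = integer(), pit_id = character(),
    apex_x = numeric(), apex_y = numeric(),
    mouth_left_x = numeric(), mouth_left_y = numeric(),
    mouth_right_x = numeric(), mouth_right_y = numeric(),
    width = numeric(), depth = numeric()
  )
}

#' @export
print.syn_dataset <- function(x, ...) {
  cond <- x$condition
  tp <- if (isTRUE(cond$stimulated)) paste0(cond$interval_to_freeze, " ms") else "unstimulated"
  cat("<syn_dataset> ", cond$condition_label, " (", tp, ")\n", sep = "")
  cat("  synapses: ", nrow(x$synapses),
      " | profiles: ", nrow(x$profiles),
      " | vesicles: ", nrow(x$vesicles),
      " | pits: ", nrow(x$pits), "\n", sep = "")
  invisible(x)
}

# Look up a profile row (single row tibble) by synapse and section.
profile_row <- function(dataset, synapse_id, section_index) {
  p <- dataset$profiles
  p[p$synapse_id == synapse_id & p$section_index == section_index, , drop = FALSE]
}

#' Validate a condition dataset against the annotation invariants
#'
#' Checks every structural rule of the data model and returns the violations
#' as data, not errors: membrane polylines have at least 2 finite points;
#' profile areas are positive; vesicle diameters are positive and cores are
#' `"clear"` or `"dense"`; pit widths are positive and depths non-negative;
#' adherens-junction marks and pit mouth points lie on the membrane polyline
#' within `placement_tolerance`; section indices within a synapse are
#' strictly consecutive; every synapse has at least one dense-projection-
#' bearing profile; a stimulated condition carries a positive
#' `interval_to_freeze`.
#'
#' @param dataset A [syn_dataset].
#' @param placement_tolerance Maximum allowed distance (nm) of an
#'   "on-membrane" point from the membrane polyline. Default 5 nm
#'   (annotation jitter).
#' @return A tibble of issues with columns `record`, `field`, `rule`,
#'   `message`; zero rows when the dataset is valid.
#' @export
validate_dataset <- function(dataset, placement_tolerance = 5) {
  stopifnot(inherits(dataset, "syn_dataset"))
  issues <- list()
  add <- function(record, field, rule, message) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      record = record, field = field, rule = rule, message = message
    )
  }

  cond <- dataset$condition
  if (isTRUE(cond$stimulated) &&
      (is.na(cond$interval_to_freeze) || cond$interval_to_freeze <= 0)) {
    add("condition", "interval_to_freeze", "positive_when_stimulated",
        "stimulated condition requires interval_to_freeze > 0")
  }

  for (sid in dataset$synapses$synapse_id) {
    prof <- dataset$profiles[dataset$profiles$synapse_id == sid, ]
    if (nrow(prof) == 0) {
      add(sid, "profiles", "nonempty", "synapse has no profiles")
      next
    }
    idx <- sort(prof$section_index)
    if (length(idx) > 1 && any(diff(idx) != 1)) {
      gaps <- idx[which(diff(idx) != 1)]
      add(sid, "section_index", "contiguous",
          paste0("non-contiguous sections after index ",
                 paste(gaps, collapse = ", ")))
    }
    if (!any(!vapply(prof$dense_projection, is.null, logical(1)))) {
      add(sid, "dense_projection", "at_least_one",
          "no profile in the synapse contains a dense projection")
    }
    for (i in seq_len(nrow(prof))) {
      rec <- paste0(sid, "/section ", prof$section_index[i])
      mem <- prof$membrane[[i]]
      if (is.null(mem) || !is.matrix(mem) || nrow(mem) < 2) {
        add(rec, "membrane", "min_points", "membrane needs >= 2 points")
        next
      }
      if (!all(is.finite(mem))) {
        add(rec, "membrane", "finite", "membrane has non-finite coordinates")
      }
      if (!is.finite(prof$profile_area[i]) || prof$profile_area[i] <= 0) {
        add(rec, "profile_area", "positive", "profile_area must be > 0")
      }
      aj <- prof$adherens_junctions[[i]]
      if (!is.null(aj) && nrow(aj) > 0) {
        d <- dist_to_polyline(aj[, 1], aj[, 2], mem)$distance
        off <- which(d > placement_tolerance)
        for (k in off) {
          add(rec, "adherens_junctions", "on_membrane",
              sprintf("adherens-junction mark %d is %.1f nm off the membrane",
                      k, d[k]))
        }
      }
    }
  }

  v <- dataset$vesicles
  if (nrow(v) > 0) {
    bad_d <- which(!is.finite(v$diameter) | v$diameter <= 0)
    for (k in bad_d) {
      add(paste0("vesicle ", v$vesicle_id[k]), "diameter", "positive",
          "vesicle diameter must be > 0")
    }
    bad_core <- which(!v$core %in% c("clear", "dense"))
    for (k in bad_core) {
      add(paste0("vesicle ", v$vesicle_id[k]), "core", "enum",
          "core must be 'clear' or 'dense'")
    }
  }

  p <- dataset$pits
  if (nrow(p) > 0) {
    for (k in seq_len(nrow(p))) {
      rec <- paste0("pit ", p$pit_id[k])
      if (!is.finite(p$width[k]) || p$width[k] <= 0) {
        add(rec, "width", "positive", "pit width must be > 0")
      }
      if (!is.finite(p$depth[k]) || p$depth[k] < 0) {
        add(rec, "depth", "nonnegative", "pit depth must be >= 0")
      }
      prow <- profile_row(dataset, p$synapse_id[k], p$section_index[k])
      if (nrow(prow) == 1) {
        mem <- prow$membrane[[1]]
        dm <- dist_to_polyline(
          c(p$mouth_left_x[k], p$mouth_right_x[k]),
          c(p$mouth_left_y[k], p$mouth_right_y[k]), mem
        )$distance
        if (any(dm > placement_tolerance)) {
          add(rec, "mouth", "on_membrane",
              sprintf("pit mouth point %.1f nm off the membrane", max(dm)))
        }
      }
    }
  }

  if (length(issues) == 0) {
    tibble::tibble(record = character(), field = character(),
                   rule = character(), message = character())
  } else {
    dplyr::bind_rows(issues)
  }
}
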