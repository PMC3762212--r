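# Reading and writing annotation datasets. JSON is the canonical on-disk
# form (one dataset per file, schema mirroring the syn_dataset tibbles); a
# flat CSV dialect (one row per structure, profile metadata repeated) is
# provided for spreadsheet interoperability.

CORE_VESICLE_COLS <- c("synapse_id", "section_index", "vesicle_id",
                       "x", "y", "diameter", "core", "tether_observed")
CORE_PIT_COLS <- c("synapse_id", "section_index", "pit_id",
                   "apex_x", "apex_y", "mouth_left_x", "mouth_left_y",
                   "mouth_right_x", "mouth_right_y", "width", "depth")

# Stable column layout after reading: core columns first, extra columns in
# alphabetical order, with empty strings in extras promoted back to NA.
normalize_extras <- function(df, core_cols) {
  extras <- sort(setdiff(names(df), core_cols))
  for (e in extras) {
    if (is.character(df[[e]])) df[[e]][!nzchar(df[[e]])] <- NA_character_
  }
  df[, c(intersect(core_cols, names(df)), extras)]
}

guess_format <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
  else if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
  else stop("cannot guess format from extension of ", path, call. = FALSE)
}

#' Read a condition dataset from disk
#'
#' Parses the package's JSON schema or flat CSV dialect back into a
#' [syn_dataset], validating all invariants afterwards. Unknown scalar
#' fields on vesicle and pit records (such as generator truth labels) are
#' preserved as extra columns.
#'
#' @param path File to read.
#' @param format `"json"` or `"csv"`; guessed from the extension by default.
#' @param validate Run [validate_dataset()] and error on issues
#'   (default `TRUE`).
#' @return A [syn_dataset].
#' @examples
#' f <- system.file("extdata", "example_unstimulated.json",
#'                  package = "synmorph")
#' ds <- read_dataset(f)
#' ds
#' @export
read_dataset <- function(path, format = guess_format(path), validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- match.arg(format, c("json", "csv"))
  ds <- if (format == "json") read_dataset_json(path) else read_dataset_csv(path)
  if (validate) {
    iss <- validate_dataset(ds)
    if (nrow(iss) > 0) {
      stop("dataset failed validation: ",
           paste(utils::head(iss$message, 5), collapse = "; "),
           if (nrow(iss) > 5) sprintf(" (and %d more)", nrow(iss) - 5) else "",
           call. = FALSE)
    }
  }
  ds
}

#' Write a condition dataset to disk
#'
#' Inverse of [read_dataset()]: `read_dataset(write_dataset(ds, f))` returns
#' a dataset equal to `ds`, and rewriting a file produced by this function
#' reproduces it byte for byte (canonical serialization).
#'
#' @param dataset A [syn_dataset].
#' @param path Output file.
#' @param format `"json"` (canonical) or `"csv"`; guessed from the extension
#'   by default.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, format = guess_format(path)) {
  stopifnot(inherits(dataset, "syn_dataset"))
  format <- match.arg(format, c("json", "csv"))
  if (format == "json") write_dataset_json(dataset, path)
  else write_dataset_csv(dataset, path)
  invisible(path)
}

## ---- JSON -----------------------------------------------------------------

coords_to_list <- function(m) {
  if (is.null(m) || nrow(m) == 0) return(NULL)
  lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
}

list_to_coords <- function(lst) {
  if (is.null(lst) || length(lst) == 0) return(NULL)
  do.call(rbind, lapply(lst, function(p) c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
}

structure_extras <- function(df, core_cols, i) {
  extra <- sort(setdiff(names(df), core_cols))
  out <- list()
  for (col in extra) {
    val <- df[[col]][i]
    if (!is.na(val)) out[[col]] <- val
  }
  out
}

write_dataset_json <- function(dataset, path) {
  cond <- dataset$condition
  syn_list <- lapply(seq_len(nrow(dataset$synapses)), function(si) {
    sid <- dataset$synapses$synapse_id[si]
    prof <- dataset$profiles[dataset$profiles$synapse_id == sid, ]
    prof <- prof[order(prof$section_index), ]
    profs <- lapply(seq_len(nrow(prof)), function(pi) {
      sec <- prof$section_index[pi]
      v <- dataset$vesicles[dataset$vesicles$synapse_id == sid &
                            dataset$vesicles$section_index == sec, ]
      p <- dataset$pits[dataset$pits$synapse_id == sid &
                        dataset$pits$section_index == sec, ]
      ves <- lapply(seq_len(nrow(v)), function(k) {
        c(list(id = v$vesicle_id[k], center = c(v$x[k], v$y[k]),
               diameter = v$diameter[k], core = v$core[k],
               tether_observed = v$tether_observed[k]),
          structure_extras(v, CORE_VESICLE_COLS, k))
      })
      pit <- lapply(seq_len(nrow(p)), function(k) {
        c(list(id = p$pit_id[k],
               apex = c(p$apex_x[k], p$apex_y[k]),
               mouth_left = c(p$mouth_left_x[k], p$mouth_left_y[k]),
               mouth_right = c(p$mouth_right_x[k], p$mouth_right_y[k]),
               width = p$width[k], depth = p$depth[k]),
          structure_extras(p, CORE_PIT_COLS, k))
      })
      out <- list(
        section_index = sec,
        profile_area = prof$profile_area[pi],
        membrane = coords_to_list(prof$membrane[[pi]]),
        adherens_junctions = coords_to_list(prof$adherens_junctions[[pi]]),
        vesicles = ves,
        pits = pit
      )
      dp <- coords_to_list(prof$dense_projection[[pi]])
      if (!is.null(dp)) out$dense_projection <- dp
      if (is.null(out$adherens_junctions)) out$adherens_junctions <- list()
      out
    })
    list(id = sid,
         section_thickness = dataset$synapses$section_thickness[si],
         profiles = profs)
  })
  obj <- list(
    schema = "synmorph-dataset-v1",
    condition_label = cond$condition_label,
    stimulated = cond$stimulated,
    synapses = syn_list
  )
  if (!is.na(cond$interval_to_freeze)) {
    obj <- append(obj, list(interval_to_freeze = cond$interval_to_freeze),
                  after = 3)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
}

read_dataset_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  required <- c("condition_label", "stimulated", "synapses")
  missing <- setdiff(required, names(obj))
  if (length(missing) > 0) {
    stop("schema error: missing required field(s) ",
         paste(missing, collapse = ", "), " in dataset record", call. = FALSE)
  }
  syn_rows <- list(); prof_rows <- list(); ves_rows <- list(); pit_rows <- list()
  for (syn in obj$synapses) {
    for (f in c("id", "profiles")) {
      if (is.null(syn[[f]])) {
        stop("schema error: missing required field '", f, "' in synapse record",
             call. = FALSE)
      }
    }
    sid <- syn$id
    syn_rows[[length(syn_rows) + 1]] <- tibble::tibble(
      synapse_id = sid,
      section_thickness = as.numeric(syn$section_thickness %||% 33)
    )
    for (pr in syn$profiles) {
      for (f in c("section_index", "profile_area", "membrane")) {
        if (is.null(pr[[f]])) {
          stop("schema error: missing required field '", f,
               "' in profile record of synapse ", sid, call. = FALSE)
        }
      }
      prof_rows[[length(prof_rows) + 1]] <- tibble::tibble(
        synapse_id = sid,
        section_index = as.integer(pr$section_index),
        profile_area = as.numeric(pr$profile_area),
        membrane = list(list_to_coords(pr$membrane)),
        dense_projection = list(list_to_coords(pr$dense_projection)),
        adherens_junctions = list(
          list_to_coords(pr$adherens_junctions) %||%
            matrix(numeric(0), ncol = 2)
        )
      )
      for (v in pr$vesicles %||% list()) {
        for (f in c("id", "center", "diameter", "core", "tether_observed")) {
          if (is.null(v[[f]])) {
            stop("schema error: missing required field '", f,
                 "' in vesicle record of synapse ", sid, call. = FALSE)
          }
        }
        row <- tibble::tibble(
          synapse_id = sid, section_index = as.integer(pr$section_index),
          vesicle_id = v$id,
          x = as.numeric(v$center[[1]]), y = as.numeric(v$center[[2]]),
          diameter = as.numeric(v$diameter), core = v$core,
          tether_observed = as.logical(v$tether_observed)
        )
        extras <- setdiff(names(v),
                          c("id", "center", "diameter", "core", "tether_observed"))
        for (e in extras) row[[e]] <- v[[e]]
        ves_rows[[length(ves_rows) + 1]] <- row
      }
      for (p in pr$pits %||% list()) {
        for (f in c("id", "apex", "mouth_left", "mouth_right", "width", "depth")) {
          if (is.null(p[[f]])) {
            stop("schema error: missing required field '", f,
                 "' in pit record of synapse ", sid, call. = FALSE)
          }
        }
        row <- tibble::tibble(
          synapse_id = sid, section_index = as.integer(pr$section_index),
          pit_id = p$id,
          apex_x = as.numeric(p$apex[[1]]), apex_y = as.numeric(p$apex[[2]]),
          mouth_left_x = as.numeric(p$mouth_left[[1]]),
          mouth_left_y = as.numeric(p$mouth_left[[2]]),
          mouth_right_x = as.numeric(p$mouth_right[[1]]),
          mouth_right_y = as.numeric(p$mouth_right[[2]]),
          width = as.numeric(p$width), depth = as.numeric(p$depth)
        )
        extras <- setdiff(names(p), c("id", "apex", "mouth_left", "mouth_right",
                                      "width", "depth"))
        for (e in extras) row[[e]] <- p[[e]]
        pit_rows[[length(pit_rows) + 1]] <- row
      }
    }
  }
  ves <- if (length(ves_rows)) {
    normalize_extras(dplyr::bind_rows(ves_rows), CORE_VESICLE_COLS)
  } else empty_vesicles()
  pit <- if (length(pit_rows)) {
    normalize_extras(dplyr::bind_rows(pit_rows), CORE_PIT_COLS)
  } else empty_pits()
  syn_dataset(
    condition_label = obj$condition_label,
    stimulated = obj$stimulated,
    interval_to_freeze = as.numeric(obj$interval_to_freeze %||% NA_real_),
    synapses = if (length(syn_rows)) dplyr::bind_rows(syn_rows) else
      tibble::tibble(synapse_id = character(), section_thickness = numeric()),
    profiles = if (length(prof_rows)) dplyr::bind_rows(prof_rows) else
      tibble::tibble(synapse_id = character(), section_index = integer(),
                     profile_area = numeric(), membrane = list(),
                     dense_projection = list(), adherens_junctions = list()),
    vesicles = ves,
    pits = pit
  )
}

## ---- CSV ------------------------------------------------------------------

# Polyline/polygon coordinates are packed into a single cell as
# "x1 y1;x2 y2;..." with full double precision.
pack_coords <- function(m) {
  if (is.null(m) || nrow(m) == 0) return("")
  paste(apply(m, 1, function(r) {
    paste(format(r, digits = 17, scientific = FALSE, trim = TRUE), collapse = " ")
  }), collapse = ";")
}

unpack_coords <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  rows <- strsplit(s, ";", fixed = TRUE)[[1]]
  do.call(rbind, lapply(rows, function(r) as.numeric(strsplit(r, " ")[[1]])))
}

#' @details The CSV dialect has one row per record with a `record` column of
#'   `"profile"`, `"vesicle"` or `"pit"`. Every row repeats
#'   `condition_label`, `stimulated`, `interval_to_freeze`, `synapse_id`,
#'   `section_thickness` and `section_index`. Profile rows carry
#'   `profile_area` plus the membrane, dense-projection and
#'   adherens-junction geometry packed as `"x y;x y;..."` strings; vesicle
#'   rows carry `id`, `x`, `y`, `diameter`, `core`, `tether_observed`; pit
#'   rows carry `id`, `apex_x/y`, `mouth_left_x/y`, `mouth_right_x/y`,
#'   `width`, `depth`. Extra vesicle/pit columns are appended verbatim.
#' @rdname write_dataset
write_dataset_csv <- function(dataset, path) {
  cond <- dataset$condition
  meta <- function(sid, sec) {
    st <- dataset$synapses$section_thickness[dataset$synapses$synapse_id == sid]
    tibble::tibble(
      condition_label = cond$condition_label, stimulated = cond$stimulated,
      interval_to_freeze = cond$interval_to_freeze,
      synapse_id = sid, section_thickness = st, section_index = sec
    )
  }
  rows <- list()
  for (i in seq_len(nrow(dataset$profiles))) {
    pr <- dataset$profiles[i, ]
    r <- meta(pr$synapse_id, pr$section_index)
    r$record <- "profile"
    r$profile_area <- pr$profile_area
    r$membrane <- pack_coords(pr$membrane[[1]])
    r$dense_projection <- pack_coords(pr$dense_projection[[1]])
    r$adherens_junctions <- pack_coords(pr$adherens_junctions[[1]])
    rows[[length(rows) + 1]] <- r
  }
  v <- dataset$vesicles
  for (i in seq_len(nrow(v))) {
    r <- meta(v$synapse_id[i], v$section_index[i])
    r$record <- "vesicle"
    r$id <- v$vesicle_id[i]
    r$x <- v$x[i]; r$y <- v$y[i]; r$diameter <- v$diameter[i]
    r$core <- v$core[i]; r$tether_observed <- v$tether_observed[i]
    for (e in sort(setdiff(names(v), CORE_VESICLE_COLS))) r[[e]] <- v[[e]][i]
    rows[[length(rows) + 1]] <- r
  }
  p <- dataset$pits
  for (i in seq_len(nrow(p))) {
    r <- meta(p$synapse_id[i], p$section_index[i])
    r$record <- "pit"
    r$id <- p$pit_id[i]
    for (col in c("apex_x", "apex_y", "mouth_left_x", "mouth_left_y",
                  "mouth_right_x", "mouth_right_y", "width", "depth")) {
      r[[col]] <- p[[col]][i]
    }
    for (e in sort(setdiff(names(p), CORE_PIT_COLS))) r[[e]] <- p[[e]][i]
    rows[[length(rows) + 1]] <- r
  }
  df <- dplyr::bind_rows(rows)
  readr::write_csv(df, path, na = "")
}

# Best-effort type restoration for extra CSV columns (read as character):
# numeric if every non-blank value parses, logical if every value is
# TRUE/FALSE, character otherwise.
coerce_extra <- function(x) {
  if (!is.character(x)) return(x)
  xx <- x
  xx[!nzchar(xx)] <- NA_character_
  if (all(is.na(xx))) return(xx)
  num <- suppressWarnings(as.numeric(xx))
  if (identical(is.na(num), is.na(xx))) return(num)
  if (all(is.na(xx) | xx %in% c("TRUE", "FALSE"))) return(as.logical(xx))
  xx
}

read_dataset_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        na = character(),
                        col_types = readr::cols(.default = "c"))
  req <- c("condition_label", "stimulated", "synapse_id", "section_index",
           "record")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    stop("schema error: missing required column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  itf <- if ("interval_to_freeze" %in% names(df)) {
    vals <- num_or_na(df$interval_to_freeze)
    if (all(is.na(vals))) NA_real_ else vals[!is.na(vals)][1]
  } else NA_real_

  prof_df <- df[df$record == "profile", ]
  synapses <- dplyr::distinct(
    prof_df, synapse_id = .data$synapse_id,
    section_thickness = num_or_na(.data$section_thickness)
  )
  profiles <- tibble::tibble(
    synapse_id = as.character(prof_df$synapse_id),
    section_index = as.integer(prof_df$section_index),
    profile_area = num_or_na(prof_df$profile_area),
    membrane = lapply(as.character(prof_df$membrane), unpack_coords),
    dense_projection = lapply(as.character(prof_df$dense_projection), unpack_coords),
    adherens_junctions = lapply(as.character(prof_df$adherens_junctions), function(s) {
      unpack_coords(s) %||% matrix(numeric(0), ncol = 2)
    })
  )

  meta_cols <- c("condition_label", "stimulated", "interval_to_freeze",
                 "section_thickness", "record", "profile_area", "membrane",
                 "dense_projection", "adherens_junctions")
  ves_df <- df[df$record == "vesicle", ]
  vesicles <- if (nrow(ves_df) > 0) {
    out <- tibble::tibble(
      synapse_id = as.character(ves_df$synapse_id),
      section_index = as.integer(ves_df$section_index),
      vesicle_id = as.character(ves_df$id),
      x = num_or_na(ves_df$x), y = num_or_na(ves_df$y),
      diameter = num_or_na(ves_df$diameter),
      core = as.character(ves_df$core),
      tether_observed = as.logical(ves_df$tether_observed)
    )
    extras <- setdiff(names(ves_df),
                      c(meta_cols, "synapse_id", "section_index", "id", "x", "y",
                        "diameter", "core", "tether_observed",
                        "apex_x", "apex_y", "mouth_left_x", "mouth_left_y",
                        "mouth_right_x", "mouth_right_y", "width", "depth"))
    for (e in extras) {
      col <- ves_df[[e]]
      if (!all(is.na(col) | col == "")) out[[e]] <- coerce_extra(col)
    }
    out
  } else empty_vesicles()

  pit_df <- df[df$record == "pit", ]
  pits <- if (nrow(pit_df) > 0) {
    out <- tibble::tibble(
      synapse_id = as.character(pit_df$synapse_id),
      section_index = as.integer(pit_df$section_index),
      pit_id = as.character(pit_df$id),
      apex_x = num_or_na(pit_df$apex_x), apex_y = num_or_na(pit_df$apex_y),
      mouth_left_x = num_or_na(pit_df$mouth_left_x),
      mouth_left_y = num_or_na(pit_df$mouth_left_y),
      mouth_right_x = num_or_na(pit_df$mouth_right_x),
      mouth_right_y = num_or_na(pit_df$mouth_right_y),
      width = num_or_na(pit_df$width), depth = num_or_na(pit_df$depth)
    )
    extras <- setdiff(names(pit_df),
                      c(meta_cols, "synapse_id", "section_index", "id",
                        "apex_x", "apex_y", "mouth_left_x", "mouth_left_y",
                        "mouth_right_x", "mouth_right_y", "width", "depth",
                        "x", "y", "diameter", "core", "tether_observed"))
    for (e in extras) {
      col <- pit_df[[e]]
      if (!all(is.na(col) | col == "")) out[[e]] <- coerce_extra(col)
    }
    out
  } else empty_pits()

  syn_dataset(
    condition_label = as.character(df$condition_label[1]),
    stimulated = as.logical(df$stimulated[1]),
    interval_to_freeze = itf,
    synapses = synapses, profiles = profiles,
    vesicles = normalize_extras(vesicles, CORE_VESICLE_COLS),
    pits = normalize_extras(pits, CORE_PIT_COLS)
  )
}
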