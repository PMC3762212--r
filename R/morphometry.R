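# Morphometry: 3D distances to the dense projection, 33-nm distance
# histograms, reference normalization, per-profile / per-synapse pool
# aggregates, and Mann-Whitney group comparisons.

#' Normalization references
#'
#' Counts along the active zone are rescaled to a typical active-zone
#' membrane length, per-profile totals to a typical varicosity
#' cross-sectional area, so that differences in terminal size do not
#' masquerade as pool-size changes.
#'
#' @param typical_active_zone_length nm, default 670.
#' @param typical_profile_area nm^2, default 60700.
#' @return List of class `syn_norm_refs`.
#' @export
normalization_refs <- function(typical_active_zone_length = 670,
                               typical_profile_area = 60700) {
  stopifnot(typical_active_zone_length > 0, typical_profile_area > 0)
  structure(list(typical_active_zone_length = typical_active_zone_length,
                 typical_profile_area = typical_profile_area),
            class = "syn_norm_refs")
}

#' Rescale a count to a reference measure
#'
#' `count * reference / observed`: linear in the count, inverse-linear in
#' the observed measure. A count of 5 along a 335 nm active zone becomes 10
#' per typical 670 nm active zone.
#'
#' @param count Raw count (vector allowed).
#' @param observed Observed measure for each count: active-zone length (nm)
#'   or profile area (nm^2). Must be > 0.
#' @param refs [normalization_refs()].
#' @param mode `"active_zone_length"` or `"profile_area"` — which reference
#'   to rescale to.
#' @return Normalized count(s).
#' @export
normalize_count <- function(count, observed, refs = normalization_refs(),
                            mode = c("active_zone_length", "profile_area")) {
  mode <- match.arg(mode)
  if (any(!is.finite(observed) | observed <= 0)) {
    stop("observed measure must be > 0", call. = FALSE)
  }
  ref <- switch(mode,
                active_zone_length = refs$typical_active_zone_length,
                profile_area = refs$typical_profile_area)
  count * ref / observed
}

#' 3D distance from vesicles to the nearest dense-projection edge
#'
#' For a vesicle in section *i* and each dense-projection-bearing section
#' *j* of the same reconstruction, the distance is
#' `sqrt(x^2 + z^2)` with `x` the in-plane distance from the vesicle center
#' to the projection of section *j*'s dense-projection edge and
#' `z = (i - j) * section_thickness`; the minimum over *j* is reported. A
#' vesicle whose edge is within `touch_tolerance` of the dense-projection
#' edge in its own section is flagged as touching (the reserved 0-nm
#' histogram column).
#'
#' @param dataset A [syn_dataset].
#' @param touch_tolerance nm, default 2.
#' @return The `vesicles` tibble with `dp_distance_3d` and `touching`
#'   appended.
#' @export
distance_to_dense_projection_3d <- function(dataset, touch_tolerance = 2) {
  stopifnot(inherits(dataset, "syn_dataset"))
  v <- dataset$vesicles
  if (nrow(v) == 0) {
    return(dplyr::bind_cols(v, tibble::tibble(dp_distance_3d = numeric(),
                                              touching = logical())))
  }
  out_d <- numeric(nrow(v)); out_touch <- logical(nrow(v))
  for (si in seq_len(nrow(dataset$synapses))) {
    sid <- dataset$synapses$synapse_id[si]
    st <- dataset$synapses$section_thickness[si]
    prof <- dataset$profiles[dataset$profiles$synapse_id == sid, ]
    sel <- which(v$synapse_id == sid)
    if (length(sel) == 0) next
    out_d[sel] <- dp_distance_3d(v$x[sel], v$y[sel], v$section_index[sel],
                                 prof, st)
    # touching: vesicle edge meets the dense-projection edge in its own section
    for (k in sel) {
      pr <- prof[prof$section_index == v$section_index[k], ]
      dp <- if (nrow(pr) == 1) pr$dense_projection[[1]] else NULL
      out_touch[k] <- !is.null(dp) &&
        (dist_to_polygon_edge(v$x[k], v$y[k], dp) - v$diameter[k] / 2) <=
          touch_tolerance
    }
  }
  dplyr::bind_cols(v, tibble::tibble(dp_distance_3d = out_d,
                                     touching = out_touch))
}

#' Bin distances into a 33-nm histogram with a reserved touching column
#'
#' Bin 0 holds only structures flagged as touching the dense projection;
#' all other distances fall into half-open bins `[k*w, (k+1)*w)` reported as
#' bins 1, 2, ... — so a non-touching structure at exactly 0 nm is in bin 1
#' and one at exactly 33.0 nm is in bin 2.
#'
#' @param distances Non-negative distances (nm).
#' @param touching Logical vector, same length.
#' @param bin_width nm, default 33 (one section).
#' @return A tibble of class `syn_histogram` with `bin`, `lower`, `upper`
#'   (NA for the touching bin) and `count`.
#' @export
bin_by_distance <- function(distances, touching = rep(FALSE, length(distances)),
                            bin_width = 33) {
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  if (any(distances < 0)) stop("distances must be >= 0", call. = FALSE)
  stopifnot(length(distances) == length(touching))
  idx <- ifelse(touching, 0L, floor(distances / bin_width) + 1L)
  kmax <- max(c(idx, 0L))
  counts <- tabulate(idx + 1L, nbins = kmax + 1L)
  out <- tibble::tibble(
    bin = 0:kmax,
    lower = c(NA_real_, (0:(kmax - 1)) * bin_width)[seq_len(kmax + 1)],
    upper = c(NA_real_, (1:kmax) * bin_width)[seq_len(kmax + 1)],
    count = counts
  )
  class(out) <- c("syn_histogram", class(out))
  attr(out, "bin_width") <- bin_width
  out
}

#' Active-zone membrane length of a profile
#'
#' Arc length of the membrane from the dense-projection edge to the
#' flanking adherens-junction mark, summed over both sides (the
#' dense-projection span itself is excluded).
#'
#' @param membrane Membrane polyline.
#' @param dense_projection Dense-projection polygon (or `NULL`).
#' @param adherens Adherens-junction marks.
#' @return Length in nm.
#' @export
active_zone_length <- function(membrane, dense_projection, adherens) {
  iv <- active_zone_interval(membrane, dense_projection, adherens)
  dp_s <- if (!is.null(dense_projection) && nrow(dense_projection) > 0) {
    range(dist_to_polyline(dense_projection[, 1], dense_projection[, 2],
                           membrane)$s)
  } else rep(mean(c(iv$lo, iv$hi)), 2)
  max(dp_s[1] - iv$lo, 0) + max(iv$hi - dp_s[2], 0)
}

#' Per-profile vesicle pool counts
#'
#' Applies the pool rule (edge distance to the membrane plus the annotator's
#' tether flag) to every synaptic vesicle and tallies counts per profile.
#' This is the light-weight path for pool time courses: it skips the zone
#' and site geometry that [classify_dataset()] also computes.
#'
#' @param dataset A [syn_dataset].
#' @param params [classification_params()].
#' @return Tibble with one row per profile: `synapse_id`, `section_index`,
#'   `profile_area`, and columns `docked`, `tethered`, `pool30`,
#'   `cytoplasmic` (synaptic vesicles only).
#' @export
pool_counts_per_profile <- function(dataset, params = classification_params()) {
  stopifnot(inherits(dataset, "syn_dataset"))
  prof <- dataset$profiles
  v <- dataset$vesicles
  pool_levels <- c("docked", "tethered", "pool30", "cytoplasmic")
  out <- matrix(0L, nrow = nrow(prof), ncol = 4,
                dimnames = list(NULL, pool_levels))
  if (nrow(v) > 0) {
    key_prof <- paste(prof$synapse_id, prof$section_index)
    key_ves <- paste(v$synapse_id, v$section_index)
    idx <- match(key_ves, key_prof)
    sv <- vesicle_kind(v$core, v$diameter, params) == "synaptic_vesicle"
    vx <- v$x; vy <- v$y; vd <- v$diameter; vt <- v$tether_observed
    sel_by_prof <- split(which(sv), idx[sv])
    for (pk in names(sel_by_prof)) {
      pi <- as.integer(pk)
      sel <- sel_by_prof[[pk]]
      ed <- edge_distance_to_membrane(vx[sel], vy[sel], vd[sel],
                                      prof$membrane[[pi]])
      pool <- vesicle_pool(ed, vt[sel], params)
      out[pi, ] <- tabulate(match(pool, pool_levels), nbins = 4)
    }
  }
  dplyr::bind_cols(
    prof[, c("synapse_id", "section_index", "profile_area")],
    tibble::as_tibble(out)
  )
}

#' Aggregate vesicle pools and endocytic structures
#'
#' Computes the study's two aggregation scopes. Per profile: mean +/- SEM of
#' docked / tethered / 30-nm counts by zone, raw and normalized (active-zone
#' counts to the typical active-zone length; all-zone totals to the typical
#' profile area). Per synapse: mean +/- SEM of large-vesicle and pit counts
#' by site.
#'
#' @param dataset A [syn_dataset].
#' @param refs [normalization_refs()].
#' @param params [classification_params()].
#' @return List of class `syn_pool_counts` with tibbles `per_profile` and
#'   `per_synapse`.
#' @export
aggregate_pools <- function(dataset, refs = normalization_refs(),
                            params = classification_params()) {
  stopifnot(inherits(dataset, "syn_dataset"))
  if (nrow(dataset$profiles) == 0) stop("empty dataset", call. = FALSE)
  labeled <- classify_dataset(dataset, params)
  v <- labeled$vesicles
  p <- labeled$pits

  # per-profile geometry: active-zone length and area
  prof <- dataset$profiles |>
    dplyr::mutate(
      az_length = purrr::pmap_dbl(
        list(.data$membrane, .data$dense_projection, .data$adherens_junctions),
        active_zone_length
      )
    ) |>
    dplyr::select("synapse_id", "section_index", "profile_area", "az_length")

  pools <- c("docked", "tethered", "pool30", "cytoplasmic")
  grid <- tidyr::expand_grid(
    prof,
    pool = pools,
    zone = c("active_zone", "perisynaptic")
  )
  counts <- if (nrow(v) > 0) {
    v |>
      dplyr::filter(.data$kind == "synaptic_vesicle") |>
      dplyr::count(.data$synapse_id, .data$section_index, .data$pool,
                   .data$zone, name = "count")
  } else {
    tibble::tibble(synapse_id = character(), section_index = integer(),
                   pool = character(), zone = character(), count = integer())
  }
  per_prof_zone <- grid |>
    dplyr::left_join(counts,
                     by = c("synapse_id", "section_index", "pool", "zone")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))

  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0

  by_zone <- per_prof_zone |>
    dplyr::filter(.data$zone == "active_zone") |>
    dplyr::mutate(norm = normalize_count(.data$count, .data$az_length, refs,
                                         "active_zone_length")) |>
    dplyr::group_by(.data$pool, .data$zone) |>
    dplyr::summarise(
      n = dplyr::n(), mean_raw = mean(.data$count), sem_raw = sem(.data$count),
      mean_norm = mean(.data$norm), sem_norm = sem(.data$norm),
      .groups = "drop"
    ) |>
    dplyr::mutate(norm_mode = "active_zone_length")

  peri <- per_prof_zone |>
    dplyr::filter(.data$zone == "perisynaptic") |>
    dplyr::group_by(.data$pool, .data$zone) |>
    dplyr::summarise(
      n = dplyr::n(), mean_raw = mean(.data$count), sem_raw = sem(.data$count),
      mean_norm = NA_real_, sem_norm = NA_real_, .groups = "drop"
    ) |>
    dplyr::mutate(norm_mode = NA_character_)

  totals <- per_prof_zone |>
    dplyr::group_by(.data$synapse_id, .data$section_index, .data$profile_area,
                    .data$pool) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::mutate(norm = normalize_count(.data$count, .data$profile_area, refs,
                                         "profile_area")) |>
    dplyr::group_by(.data$pool) |>
    dplyr::summarise(
      n = dplyr::n(), mean_raw = mean(.data$count), sem_raw = sem(.data$count),
      mean_norm = mean(.data$norm), sem_norm = sem(.data$norm),
      .groups = "drop"
    ) |>
    dplyr::mutate(zone = "all", norm_mode = "profile_area")

  per_profile <- dplyr::bind_rows(by_zone, peri, totals) |>
    dplyr::select("pool", "zone", "n", "mean_raw", "sem_raw", "mean_norm",
                  "sem_norm", "norm_mode") |>
    dplyr::arrange(.data$pool, .data$zone)

  # per-synapse: endocytic structures by class and site
  n_syn <- nrow(dataset$synapses)
  struct <- dplyr::bind_rows(
    if (nrow(v) > 0) {
      v |>
        dplyr::filter(.data$kind == "large_vesicle") |>
        dplyr::transmute(.data$synapse_id, class = "large_vesicle", .data$site)
    },
    if (nrow(p) > 0) {
      p |> dplyr::transmute(.data$synapse_id, class = .data$pit_class,
                            .data$site)
    }
  )
  per_synapse <- if (!is.null(struct) && nrow(struct) > 0) {
    tidyr::expand_grid(
      synapse_id = dataset$synapses$synapse_id,
      dplyr::distinct(struct, .data$class, .data$site)
    ) |>
      dplyr::left_join(
        dplyr::count(struct, .data$synapse_id, .data$class, .data$site,
                     name = "count"),
        by = c("synapse_id", "class", "site")
      ) |>
      dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
      dplyr::group_by(.data$class, .data$site) |>
      dplyr::summarise(
        n = n_syn, mean_raw = mean(.data$count), sem_raw = sem(.data$count),
        total = sum(.data$count), .groups = "drop"
      )
  } else {
    tibble::tibble(class = character(), site = character(), n = integer(),
                   mean_raw = numeric(), sem_raw = numeric(),
                   total = integer())
  }

  structure(list(per_profile = per_profile, per_synapse = per_synapse,
                 n_profiles = nrow(dataset$profiles), n_synapses = n_syn),
            class = "syn_pool_counts")
}

#' @export
print.syn_pool_counts <- function(x, ...) {
  cat("<syn_pool_counts> ", x$n_profiles, " profiles, ", x$n_synapses,
      " synapses\n", sep = "")
  cat("per profile:\n"); print(x$per_profile)
  if (nrow(x$per_synapse) > 0) {
    cat("per synapse:\n"); print(x$per_synapse)
  }
  invisible(x)
}

## ---- Mann-Whitney U -------------------------------------------------------

# Rank-sum U statistic for sample a against b, using midranks for ties.
mw_u_statistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

# Exact two-sided p by full enumeration of all choose(n1+n2, n1) group
# assignments of the observed (mid)ranks.
mw_exact_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  eps <- 1e-9
  p_le <- mean(u_all <= u_obs + eps)
  p_ge <- mean(u_all >= u_obs - eps)
  min(1, 2 * min(p_le, p_ge))
}

# Normal approximation with tie correction and continuity correction.
mw_approx_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  u <- mw_u_statistic(a, b)
  mu <- n1 * n2 / 2
  ties <- table(c(a, b))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Compare two groups with a Mann-Whitney U test
#'
#' Two-sided test of location shift, suited to small, skewed samples. The
#' p-value is exact — computed by full enumeration of all group assignments
#' of the observed ranks — when both samples have at most `exact_max`
#' observations, and uses the normal approximation with tie and continuity
#' corrections otherwise. The significance threshold is Bonferroni-adjusted
#' to `alpha / n_comparisons`.
#'
#' @param a,b Numeric samples (non-empty).
#' @param n_comparisons Number of simultaneous comparisons for the
#'   Bonferroni correction (default 1).
#' @param alpha Family-wise confidence level (default 0.05).
#' @param exact_max Largest per-group size for exact enumeration (default 8).
#' @return One-row tibble: `statistic` (U of `a`), `p_value`, `method`,
#'   `n1`, `n2`, `adjusted_alpha`, `significant`.
#' @export
compare_groups <- function(a, b, n_comparisons = 1, alpha = 0.05,
                           exact_max = 8) {
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  exact <- length(a) <= exact_max && length(b) <= exact_max
  p <- if (exact) mw_exact_p(a, b) else mw_approx_p(a, b)
  thr <- alpha / n_comparisons
  tibble::tibble(
    statistic = mw_u_statistic(a, b),
    p_value = p,
    method = if (exact) "exact_enumeration" else "normal_approximation",
    n1 = length(a), n2 = length(b),
    adjusted_alpha = thr,
    significant = p < thr
  )
}
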