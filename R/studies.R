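# Seeded replicate simulation studies: generate a synthetic experiment at
# the study's sampling, run the corresponding fit, and collect the recovered
# time constants. Replicate i of a study uses seed base_seed * 1000 + i.

FREEZE_TIMEPOINTS <- c(20, 50, 100, 300, 1000, 3000, 10000)
# synapses per timepoint ~ published profile counts / 5 profiles per synapse
# (50, 104, 83, 89, 111, 91, 121 profiles)
FREEZE_N_SYNAPSES <- c(10, 21, 17, 18, 22, 18, 24)

#' Replicate study: docked-pool refill time constant
#'
#' Each replicate generates one full flash-and-freeze dataset series at the
#' study's timepoints and per-timepoint sampling, computes the mean docked
#' count per profile (with its SEM) at each timepoint via the pool
#' classifier rule, and fits the single-exponential recovery weighted by
#' 1/SEM^2.
#'
#' @param n_reps Number of replicates (default 200).
#' @param base_seed Base seed; replicate i uses `base_seed * 1000 + i`.
#' @param timepoints,n_synapses Freeze timepoints (ms) and synapses per
#'   timepoint; defaults follow the study's per-timepoint profile counts.
#' @param params [generator_params()].
#' @return Tibble with one row per replicate: `rep`, `tau` (ms),
#'   `converged`.
#' @export
docked_refill_study <- function(n_reps = 200, base_seed = 1,
                                timepoints = FREEZE_TIMEPOINTS,
                                n_synapses = FREEZE_N_SYNAPSES,
                                params = generator_params()) {
  purrr::map_dfr(seq_len(n_reps), function(i) {
    dss <- generate_dataset(timepoints, n_synapses, params,
                            seed = base_seed * 1000 + i)
    series <- purrr::map_dfr(dss, function(d) {
      pc <- pool_counts_per_profile(d)
      tibble::tibble(
        t = d$condition$interval_to_freeze,
        y = mean(pc$docked),
        sem = stats::sd(pc$docked) / sqrt(nrow(pc))
      )
    })
    fit <- fit_exponential_recovery(dplyr::arrange(series, .data$t))
    tibble::tibble(rep = i, tau = fit$tau, converged = fit$converged)
  })
}

#' Replicate study: paired-pulse slow recovery time constant
#'
#' Each replicate generates one paired-pulse ratio series (intervals 50 ms
#' to 15 s, Gaussian measurement noise) and fits the double exponential.
#'
#' @inheritParams docked_refill_study
#' @param intervals Inter-pulse intervals (ms).
#' @return Tibble with `rep`, `tau_fast`, `tau_slow` (ms), `converged`.
#' @export
paired_pulse_study <- function(n_reps = 200, base_seed = 1,
                               intervals = c(50, 100, 200, 300, 500, 1000,
                                             2000, 3000, 5000, 10000, 15000),
                               params = generator_params()) {
  purrr::map_dfr(seq_len(n_reps), function(i) {
    pp <- generate_paired_pulse(intervals, params,
                                seed = base_seed * 1000 + i)
    fit <- fit_double_exponential_recovery(pp[, c("t", "y")])
    tibble::tibble(rep = i, tau_fast = fit$tau[1], tau_slow = fit$tau[2],
                   converged = fit$converged)
  })
}

#' Replicate study: junction-pit resolution time constant
#'
#' Each replicate draws per-synapse Poisson pit counts along the
#' adherens-junction decay curve from its 300 ms peak at the study's
#' post-peak timepoints and synapse numbers, and fits the exponential decay
#' weighted by 1/SEM^2.
#'
#' @inheritParams docked_refill_study
#' @param timepoints,n_synapses Post-peak timepoints (ms) and synapses per
#'   timepoint.
#' @return Tibble with `rep`, `tau` (ms), `converged`.
#' @export
pit_resolution_study <- function(n_reps = 200, base_seed = 1,
                                 timepoints = c(300, 1000, 3000, 10000),
                                 n_synapses = c(20, 23, 19, 26),
                                 params = generator_params()) {
  purrr::map_dfr(seq_len(n_reps), function(i) {
    pc <- generate_pit_counts(timepoints, n_synapses, params,
                              seed = base_seed * 1000 + i)
    # SEM floor 1/n: counting uncertainty of an all-zero timepoint
    fit <- fit_exponential_decay(
      tibble::tibble(t = pc$t, y = pc$mean_count, sem = pmax(pc$sem, 1 / pc$n))
    )
    tibble::tibble(rep = i, tau = fit$tau, converged = fit$converged)
  })
}
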