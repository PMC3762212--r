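# Recovery and decay kinetics. Three model forms:
#   pool refill      y(t) = y_inf - (y_inf - y_0) * exp(-t / tau)
#   pit resolution   y(t) = y_inf + (y_0 - y_inf) * exp(-(t - t_peak) / tau)
#   paired pulse     y(t) = 1 - A_f * exp(-t / tau_f) - A_s * exp(-t / tau_s)
# Times in ms throughout; fits are least squares (Levenberg-Marquardt via
# minpack.lm), weighted 1/SEM^2 when SEMs are supplied.

new_syn_fit <- function(model, coefficients, tau, data, fitted, r_squared,
                        aic, rss, converged, flags = character()) {
  structure(
    list(model = model, coefficients = coefficients, tau = tau, data = data,
         fitted = fitted, residuals = data$y - fitted, r_squared = r_squared,
         aic = aic, rss = rss, n = nrow(data), converged = converged,
         flags = flags),
    class = "syn_fit"
  )
}

failed_fit <- function(model, data, flags) {
  new_syn_fit(model, coefficients = c(tau = NA_real_), tau = NA_real_,
              data = data, fitted = rep(NA_real_, nrow(data)),
              r_squared = NA_real_, aic = NA_real_, rss = NA_real_,
              converged = FALSE, flags = flags)
}

check_timeseries <- function(data, min_points) {
  stopifnot(is.data.frame(data), all(c("t", "y") %in% names(data)))
  data$t <- unname(as.numeric(data$t))
  data$y <- unname(as.numeric(data$y))
  if (any(diff(data$t) <= 0)) {
    stop("t must be strictly increasing", call. = FALSE)
  }
  if (nrow(data) < min_points) {
    stop("need at least ", min_points, " points", call. = FALSE)
  }
  data
}

fit_weights <- function(data) {
  if ("sem" %in% names(data) && all(is.finite(data$sem)) && all(data$sem > 0)) {
    1 / data$sem^2
  } else {
    rep(1, nrow(data))
  }
}

# Bounded Levenberg-Marquardt over several deterministic starts; returns the
# named coefficient vector of the lowest-RSS converged run, or NULL. Uses
# nls.lm directly: boundary solutions (e.g. a zero amplitude) make the
# Jacobian singular, which the nls-interface wrapper refuses but the
# optimizer itself handles.
lm_multistart <- function(data, w, model, starts, lower) {
  sw <- sqrt(w)
  best <- NULL
  for (start in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = start, lower = lower,
        fn = function(p) sw * (data$y - model(p, data$t)),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      )),
      error = function(e) NULL
    )
    # info 1-4: converged; 5: iteration cap reached on a flat valley — the
    # parameters are still the best least-squares point found
    if (!is.null(fit) && fit$info %in% 1:5 && all(is.finite(fit$par))) {
      rss <- sum(fit$fvec^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(par = fit$par, rss = rss)
      }
    }
  }
  if (is.null(best)) NULL else best$par
}

fit_stats <- function(y, fitted, n_par) {
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  n <- length(y)
  list(rss = rss,
       r2 = if (tss > 0) 1 - rss / tss else NA_real_,
       aic = n * log(rss / n) + 2 * n_par)
}

# Initial tau from a log-linear regression on asymptote-normalized data.
init_tau <- function(t, y, y_inf) {
  z <- (y_inf - y) / max(abs(y_inf - y[1]), .Machine$double.eps)
  ok <- z > 1e-8
  if (sum(ok) >= 2) {
    sl <- unname(stats::coef(stats::lm(log(z[ok]) ~ t[ok]))[2])
    if (is.finite(sl) && sl < 0) return(-1 / sl)
  }
  unname(diff(range(t)) / 3)
}

#' Fit a single-exponential pool-recovery curve
#'
#' `y(t) = y_inf - (y_inf - y_0) * exp(-t / tau)`: a pool depleted to `y_0`
#' refilling toward `y_inf` with time constant `tau` (ms). Used for the
#' docked-pool refill time course.
#'
#' @param data Data frame with columns `t` (ms, strictly increasing), `y`,
#'   and optionally `sem` (weights `1/sem^2`). At least 4 points.
#' @return A `syn_fit` with coefficients `y_0`, `y_inf`, `tau`, plus
#'   `r_squared`, `aic`, `converged` and diagnostic `flags`.
#'   Non-convergence and degenerate inputs are flagged, not thrown.
#' @examples
#' t <- c(20, 50, 100, 300, 1000, 3000, 10000)
#' fit_exponential_recovery(
#'   data.frame(t = t, y = 2.5 - 1.6 * exp(-t / 2400))
#' )
#' @export
fit_exponential_recovery <- function(data) {
  data <- check_timeseries(data, 4)
  if (stats::sd(data$y) < .Machine$double.eps^0.5) {
    return(failed_fit("exp_recovery", data, "unidentifiable_constant_series"))
  }
  w <- fit_weights(data)
  y_inf0 <- data$y[which.max(data$t)]
  tau0 <- init_tau(data$t, data$y, y_inf0)
  model <- function(p, t) p["yinf"] - (p["yinf"] - p["y0"]) * exp(-t / p["tau"])
  cf <- lm_multistart(
    data, w, model,
    starts = lapply(c(1, 0.3, 3), function(f) {
      c(y0 = data$y[1], yinf = y_inf0, tau = tau0 * f)
    }),
    lower = c(y0 = -Inf, yinf = -Inf, tau = 1e-9)
  )
  if (is.null(cf)) {
    return(failed_fit("exp_recovery", data, "non_convergence"))
  }
  fitted <- cf["yinf"] - (cf["yinf"] - cf["y0"]) * exp(-data$t / cf["tau"])
  st <- fit_stats(data$y, fitted, 3)
  flags <- character()
  if (cf["yinf"] < cf["y0"]) flags <- c(flags, "decreasing_recovery")
  new_syn_fit("exp_recovery",
              c(y_0 = unname(cf["y0"]), y_inf = unname(cf["yinf"]),
                tau = unname(cf["tau"])),
              tau = unname(cf["tau"]), data = data, fitted = fitted,
              r_squared = st$r2, aic = st$aic, rss = st$rss,
              converged = TRUE, flags = flags)
}

#' Fit a single-exponential decay from the observed peak
#'
#' `y(t) = y_inf + (y_0 - y_inf) * exp(-(t - t_peak) / tau)` with `t_peak`
#' fixed at the first point of the series. Used for the resolution of
#' adherens-junction pits after their 300 ms peak.
#'
#' @inheritParams fit_exponential_recovery
#' @return A `syn_fit` with coefficients `y_0`, `y_inf`, `tau`. An
#'   increasing series is fitted but flagged `negative_rate`.
#' @export
fit_exponential_decay <- function(data) {
  data <- check_timeseries(data, 4)
  if (stats::sd(data$y) < .Machine$double.eps^0.5) {
    return(failed_fit("exp_decay", data, "unidentifiable_constant_series"))
  }
  t0 <- data$t[1]
  w <- fit_weights(data)
  y_inf0 <- min(data$y)
  tau0 <- init_tau(data$t - t0, -data$y, -y_inf0)
  # deterministic multi-start over the initial tau: the log-linear guess can
  # land far off when late points sit at zero
  model <- function(p, t) {
    p["yinf"] + (p["y0"] - p["yinf"]) * exp(-(t - t0) / p["tau"])
  }
  cf <- lm_multistart(
    data, w, model,
    starts = lapply(c(1, 0.1, 0.02, 5), function(f) {
      c(y0 = data$y[1], yinf = y_inf0, tau = tau0 * f)
    }),
    lower = c(y0 = -Inf, yinf = -Inf, tau = 1e-9)
  )
  if (is.null(cf)) {
    return(failed_fit("exp_decay", data, "non_convergence"))
  }
  fitted <- cf["yinf"] + (cf["y0"] - cf["yinf"]) * exp(-(data$t - t0) / cf["tau"])
  st <- fit_stats(data$y, fitted, 3)
  flags <- character()
  if (cf["y0"] < cf["yinf"]) flags <- c(flags, "negative_rate")
  new_syn_fit("exp_decay",
              c(y_0 = unname(cf["y0"]), y_inf = unname(cf["yinf"]),
                tau = unname(cf["tau"]), t_peak = t0),
              tau = unname(cf["tau"]), data = data, fitted = fitted,
              r_squared = st$r2, aic = st$aic, rss = st$rss,
              converged = TRUE, flags = flags)
}

# k-term saturating-exponential fit of ratio data (asymptote fixed at 1):
# y = 1 - sum_i A_i exp(-t / tau_i). Used with k = 2 for paired-pulse
# recovery; k = 1 is the nested single-term model.
fit_ratio_recovery <- function(data, k = 2) {
  w <- fit_weights(data)
  tr <- range(data$t)
  depth <- max(1 - data$y[1], 0.1)
  base_taus <- if (k == 2) c(tr[1] * 2, tr[2] / 3) else tr[2] / 3
  base_amps <- rep(depth / k, k)
  # deterministic multi-start: perturb the starting taus over a log grid
  perturb <- if (k == 2) {
    list(c(1, 1), c(0.3, 1), c(3, 1), c(1, 0.3), c(1, 3))
  } else {
    list(1, 0.3, 3, 0.1, 10)
  }
  if (k == 2) {
    model <- function(p, t) {
      1 - p["a1"] * exp(-t / p["tau1"]) - p["a2"] * exp(-t / p["tau2"])
    }
    starts <- lapply(perturb, function(pf) {
      c(a1 = base_amps[1], a2 = base_amps[2],
        tau1 = base_taus[1] * pf[1], tau2 = base_taus[2] * pf[2])
    })
    lower <- c(a1 = 0, a2 = 0, tau1 = 1e-9, tau2 = 1e-9)
  } else {
    model <- function(p, t) 1 - p["a1"] * exp(-t / p["tau1"])
    starts <- lapply(perturb, function(pf) {
      c(a1 = sum(base_amps), tau1 = base_taus[1] * pf[1])
    })
    lower <- c(a1 = 0, tau1 = 1e-9)
  }
  cf <- lm_multistart(data, w, model, starts, lower)
  if (is.null(cf)) return(NULL)
  list(coef = cf, rss = sum((data$y - model(cf, data$t))^2))
}

#' Fit a double-exponential paired-pulse recovery
#'
#' `y(t) = 1 - A_f * exp(-t / tau_f) - A_s * exp(-t / tau_s)` with
#' non-negative amplitudes, fitted by Levenberg-Marquardt from five
#' deterministic multi-start initializations; components are ordered so
#' `tau_f < tau_s` after fitting. Used for the ratio of the second to the
#' first evoked response as a function of the inter-pulse interval.
#'
#' @param data Data frame with columns `t` (ms), `y` (P_i/P_1 ratios),
#'   optional `sem`. At least 6 points spanning both time scales.
#' @return A `syn_fit` with coefficients `A_f`, `tau_f`, `A_s`, `tau_s`;
#'   `tau` holds `c(tau_f, tau_s)`. On data generated from a
#'   single-exponential truth, one amplitude fits to ~0.
#' @export
fit_double_exponential_recovery <- function(data) {
  data <- check_timeseries(data, 6)
  if (stats::sd(data$y) < .Machine$double.eps^0.5) {
    return(failed_fit("double_exp_recovery", data,
                      "unidentifiable_constant_series"))
  }
  best <- fit_ratio_recovery(data, k = 2)
  if (is.null(best)) {
    return(failed_fit("double_exp_recovery", data, "non_convergence"))
  }
  cf <- best$coef
  amps <- c(cf["a1"], cf["a2"])
  taus <- c(cf["tau1"], cf["tau2"])
  ord <- order(taus)
  amps <- amps[ord]; taus <- taus[ord]
  fitted <- 1 - amps[1] * exp(-data$t / taus[1]) -
    amps[2] * exp(-data$t / taus[2])
  st <- fit_stats(data$y, fitted, 4)
  flags <- character()
  if (min(amps) < 1e-4) flags <- c(flags, "component_amplitude_near_zero")
  new_syn_fit("double_exp_recovery",
              c(A_f = unname(amps[1]), tau_f = unname(taus[1]),
                A_s = unname(amps[2]), tau_s = unname(taus[2])),
              tau = unname(taus), data = data, fitted = fitted,
              r_squared = st$r2, aic = st$aic, rss = st$rss,
              converged = TRUE, flags = flags)
}

#' Bootstrap confidence intervals for a fitted kinetic model
#'
#' Resamples residuals with replacement, refits, and reports percentile
#' intervals for every coefficient.
#'
#' @param fit A converged `syn_fit`.
#' @param n_boot Number of bootstrap draws (default 1000).
#' @param seed Integer seed for the resampling.
#' @param level Interval level (default 0.95).
#' @return Tibble with `term`, `estimate`, `conf_low`, `conf_high`,
#'   `n_boot_converged`.
#' @export
bootstrap_ci <- function(fit, n_boot = 1000, seed = 1, level = 0.95) {
  stopifnot(inherits(fit, "syn_fit"), isTRUE(fit$converged))
  refit <- switch(fit$model,
                  exp_recovery = fit_exponential_recovery,
                  exp_decay = fit_exponential_decay,
                  double_exp_recovery = fit_double_exponential_recovery)
  draws <- with_local_seed(seed, {
    purrr::map(seq_len(n_boot), function(i) {
      d <- fit$data
      d$y <- fit$fitted + sample(fit$residuals, length(fit$residuals),
                                 replace = TRUE)
      f <- refit(d)
      if (isTRUE(f$converged)) f$coefficients else NULL
    })
  })
  draws <- purrr::compact(draws)
  mat <- do.call(rbind, draws)
  a <- (1 - level) / 2
  tibble::tibble(
    term = names(fit$coefficients),
    estimate = unname(fit$coefficients),
    conf_low = apply(mat, 2, stats::quantile, probs = a, na.rm = TRUE),
    conf_high = apply(mat, 2, stats::quantile, probs = 1 - a, na.rm = TRUE),
    n_boot_converged = length(draws)
  )
}

#' @export
print.syn_fit <- function(x, ...) {
  cat("<syn_fit> model: ", x$model, "\n", sep = "")
  if (x$converged) {
    cat("  ", paste(sprintf("%s = %.4g", names(x$coefficients),
                            x$coefficients), collapse = ", "), "\n", sep = "")
    cat(sprintf("  R^2 = %.4f, AIC = %.2f, n = %d\n",
                x$r_squared, x$aic, x$n))
  } else {
    cat("  did not converge\n")
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.syn_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
glance.syn_fit <- function(x, ...) {
  tibble::tibble(model = x$model, r_squared = x$r_squared, aic = x$aic,
                 rss = x$rss, n = x$n, converged = x$converged,
                 flags = paste(x$flags, collapse = ";"))
}
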