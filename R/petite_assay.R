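#' Call petite colonies by area threshold
#'
#' A colony is called petite when its area is strictly below the threshold
#' (the conventional cutoff is 1.5 mm^2, chosen so that both assayed strains
#' have fewer than 50% respiring false-positives beneath it).
#'
#' @param colonies A tibble with column `area_mm2` (> 0), e.g. from
#'   [generate_colony_areas()] or [read_colony_csv()].
#' @param threshold_mm2 Petite area cutoff in mm^2 (strict `<`).
#' @return The input tibble with a logical `petite_call` column appended.
#' @examples
#' call_petite(tibble::tibble(area_mm2 = c(0.8, 1.49, 1.5, 3)))
#' @export
call_petite <- function(colonies, threshold_mm2 = 1.5) {
  check_columns(colonies, "area_mm2", "colonies")
  check_finite_scalar(threshold_mm2, "threshold_mm2", lower = 0)
  if (any(!is.finite(colonies$area_mm2)) || any(colonies$area_mm2 <= 0)) {
    stop_validation("colony areas must be positive and finite.")
  }
  dplyr::mutate(colonies, petite_call = .data$area_mm2 < threshold_mm2)
}

#' Calibrate the petite area threshold from labelled colonies
#'
#' Scans candidate cutoffs at midpoints between sorted distinct areas. A
#' candidate is feasible when, for every strain, the fraction of respiring
#' colonies among those below the cutoff is below `max_fp` (strains with no
#' colony below a candidate are vacuously feasible). Among feasible
#' candidates the one minimising the number of non-respiring colonies at or
#' above the cutoff (false negatives) is returned; ties go to the smallest
#' threshold.
#'
#' @param colonies A tibble with columns `strain`, `area_mm2` and a logical
#'   `respiring` label; both label classes must be present.
#' @param max_fp Maximum tolerated respiring false-positive fraction below
#'   the cutoff, per strain (default 0.5).
#' @return A `threshold_calibration` list: `threshold_mm2`, per-strain
#'   `diagnostics` (false-positive fraction below, false-negative count
#'   above), and the scanned `candidates` tibble.
#' @examples
#' colonies <- generate_colony_areas(200, petite_fraction = 0.3, seed = 1)
#' calibrate_threshold(colonies)
#' @export
calibrate_threshold <- function(colonies, max_fp = 0.5) {
  check_columns(colonies, c("strain", "area_mm2", "respiring"), "colonies")
  check_finite_scalar(max_fp, "max_fp", lower = 0, upper = 1)
  if (any(!is.finite(colonies$area_mm2)) || any(colonies$area_mm2 <= 0)) {
    stop_validation("colony areas must be positive and finite.")
  }
  resp <- colonies$respiring
  if (anyNA(resp) || !is.logical(resp)) {
    stop_validation("`respiring` must be logical without NA for calibration.")
  }
  if (all(resp) || all(!resp)) {
    rlang::abort(
      "calibration failure: both respiring and non-respiring colonies are required.",
      class = "rhozero_calibration_failure_error"
    )
  }
  areas <- sort(unique(colonies$area_mm2))
  if (length(areas) < 2) {
    rlang::abort("calibration failure: need at least two distinct areas.",
                 class = "rhozero_calibration_failure_error")
  }
  cands <- (head(areas, -1) + tail(areas, -1)) / 2

  strain_rows <- split(seq_len(nrow(colonies)), colonies$strain)
  eval_cut <- function(cut) {
    below <- colonies$area_mm2 < cut
    fps <- vapply(strain_rows, function(ri) {
      nb <- sum(below[ri])
      if (nb == 0) 0 else sum(resp[ri] & below[ri]) / nb
    }, numeric(1))
    list(
      feasible = all(fps < max_fp),
      max_fp_below = max(fps),
      fn_above = sum(!resp & !below)
    )
  }
  evals <- purrr::map(cands, eval_cut)
  cand_tbl <- tibble(
    threshold_mm2 = cands,
    feasible = purrr::map_lgl(evals, "feasible"),
    max_fp_below = purrr::map_dbl(evals, "max_fp_below"),
    fn_above = purrr::map_int(evals, ~ as.integer(.x$fn_above))
  )
  feas <- cand_tbl[cand_tbl$feasible, ]
  if (nrow(feas) == 0) {
    best_infeasible <- cand_tbl[order(cand_tbl$max_fp_below,
                                      cand_tbl$fn_above,
                                      cand_tbl$threshold_mm2), ][1, ]
    rlang::abort(
      sprintf(
        "calibration failure: no cutoff keeps the respiring false-positive fraction below %.2f for every strain (best infeasible candidate: %.4g mm^2).",
        max_fp, best_infeasible$threshold_mm2
      ),
      class = "rhozero_calibration_failure_error",
      best_candidate = best_infeasible
    )
  }
  best <- feas[order(feas$fn_above, feas$threshold_mm2), ][1, ]
  diagnostics <- dplyr::summarise(
    dplyr::group_by(colonies, .data$strain),
    n = dplyr::n(),
    n_below = sum(.data$area_mm2 < best$threshold_mm2),
    fp_fraction_below = {
      b <- .data$area_mm2 < best$threshold_mm2
      if (sum(b) == 0) 0 else sum(.data$respiring & b) / sum(b)
    },
    fn_above = sum(!.data$respiring & .data$area_mm2 >= best$threshold_mm2),
    .groups = "drop"
  )
  structure(
    list(threshold_mm2 = best$threshold_mm2,
         diagnostics = diagnostics,
         candidates = cand_tbl),
    class = "threshold_calibration"
  )
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf("<threshold_calibration> cutoff = %.4g mm^2\n", x$threshold_mm2))
  print(x$diagnostics)
  invisible(x)
}

#' Summarise petite fractions by group
#'
#' For each (genotype, time) group: the population-weighted mean petite
#' fraction (total petites over total colonies across replicates) and the
#' unweighted SEM of the per-replicate fractions (sample SD / sqrt(k)).
#' With a single replicate the SEM is undefined and returned as NA with
#' `sem_defined = FALSE` rather than fabricated.
#'
#' @param series A tibble with columns `genotype`, `time_h`, `replicate_id`,
#'   `n_total`, `n_petite`.
#' @return A tibble with one row per (genotype, time): `weighted_mean`,
#'   `mean_fraction` (simple mean), `sem`, `sem_defined`, `n_replicates`,
#'   `n_colonies`.
#' @examples
#' p <- two_state_params(0.4, 0.4, 0.15)
#' series <- generate_petite_time_series(p, seed = 1)
#' petite_fraction_summary(series)
#' @export
petite_fraction_summary <- function(series) {
  check_columns(series, c("genotype", "time_h", "replicate_id",
                          "n_total", "n_petite"), "series")
  if (nrow(series) == 0) {
    stop_validation("`series` is empty.")
  }
  if (any(series$n_total <= 0) || any(series$n_petite < 0) ||
      any(series$n_petite > series$n_total)) {
    stop_validation("counts must satisfy 0 <= n_petite <= n_total, n_total > 0.")
  }
  dplyr::summarise(
    dplyr::group_by(series, .data$genotype, .data$time_h),
    weighted_mean = sum(.data$n_petite) / sum(.data$n_total),
    mean_fraction = mean(.data$n_petite / .data$n_total),
    sem = if (dplyr::n() > 1) {
      sd(.data$n_petite / .data$n_total) / sqrt(dplyr::n())
    } else {
      NA_real_
    },
    sem_defined = dplyr::n() > 1,
    n_replicates = dplyr::n(),
    n_colonies = sum(.data$n_total),
    .groups = "drop"
  )
}

# model petite fraction at times t for loss rate r and baseline fraction f0;
# inlined closed form (no tibble construction) - this sits inside the
# bootstrap's objective function
loss_model_fraction <- function(t, r, f0, g_wt, g_mut) {
  a <- g_wt - r
  b <- g_mut
  p_wt <- (1 - f0) * exp(a * t)
  p_mut <- f0 * exp(b * t) + r * (1 - f0) * exp(b * t) * phi_expm1(a - b, t)
  p_mut / (p_wt + p_mut)
}

#' Estimate the mtDNA loss rate from a petite time series
#'
#' Fits the two-state model's mutant fraction \eqn{f(t; r, f_0)} to observed
#' petite fractions by weighted least squares (weights = colonies counted,
#' i.e. binomial precision weights), with `r` constrained to `[0, g_wt]`.
#' The measured petite fraction is identified with the population mutant
#' fraction at plating. A binomial maximum-likelihood fit is available via
#' `method = "ml"`. Confidence intervals come from a case-resampling
#' bootstrap over biological replicates (percentile intervals).
#'
#' No correction is applied for colonies founded by cells that lost mtDNA
#' after plating; see the package vignette.
#'
#' @param series A tibble with columns `replicate_id`, `time_h`, `n_total`,
#'   `n_petite`; at least 3 distinct timepoints.
#' @param g_wt,g_mut Growth constants (per hour) of rho+ and rho0 cells,
#'   typically estimated with [fit_exponential_rate()].
#' @param fit_f0 Fit the baseline fraction `f0` (default) or fix it.
#' @param f0 Baseline fraction used when `fit_f0 = FALSE`.
#' @param method `"wls"` (weighted least squares, default) or `"ml"`
#'   (binomial maximum likelihood).
#' @param n_boot Bootstrap resamples (default 1000); 0 skips the CI.
#' @param conf_level Bootstrap CI level (default 0.90).
#' @param ci_method `"expanded_percentile"` (default) widens the percentile
#'   quantiles with the small-sample t adjustment
#'   \eqn{\alpha'/2 = \Phi(-\sqrt{k/(k-1)}\, t_{k-1,\,1-\alpha/2})} so the
#'   interval attains close to its nominal level with few replicates;
#'   `"percentile"` uses the plain percentile interval, which is too
#'   narrow when only a handful of replicates are resampled.
#' @param seed Optional integer seed for the bootstrap.
#' @return A `loss_rate_fit` object with `r_hat` (per hour), `f0_hat`,
#'   percentile CI, convergence and boundary flags, and the bootstrap
#'   draws. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' p <- two_state_params(0.4, 0.4, 0.15)
#' series <- generate_petite_time_series(p, seed = 1)
#' fit <- estimate_loss_rate(series, g_wt = 0.4, g_mut = 0.4,
#'                           n_boot = 100, seed = 2)
#' glance(fit)
#' @export
estimate_loss_rate <- function(series, g_wt = 0.4, g_mut = 0.2,
                               fit_f0 = TRUE, f0 = 0,
                               method = c("wls", "ml"),
                               n_boot = 1000, conf_level = 0.90,
                               ci_method = c("expanded_percentile",
                                             "percentile"),
                               seed = NULL) {
  check_columns(series, c("replicate_id", "time_h", "n_total", "n_petite"),
                "series")
  method <- match.arg(method)
  ci_method <- match.arg(ci_method)
  check_finite_scalar(g_wt, "g_wt")
  check_finite_scalar(g_mut, "g_mut")
  if (length(unique(series$time_h)) < 3) {
    stop_validation("need at least 3 distinct timepoints to fit a loss rate.")
  }
  if (any(series$n_total <= 0) || any(series$n_petite < 0) ||
      any(series$n_petite > series$n_total)) {
    stop_validation("counts must satisfy 0 <= n_petite <= n_total, n_total > 0.")
  }

  fit1 <- fit_loss_rate_once(series, g_wt, g_mut, fit_f0, f0, method)
  boundary <- fit1$r_hat <= 1e-10 || fit1$r_hat >= g_wt - 1e-10
  if (boundary) {
    rlang::warn("loss-rate estimate lies on the constraint boundary.",
                class = "rhozero_boundary_warning")
  }

  ci <- c(NA_real_, NA_real_)
  boot_r <- numeric(0)
  if (n_boot > 0) {
    reps <- unique(series$replicate_id)
    split_reps <- split(series, series$replicate_id)
    boot_r <- with_seed_or_current(seed, vapply(seq_len(n_boot), function(i) {
      take <- sample(reps, length(reps), replace = TRUE)
      bs <- dplyr::bind_rows(split_reps[take], .id = NULL)
      fit_loss_rate_once(bs, g_wt, g_mut, fit_f0, f0, method)$r_hat
    }, numeric(1)))
    alpha <- (1 - conf_level) / 2
    if (ci_method == "expanded_percentile") {
      k <- length(reps)
      alpha <- stats::pnorm(-sqrt(k / (k - 1)) * stats::qt(1 - alpha, k - 1))
    }
    ci <- unname(quantile(boot_r, c(alpha, 1 - alpha), names = FALSE))
  }

  structure(
    list(r_hat = fit1$r_hat, f0_hat = fit1$f0_hat,
         ci_lower = ci[1], ci_upper = ci[2], conf_level = conf_level,
         ci_method = ci_method,
         n_boot = n_boot, seed = seed, method = method,
         boundary = boundary, convergence = fit1$convergence,
         objective = fit1$objective, g_wt = g_wt, g_mut = g_mut,
         fit_f0 = fit_f0, boot_r = boot_r, series = series),
    class = "loss_rate_fit"
  )
}

fit_loss_rate_once <- function(series, g_wt, g_mut, fit_f0, f0_fixed, method) {
  t <- series$time_h
  n <- series$n_total
  k <- series$n_petite
  fobs <- k / n

  objective <- function(par) {
    r <- par[1]
    f0 <- if (fit_f0) par[2] else f0_fixed
    fm <- loss_model_fraction(t, r, f0, g_wt, g_mut)
    if (method == "wls") {
      sum(n * (fobs - fm)^2)
    } else {
      fm <- pmin(pmax(fm, 1e-12), 1 - 1e-12)
      -sum(k * log(fm) + (n - k) * log(1 - fm))
    }
  }

  # crude initial slope of the weighted mean fraction; a few starts guard
  # against local minima on the bounded surface
  wmean0 <- sum(k[t == min(t)]) / sum(n[t == min(t)])
  span <- max(t) - min(t)
  slope0 <- max((sum(k[t == max(t)]) / sum(n[t == max(t)]) - wmean0) / span, 0)
  r_starts <- unique(pmin(pmax(c(slope0, 0.05, g_wt / 2), 1e-4), g_wt - 1e-4))
  f0_start <- min(max(wmean0, 1e-4), 0.99)

  best <- NULL
  for (r0 in r_starts) {
    par0 <- if (fit_f0) c(r0, f0_start) else r0
    lower <- if (fit_f0) c(0, 0) else 0
    upper <- if (fit_f0) c(g_wt, 0.999) else g_wt
    res <- tryCatch(
      optim(par0, objective, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(factr = 10, maxit = 500)),
      error = function(e) NULL
    )
    if (!is.null(res) && (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }
  if (is.null(best)) {
    rlang::abort("loss-rate fit failed to converge from any start.",
                 class = "rhozero_convergence_error")
  }
  list(
    r_hat = best$par[1],
    f0_hat = if (fit_f0) best$par[2] else f0_fixed,
    convergence = best$convergence,
    objective = best$value
  )
}

#' @export
print.loss_rate_fit <- function(x, ...) {
  cat("<loss_rate_fit>\n")
  cat(sprintf("  r_hat = %.4f /h  (f0 = %.4f, %s fit)\n",
              x$r_hat, x$f0_hat, x$method))
  if (!is.na(x$ci_lower)) {
    cat(sprintf("  %d%% bootstrap CI: [%.4f, %.4f]  (%d resamples)\n",
                round(100 * x$conf_level), x$ci_lower, x$ci_upper, x$n_boot))
  }
  if (x$boundary) cat("  note: estimate on constraint boundary\n")
  invisible(x)
}

#' @rdname estimate_loss_rate
#' @param x A `loss_rate_fit` object.
#' @param ... Unused.
#' @export
tidy.loss_rate_fit <- function(x, ...) {
  tibble(
    term = c("r", "f0"),
    estimate = c(x$r_hat, x$f0_hat),
    conf.low = c(x$ci_lower, NA_real_),
    conf.high = c(x$ci_upper, NA_real_)
  )
}

#' @rdname estimate_loss_rate
#' @export
glance.loss_rate_fit <- function(x, ...) {
  tibble(
    r_hat = x$r_hat, f0_hat = x$f0_hat,
    ci_lower = x$ci_lower, ci_upper = x$ci_upper,
    conf_level = x$conf_level, n_boot = x$n_boot,
    method = x$method, boundary = x$boundary,
    nobs = nrow(x$series)
  )
}
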