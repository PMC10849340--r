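#' Parameters of the two-state mtDNA loss model
#'
#' The model describes a growing population in which respiring (rho+) cells
#' divide with exponential growth constant `g_wt` (per hour, natural log) and
#' lose their mitochondrial genome at a constant per-cell rate `r` (per hour),
#' converting into rho0 cells that divide with growth constant `g_mut`.
#' Conversion conserves the cell: a rho+ cell becomes a rho0 cell, so the
#' instantaneous per-capita growth rate of the whole population is the
#' mutant-fraction-weighted average of `g_wt` and `g_mut`.
#'
#' The governing equations are
#' \deqn{dP_{wt}/dt = (g_{wt} - r) P_{wt}}
#' \deqn{dP_{mut}/dt = g_{mut} P_{mut} + r P_{wt}}
#'
#' @param g_wt Growth constant of rho+ (mtDNA-intact) cells, per hour.
#' @param g_mut Growth constant of rho0 (mtDNA-less) cells, per hour.
#' @param r mtDNA loss (rho+ to rho0 conversion) rate per rho+ cell, per hour.
#'   Must be non-negative.
#' @param p_wt0,p_mut0 Initial rho+ and rho0 abundances (cells, >= 0, at
#'   least one positive).
#'
#' @return An object of class `two_state_params`: a named list of the five
#'   parameters.
#' @examples
#' two_state_params(g_wt = 0.5, g_mut = 0.3, r = 0.05)
#' @export
two_state_params <- function(g_wt, g_mut, r, p_wt0 = 1, p_mut0 = 0) {
  check_finite_scalar(g_wt, "g_wt")
  check_finite_scalar(g_mut, "g_mut")
  check_finite_scalar(r, "r", lower = 0)
  check_finite_scalar(p_wt0, "p_wt0", lower = 0)
  check_finite_scalar(p_mut0, "p_mut0", lower = 0)
  if (p_wt0 + p_mut0 <= 0) {
    stop_validation("`p_wt0 + p_mut0` must be positive.")
  }
  structure(
    list(g_wt = g_wt, g_mut = g_mut, r = r, p_wt0 = p_wt0, p_mut0 = p_mut0),
    class = "two_state_params"
  )
}

#' @export
print.two_state_params <- function(x, ...) {
  cat("<two_state_params>\n")
  cat(sprintf("  g_wt  = %g /h   g_mut = %g /h   r = %g /h\n",
              x$g_wt, x$g_mut, x$r))
  cat(sprintf("  p_wt0 = %g      p_mut0 = %g\n", x$p_wt0, x$p_mut0))
  invisible(x)
}

as_two_state_params <- function(x) {
  if (inherits(x, "two_state_params")) return(x)
  if (is.list(x) && all(c("g_wt", "g_mut", "r") %in% names(x))) {
    return(two_state_params(
      g_wt = x$g_wt, g_mut = x$g_mut, r = x$r,
      p_wt0 = if (is.null(x$p_wt0)) 1 else x$p_wt0,
      p_mut0 = if (is.null(x$p_mut0)) 0 else x$p_mut0
    ))
  }
  stop_validation("`params` must be a `two_state_params` object or a list with g_wt, g_mut, r.")
}

# phi(k, t) = (exp(k t) - 1) / k, evaluated stably.
# For |k| below the cancellation guard the exact limit t * exp(k t / 2)-style
# series is used; elsewhere expm1 keeps the small-gap branch accurate.
phi_expm1 <- function(k, t, guard = 1e-9) {
  if (abs(k) < guard) {
    kt <- k * t
    t * (1 + kt / 2 + kt^2 / 6)
  } else {
    expm1(k * t) / k
  }
}

#' Closed-form solution of the two-state model
#'
#' Solves the linear system analytically:
#' \deqn{P_{wt}(t) = P_{wt}(0) e^{(g_{wt}-r)t}}
#' \deqn{P_{mut}(t) = P_{mut}(0) e^{g_{mut} t} +
#'   r P_{wt}(0) e^{g_{mut} t} \frac{e^{(g_{wt}-r-g_{mut})t} - 1}{g_{wt}-r-g_{mut}}}
#' with the degenerate limit \eqn{r P_{wt}(0) t e^{g_{mut} t}} when
#' \eqn{g_{wt} - r = g_{mut}}. The ratio term is evaluated through `expm1`
#' when the gap is small to avoid catastrophic cancellation.
#'
#' @param params A [two_state_params()] object (or compatible list).
#' @param times Numeric vector of times in hours, non-negative.
#'
#' @return A tibble of class `population_trajectory` with columns `time_h`,
#'   `p_wt`, `p_mut` and the mutant fraction `f` (NA where the total
#'   abundance is zero).
#' @examples
#' p <- two_state_params(0.5, 0.25, 0.05)
#' solve_closed_form(p, times = 0:10)
#' @export
solve_closed_form <- function(params, times) {
  params <- as_two_state_params(params)
  check_times(times)
  a <- params$g_wt - params$r # effective rho+ rate
  b <- params$g_mut
  p_wt <- params$p_wt0 * exp(a * times)
  phi <- phi_expm1(a - b, times)
  p_mut <- params$p_mut0 * exp(b * times) +
    params$r * params$p_wt0 * exp(b * times) * phi
  total <- p_wt + p_mut
  f <- ifelse(total > 0, p_mut / total, NA_real_)
  new_trajectory(tibble(time_h = times, p_wt = p_wt, p_mut = p_mut, f = f))
}

new_trajectory <- function(df) {
  class(df) <- c("population_trajectory", class(df))
  df
}

#' Mutant (rho0) fraction at given times
#'
#' @inheritParams solve_closed_form
#' @param t Time(s) in hours, non-negative.
#' @return Numeric vector of mutant fractions in `[0, 1]`.
#' @examples
#' mutant_fraction_at(two_state_params(0.5, 0.3, 0.05), t = c(0, 10, 200))
#' @export
mutant_fraction_at <- function(params, t) {
  traj <- solve_closed_form(params, t)
  if (anyNA(traj$f)) {
    rlang::abort("Mutant fraction is undefined: total abundance is zero.",
                 class = "rhozero_undefined_fraction_error")
  }
  traj$f
}

#' Equilibrium mutant fraction
#'
#' Under coexistence (`g_wt - r > g_mut`) the rho+ subpopulation outgrows the
#' conversion flux and the mutant fraction settles at
#' \eqn{f^* = r / (g_{wt} - g_{mut})}; otherwise the mutant fixes
#' (\eqn{f^* = 1}).
#'
#' @inheritParams solve_closed_form
#' @return A single fraction in `[0, 1]`.
#' @examples
#' equilibrium_fraction(two_state_params(0.5, 0.3, 0.05)) # 0.25
#' @export
equilibrium_fraction <- function(params) {
  params <- as_two_state_params(params)
  if (params$g_wt - params$r > params$g_mut) {
    params$r / (params$g_wt - params$g_mut)
  } else {
    1
  }
}

#' Instantaneous per-capita population growth rate
#'
#' Because conversion conserves cells, the total obeys
#' \eqn{dT/dt = g_{wt} P_{wt} + g_{mut} P_{mut}}, i.e. the per-capita rate is
#' the mutant-fraction-weighted average \eqn{(1-f) g_{wt} + f g_{mut}}. At
#' equilibrium this equals \eqn{(1-f^*) g_{wt} + f^* g_{mut} = g_{wt} - r}.
#'
#' @inheritParams mutant_fraction_at
#' @return Per-hour rate(s), same length as `t`.
#' @export
population_growth_rate <- function(params, t) {
  params <- as_two_state_params(params)
  f <- mutant_fraction_at(params, t)
  (1 - f) * params$g_wt + f * params$g_mut
}

#' Classify the long-run regime of the model
#'
#' Coexistence requires the effective rho+ growth rate to exceed the mutant
#' rate strictly (`g_wt - r > g_mut`); the boundary case is classified as
#' fixation (no finite equilibrium).
#'
#' @inheritParams solve_closed_form
#' @return A one-row tibble with `regime` ("COEXISTENCE" or "FIXATION"), the
#'   equilibrium fraction `f_star`, and the long-run per-capita
#'   `growth_rate` (`max(g_wt - r, g_mut)`, per hour).
#' @examples
#' classify_regime(two_state_params(0.5, 0.3, 0.05))
#' @export
classify_regime <- function(params) {
  params <- as_two_state_params(params)
  f_star <- equilibrium_fraction(params)
  tibble(
    regime = if (f_star < 1) "COEXISTENCE" else "FIXATION",
    f_star = f_star,
    growth_rate = max(params$g_wt - params$r, params$g_mut)
  )
}

#' Sweep the mutant fraction over a parameter grid
#'
#' Recomputes the trajectory for each value of a single varied parameter
#' (the loss rate `r` or the mutant growth constant `g_mut`), holding the
#' remaining parameters at their base values.
#'
#' @param base A [two_state_params()] object used for the non-varied fields.
#' @param vary Which parameter to vary: `"r"` or `"g_mut"`.
#' @param values Numeric vector of values for the varied parameter.
#' @param times Times (hours) at which to evaluate the mutant fraction.
#' @return A tibble in long format with columns `value` (the varied
#'   parameter), `time_h` and `f`. At fixed time, `f` is non-decreasing in
#'   either varied parameter.
#' @examples
#' base <- two_state_params(0.5, 0.25, 0.02)
#' sweep_fraction_grid(base, "r", c(0, 0.05, 0.1, 0.2), times = 0:24)
#' @export
sweep_fraction_grid <- function(base, vary = c("r", "g_mut"), values, times) {
  base <- as_two_state_params(base)
  vary <- match.arg(vary)
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop_validation("`values` must be finite numeric.")
  }
  if (vary == "r" && any(values < 0)) {
    stop_validation("loss rates must be non-negative.")
  }
  check_times(times)
  purrr::map_dfr(values, function(v) {
    p <- base
    p[[vary]] <- v
    traj <- solve_closed_form(p, times)
    tibble(value = v, time_h = traj$time_h, f = traj$f)
  })
}

#' Convert natural-log growth constants to doublings per hour
#'
#' Reporting-layer helper: rates are carried internally as natural-log
#' constants per hour; dividing by `log(2)` expresses them as doublings/hour.
#'
#' @param rate Natural-log growth constant(s), per hour.
#' @return Doublings per hour.
#' @export
doublings_per_hour <- function(rate) rate / log(2)

#' Export a trajectory as TSV
#'
#' Writes columns `time_h`, `p_wt`, `p_mut`, `f`.
#'
#' @param trajectory A trajectory tibble from [solve_closed_form()] or
#'   [simulate_population_stochastic()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(trajectory, path) {
  check_columns(trajectory, c("time_h", "p_wt", "p_mut", "f"), "trajectory")
  readr::write_tsv(trajectory[, c("time_h", "p_wt", "p_mut", "f")], path)
  invisible(path)
}
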