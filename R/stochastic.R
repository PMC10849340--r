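#' Exact stochastic simulation of the two-state model
#'
#' Event-driven (Gillespie) counterpart of [solve_closed_form()]. Three event
#' channels act on integer cell counts: rho+ division (rate `g_wt` per rho+
#' cell), rho+ to rho0 conversion (rate `r` per rho+ cell, cell conserved),
#' and rho0 division (rate `g_mut` per rho0 cell). The first moment of the
#' process matches the deterministic closed form; individual runs fluctuate
#' with demographic noise of relative size roughly \eqn{1/\sqrt{N}}.
#'
#' Negative growth constants are not supported here (no death channel); the
#' deterministic solver handles them.
#'
#' @inheritParams solve_closed_form
#' @param t_end End time in hours (>= 0).
#' @param seed Optional integer seed; fixed seed gives an identical
#'   trajectory on rerun.
#' @param cap Population cap; if total abundance reaches `cap` the
#'   simulation stops early with a warning and the trajectory is truncated.
#' @return A `population_trajectory` tibble (columns `time_h`, `p_wt`,
#'   `p_mut`, `f`), one row per event, with attribute `truncated`.
#' @examples
#' p <- two_state_params(0.5, 0.3, 0.05, p_wt0 = 100)
#' sim <- simulate_population_stochastic(p, t_end = 6, seed = 1)
#' tail(sim)
#' @export
simulate_population_stochastic <- function(params, t_end, seed = NULL,
                                           cap = 1e6) {
  params <- as_two_state_params(params)
  check_finite_scalar(t_end, "t_end", lower = 0)
  check_finite_scalar(cap, "cap", lower = 1)
  if (params$g_wt < 0 || params$g_mut < 0) {
    stop_validation("stochastic simulation requires non-negative growth constants.")
  }
  if (params$p_wt0 != round(params$p_wt0) || params$p_mut0 != round(params$p_mut0)) {
    stop_validation("initial abundances must be integers for stochastic simulation.")
  }
  res <- with_seed_or_current(seed, gillespie_two_state_cpp(
    params$g_wt, params$g_mut, params$r,
    params$p_wt0, params$p_mut0, t_end, cap
  ))
  if (isTRUE(res$truncated)) {
    rlang::warn(sprintf(
      "population reached the cap (%g); trajectory truncated at t = %.3f h",
      cap, max(res$time_h)
    ), class = "rhozero_truncation_warning")
  }
  total <- res$p_wt + res$p_mut
  out <- new_trajectory(tibble(
    time_h = res$time_h, p_wt = res$p_wt, p_mut = res$p_mut,
    f = ifelse(total > 0, res$p_mut / total, NA_real_)
  ))
  attr(out, "truncated") <- isTRUE(res$truncated)
  out
}

#' Mutant fraction of a stochastic trajectory at given times
#'
#' Reads the piecewise-constant state of an event-resolved trajectory at
#' arbitrary times (last event at or before each time).
#'
#' @param trajectory A `population_trajectory` from
#'   [simulate_population_stochastic()].
#' @param t Times in hours.
#' @return Mutant fraction(s) at `t`.
#' @export
trajectory_fraction_at <- function(trajectory, t) {
  check_columns(trajectory, c("time_h", "f"), "trajectory")
  idx <- findInterval(t, trajectory$time_h)
  if (any(idx == 0)) {
    stop_validation("`t` precedes the start of the trajectory.")
  }
  trajectory$f[idx]
}
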