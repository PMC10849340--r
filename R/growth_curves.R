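#' Fit an exponential growth constant to an OD600 curve
#'
#' Log-transforms the OD series, selects the linear range, and fits ordinary
#' least squares of `ln(OD)` on time (hours). The linear range is
#' operationalised as the longest contiguous window whose blank-subtracted
#' OD lies within `[od_min, od_max]` and whose log-linear fit reaches
#' `r2_min`, with at least `min_points` points; among equally long windows
#' the earliest is taken.
#'
#' @param curve A tibble with columns `time_min` (strictly increasing) and
#'   `od600`; a `curve_id` column is carried through if present. At least 8
#'   points are required.
#' @param blank Blank absorbance to subtract (OD units). Points at or below
#'   the blank are excluded.
#' @param od_min,od_max Blank-subtracted OD bounds of the linear range.
#'   The lower bound keeps points above read noise; the upper bound stops
#'   before saturation (defaults 0.02 and 0.5).
#' @param r2_min Minimum R-squared of the accepted window (default 0.99).
#' @param min_points Minimum number of points in the window (default 9,
#'   i.e. about 3 hours at 20-minute sampling).
#' @return A `growth_fit` object: rate (per hour, natural log), intercept
#'   (log-OD at window start), the window indices, R-squared, and the data.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' curve <- generate_growth_curve(rate = 0.35, seed = 1)
#' fit <- fit_exponential_rate(curve)
#' glance(fit)
#' @export
fit_exponential_rate <- function(curve, blank = 0, od_min = 0.02,
                                 od_max = 0.5, r2_min = 0.99,
                                 min_points = 9) {
  check_columns(curve, c("time_min", "od600"), "curve")
  if (nrow(curve) < 8) {
    stop_validation("a growth curve needs at least 8 points.")
  }
  check_times(curve$time_min, strictly_increasing = TRUE)
  od_adj <- curve$od600 - blank
  eligible <- is.finite(od_adj) & od_adj >= od_min & od_adj <= od_max & od_adj > 0

  win <- select_linear_window(curve$time_min / 60, od_adj, eligible,
                              r2_min, min_points)
  if (is.null(win)) {
    rlang::abort(
      "no linear range: no contiguous window satisfies the OD bounds and R^2 threshold.",
      class = "rhozero_no_linear_range_error"
    )
  }
  idx <- win$start:win$end
  t_h <- curve$time_min[idx] / 60
  y <- log(od_adj[idx])
  fit <- lm(y ~ t_h)
  structure(
    list(
      rate = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      rate_se = suppressWarnings(summary(fit)$coefficients[2, 2]),
      window = c(start = win$start, end = win$end),
      r_squared = win$r2,
      n_points = length(idx),
      curve_id = if ("curve_id" %in% names(curve)) curve$curve_id[1] else NA_character_,
      blank = blank,
      data = curve
    ),
    class = "growth_fit"
  )
}

# longest contiguous eligible window with R^2 >= r2_min; O(n^2) scan with
# prefix sums (curves have at most a few hundred points)
select_linear_window <- function(t_h, od_adj, eligible, r2_min, min_points) {
  runs <- rle(eligible)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  best <- NULL
  for (k in which(runs$values & runs$lengths >= min_points)) {
    s0 <- starts[k]; e0 <- ends[k]
    x <- t_h[s0:e0]
    y <- log(od_adj[s0:e0])
    L <- length(x)
    cx <- cumsum(x); cy <- cumsum(y)
    cxx <- cumsum(x^2); cyy <- cumsum(y^2); cxy <- cumsum(x * y)
    seg <- function(c, i, j) c[j] - if (i > 1) c[i - 1] else 0
    for (len in seq(L, min_points)) {
      if (!is.null(best) && len <= best$len) break
      for (i in seq_len(L - len + 1)) {
        j <- i + len - 1
        n <- len
        sx <- seg(cx, i, j); sy <- seg(cy, i, j)
        sxx <- seg(cxx, i, j); syy <- seg(cyy, i, j); sxy <- seg(cxy, i, j)
        ssxx <- sxx - sx^2 / n
        ssyy <- syy - sy^2 / n
        ssxy <- sxy - sx * sy / n
        if (ssyy <= 0 || ssxx <= 0) next # flat in y or degenerate in x
        r2 <- ssxy^2 / (ssxx * ssyy)
        if (r2 >= r2_min) {
          best <- list(start = s0 + i - 1, end = s0 + j - 1, len = len, r2 = r2)
          break # earliest window of this (maximal) length in this run
        }
      }
      if (!is.null(best) && best$len == len) break
    }
  }
  best
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit>", if (!is.na(x$curve_id)) x$curve_id else "", "\n")
  cat(sprintf("  rate     = %.4f /h (%.4f doublings/h)\n",
              x$rate, doublings_per_hour(x$rate)))
  cat(sprintf("  window   = points %d..%d (n = %d), R^2 = %.5f\n",
              x$window[1], x$window[2], x$n_points, x$r_squared))
  invisible(x)
}

#' @rdname fit_exponential_rate
#' @param x A `growth_fit` object.
#' @param ... Unused.
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(
    term = c("intercept", "rate"),
    estimate = c(x$intercept, x$rate),
    std.error = c(NA_real_, x$rate_se)
  )
}

#' @rdname fit_exponential_rate
#' @export
glance.growth_fit <- function(x, ...) {
  tibble(
    curve_id = x$curve_id,
    rate = x$rate,
    doublings_per_h = doublings_per_hour(x$rate),
    r_squared = x$r_squared,
    n_points = x$n_points,
    window_start_min = x$data$time_min[x$window[1]],
    window_end_min = x$data$time_min[x$window[2]]
  )
}

#' Fit growth constants for every curve on a plate
#'
#' @param plate A long tibble with columns `curve_id`, `time_min`, `od600`
#'   (see [read_plate_csv()]).
#' @param groups Optional tibble mapping `curve_id` to annotation columns
#'   (e.g. strain, condition, replicate); joined onto the output.
#' @param blank Either a number (OD units), `"none"` (0), or
#'   `"first_median"` (median OD across curves at the earliest timepoint).
#' @inheritParams fit_exponential_rate
#' @param .errors How to treat curves with no linear range: `"na"` (default,
#'   rate NA) or `"error"`.
#' @return A tibble with one row per curve: `curve_id`, `rate`,
#'   `doublings_per_h`, `r_squared`, `n_points`, window bounds, plus any
#'   group columns.
#' @export
fit_growth_rates <- function(plate, groups = NULL, blank = "none",
                             od_min = 0.02, od_max = 0.5, r2_min = 0.99,
                             min_points = 9, .errors = c("na", "error")) {
  check_columns(plate, c("curve_id", "time_min", "od600"), "plate")
  .errors <- match.arg(.errors)
  if (identical(blank, "none")) {
    blank <- 0
  } else if (identical(blank, "first_median")) {
    t0 <- min(plate$time_min)
    blank <- median(plate$od600[plate$time_min == t0])
  }
  check_finite_scalar(blank, "blank")
  out <- purrr::map_dfr(split(plate, plate$curve_id), function(cv) {
    cv <- cv[order(cv$time_min), ]
    fit <- tryCatch(
      fit_exponential_rate(cv, blank = blank, od_min = od_min,
                           od_max = od_max, r2_min = r2_min,
                           min_points = min_points),
      rhozero_no_linear_range_error = function(e) {
        if (.errors == "error") rlang::abort(conditionMessage(e), parent = e)
        NULL
      }
    )
    if (is.null(fit)) {
      tibble(curve_id = cv$curve_id[1], rate = NA_real_,
             doublings_per_h = NA_real_, r_squared = NA_real_,
             n_points = NA_integer_, window_start_min = NA_real_,
             window_end_min = NA_real_)
    } else {
      glance(fit)
    }
  })
  if (!is.null(groups)) {
    check_columns(groups, "curve_id", "groups")
    out <- dplyr::left_join(out, groups, by = "curve_id")
  }
  out
}

#' Compare growth rates between two groups (t-test)
#'
#' Welch's unequal-variance t-test by default (switchable to the pooled
#' test). The one-tailed alternative is that `group_a` exceeds `group_b`.
#'
#' @param group_a,group_b Numeric vectors of growth rates (n >= 2 each).
#' @param tails 1 or 2.
#' @param var_equal Use the pooled-variance test instead of Welch.
#' @return A one-row tibble: `statistic` (t), `df`, `p_value`, `mean_a`,
#'   `mean_b`, `tails`.
#' @examples
#' compare_rates(c(0.41, 0.40, 0.42), c(0.20, 0.22, 0.21))
#' @export
compare_rates <- function(group_a, group_b, tails = 2, var_equal = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop_validation("each group needs at least 2 values.")
  }
  if (!tails %in% c(1, 2)) {
    stop_validation("`tails` must be 1 or 2.")
  }
  alternative <- if (tails == 1) "greater" else "two.sided"
  ht <- tryCatch(
    t.test(group_a, group_b, alternative = alternative,
           var.equal = var_equal),
    error = function(e) NULL
  )
  if (is.null(ht)) {
    # both groups constant: equal means -> no evidence of difference;
    # unequal constant means -> infinite separation
    if (isTRUE(all.equal(mean(group_a), mean(group_b)))) {
      return(tibble(statistic = 0, df = NA_real_, p_value = 1,
                    mean_a = mean(group_a), mean_b = mean(group_b),
                    tails = tails))
    }
    stat <- sign(mean(group_a) - mean(group_b)) * Inf
    p <- if (tails == 1) as.numeric(stat < 0) else 0
    return(tibble(statistic = stat, df = NA_real_, p_value = p,
                  mean_a = mean(group_a), mean_b = mean(group_b),
                  tails = tails))
  }
  tibble(
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value, mean_a = mean(group_a), mean_b = mean(group_b),
    tails = tails
  )
}

#' Pearson correlation between validation rates and screen rank metrics
#'
#' Used to compare arrayed growth-rate measurements of re-tested strains
#' with their pooled-screen rank metrics.
#'
#' @param x,y Equal-length numeric vectors (n >= 3), finite.
#' @return A one-row tibble: `r`, `n`, `statistic`, `p_value`.
#' @examples
#' correlate_validation(c(1, 2, 3, 4, 5), c(1.1, 1.9, 3.2, 3.8, 5.1))
#' @export
correlate_validation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop_validation("`x` and `y` must have equal length >= 3.")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_validation("`x` and `y` must be finite.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    rlang::abort("correlation undefined: zero variance input.",
                 class = "rhozero_undefined_correlation_error")
  }
  ht <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ht$estimate), n = length(x),
         statistic = unname(ht$statistic), p_value = ht$p.value)
}
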