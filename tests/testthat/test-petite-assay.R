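test_that("petite calls use a strict area threshold", {
  df <- tibble::tibble(area_mm2 = c(1.49, 1.5, 0.8, 3))
  called <- call_petite(df)
  expect_equal(called$petite_call, c(TRUE, FALSE, TRUE, FALSE))
  expect_true(call_petite(tibble::tibble(area_mm2 = 1.5), 2.0)$petite_call)
  expect_error(call_petite(tibble::tibble(area_mm2 = 0)),
               class = "rhozero_validation_error")
  expect_error(call_petite(tibble::tibble(area_mm2 = -1)),
               class = "rhozero_validation_error")
})

test_that("threshold calibration separates clean bimodal data", {
  colonies <- dplyr::bind_rows(
    generate_colony_areas(150, petite_fraction = 0.3, strain = "ctrl", seed = 1),
    generate_colony_areas(150, petite_fraction = 0.5, strain = "stress", seed = 2)
  )
  cal <- calibrate_threshold(colonies)
  # perfectly separated labels: zero false negatives above and the smallest
  # qualifying midpoint is returned
  expect_equal(sum(!colonies$respiring &
                     colonies$area_mm2 >= cal$threshold_mm2), 0)
  expect_equal(cal$threshold_mm2,
               min(cal$candidates$threshold_mm2[
                 cal$candidates$feasible & cal$candidates$fn_above == 0
               ]))
  max_nonresp <- max(colonies$area_mm2[!colonies$respiring])
  min_resp_above <- min(colonies$area_mm2[colonies$respiring &
                                            colonies$area_mm2 > max_nonresp])
  expect_equal(cal$threshold_mm2, (max_nonresp + min_resp_above) / 2)
})

test_that("calibration equals a brute-force scan on a toy set with a mislabel", {
  toy <- tibble::tibble(
    strain = rep("s", 10),
    area_mm2 = c(0.4, 0.5, 0.6, 0.7, 1.0, 2.2, 2.5, 2.8, 3.1, 3.4),
    respiring = c(FALSE, FALSE, TRUE, FALSE, FALSE,
                  TRUE, TRUE, FALSE, TRUE, TRUE) # one large non-respirer
  )
  cal <- calibrate_threshold(toy)
  brute <- brute_threshold(toy)
  expect_equal(cal$threshold_mm2, brute$cut)
  expect_equal(cal$diagnostics$fn_above, brute$fn)

  set.seed(9)
  noisy <- generate_colony_areas(120, petite_fraction = 0.35,
                                 label_noise = 0.05, seed = 10)
  cal2 <- calibrate_threshold(noisy)
  brute2 <- brute_threshold(noisy)
  expect_equal(cal2$threshold_mm2, brute2$cut)
})

test_that("degenerate labels trigger a calibration failure", {
  allresp <- generate_colony_areas(50, petite_fraction = 0, seed = 3)
  expect_error(calibrate_threshold(allresp),
               class = "rhozero_calibration_failure_error")
})

test_that("petite fraction summaries weight by colonies counted", {
  series <- tibble::tibble(
    genotype = "g", time_h = 0,
    replicate_id = c("a", "b", "c"),
    n_total = c(10, 10, 20), n_petite = c(2, 4, 6)
  )
  s <- petite_fraction_summary(series)
  expect_equal(s$weighted_mean, 12 / 40)
  expect_equal(s$mean_fraction, mean(c(0.2, 0.4, 0.3)))
  expect_equal(s$sem, sd(c(0.2, 0.4, 0.3)) / sqrt(3))

  equal_n <- dplyr::mutate(series, n_total = 10, n_petite = c(2, 4, 6))
  se <- petite_fraction_summary(equal_n)
  expect_equal(se$weighted_mean, se$mean_fraction)

  single <- tibble::tibble(genotype = "g", time_h = 0, replicate_id = "a",
                           n_total = 50, n_petite = 5)
  ss <- petite_fraction_summary(single)
  expect_equal(ss$weighted_mean, 0.1)
  expect_true(is.na(ss$sem))
  expect_false(ss$sem_defined)

  expect_error(petite_fraction_summary(series[0, ]),
               class = "rhozero_validation_error")
  # weighted mean bounded by the per-replicate fractions
  p <- two_state_params(0.4, 0.3, 0.1)
  big <- generate_petite_time_series(p, seed = 7)
  summ <- petite_fraction_summary(big)
  fr <- dplyr::summarise(
    dplyr::group_by(big, time_h),
    lo = min(n_petite / n_total), hi = max(n_petite / n_total)
  )
  expect_true(all(summ$weighted_mean >= fr$lo & summ$weighted_mean <= fr$hi))
})

test_that("noiseless series recover the generating loss rate exactly", {
  g_wt <- 0.45; g_mut <- 0.3; r_true <- 0.12; f0_true <- 0.03
  times <- c(0, 3, 6, 9)
  p <- two_state_params(g_wt, g_mut, r_true,
                        p_wt0 = 1 - f0_true, p_mut0 = f0_true)
  f <- mutant_fraction_at(p, times)
  series <- tidyr::expand_grid(replicate_id = c("a", "b"), time_h = times)
  series$n_total <- 1e6
  series$n_petite <- rep(f, 2) * 1e6 # exact fractions, no sampling noise
  fit <- estimate_loss_rate(series, g_wt = g_wt, g_mut = g_mut, n_boot = 0)
  expect_lt(abs(fit$r_hat - r_true), 1e-6)
  expect_lt(abs(fit$f0_hat - f0_true), 1e-5)
})

test_that("all-zero petite counts give a flagged boundary estimate of zero", {
  series <- tidyr::expand_grid(replicate_id = c("a", "b"),
                               time_h = c(0, 3, 6, 9))
  series$n_total <- 150
  series$n_petite <- 0
  expect_warning(
    fit <- estimate_loss_rate(series, g_wt = 0.4, g_mut = 0.4, n_boot = 0),
    class = "rhozero_boundary_warning"
  )
  expect_equal(fit$r_hat, 0, tolerance = 1e-8)
  expect_true(fit$boundary)
})

test_that("loss-rate estimates are invariant to relabeling and count scaling", {
  p <- two_state_params(0.4, 0.4, 0.15)
  series <- generate_petite_time_series(p, seed = 21)
  fit0 <- estimate_loss_rate(series, g_wt = 0.4, g_mut = 0.4, n_boot = 0)

  relab <- dplyr::mutate(series, replicate_id = sample(replicate_id))
  fit1 <- estimate_loss_rate(relab, g_wt = 0.4, g_mut = 0.4, n_boot = 0)
  expect_equal(fit1$r_hat, fit0$r_hat, tolerance = 1e-8)

  scaled <- dplyr::mutate(series, n_total = 3 * n_total,
                          n_petite = 3 * n_petite)
  fit2 <- estimate_loss_rate(scaled, g_wt = 0.4, g_mut = 0.4, n_boot = 0)
  expect_equal(fit2$r_hat, fit0$r_hat, tolerance = 1e-6)
})

test_that("short-time fits agree with the linear slope approximation", {
  # with f0 = 0 and small t, f(t) ~ r t
  g_wt <- 0.4; g_mut <- 0.4; r_true <- 0.02
  times <- c(0, 0.25, 0.5, 0.75)
  p <- two_state_params(g_wt, g_mut, r_true)
  f <- mutant_fraction_at(p, times)
  slope <- coef(lm(f ~ times))[2]
  expect_equal(unname(slope), r_true, tolerance = 0.01)

  series <- tidyr::expand_grid(replicate_id = "a", time_h = times)
  series$n_total <- 1e6
  series$n_petite <- f * 1e6
  fit <- estimate_loss_rate(series, g_wt = g_wt, g_mut = g_mut,
                            fit_f0 = FALSE, n_boot = 0)
  expect_equal(fit$r_hat, unname(slope), tolerance = 0.01)
})

test_that("weighted least squares and binomial ML agree within the CI width", {
  p <- two_state_params(0.4, 0.4, 0.15)
  series <- generate_petite_time_series(p, seed = 33)
  wls <- estimate_loss_rate(series, g_wt = 0.4, g_mut = 0.4,
                            n_boot = 100, seed = 1)
  ml <- estimate_loss_rate(series, g_wt = 0.4, g_mut = 0.4, method = "ml",
                           n_boot = 0)
  expect_lt(abs(wls$r_hat - ml$r_hat), wls$ci_upper - wls$ci_lower)
})

test_that("loss-rate fits expose tidy, glance and autoplot", {
  p <- two_state_params(0.4, 0.4, 0.15)
  series <- generate_petite_time_series(p, seed = 40)
  fit <- estimate_loss_rate(series, g_wt = 0.4, g_mut = 0.4,
                            n_boot = 50, seed = 2)
  td <- tidy(fit)
  expect_equal(td$term, c("r", "f0"))
  expect_true(td$conf.low[1] <= fit$r_hat && fit$r_hat <= td$conf.high[1])
  expect_equal(glance(fit)$n_boot, 50)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_petite_fractions(series), "ggplot")
})
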