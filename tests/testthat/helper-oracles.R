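# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# adaptive numeric integration of the two coupled ODEs
ode_trajectory <- function(params, times) {
  rhs <- function(t, y, parms) {
    with(as.list(parms), {
      list(c(
        (g_wt - r) * y[1],
        g_mut * y[2] + r * y[1]
      ))
    })
  }
  out <- deSolve::lsoda(
    y = c(p_wt = params$p_wt0, p_mut = params$p_mut0),
    times = times, func = rhs,
    parms = c(g_wt = params$g_wt, g_mut = params$g_mut, r = params$r),
    rtol = 1e-11, atol = 1e-12
  )
  as.data.frame(out)
}

# textbook Welch t statistic and two-sided p
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}

# Pearson r from the covariance formula
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# BH step-up: adjusted p_(i) = min_{j >= i} m p_(j) / j, in input order
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- m * p[ord][i:m] / (i:m)
    adj_sorted[i] <- min(1, min(vals))
  }
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

# exhaustive threshold scan replicating the calibration rule by brute force
brute_threshold <- function(colonies, max_fp = 0.5) {
  areas <- sort(unique(colonies$area_mm2))
  cands <- (head(areas, -1) + tail(areas, -1)) / 2
  best <- NULL
  for (cut in cands) {
    ok <- TRUE
    for (s in unique(colonies$strain)) {
      sub <- colonies[colonies$strain == s, ]
      below <- sub$area_mm2 < cut
      if (sum(below) > 0 && sum(sub$respiring & below) / sum(below) >= max_fp) {
        ok <- FALSE
        break
      }
    }
    if (!ok) next
    fn <- sum(!colonies$respiring & colonies$area_mm2 >= cut)
    if (is.null(best) || fn < best$fn) best <- list(cut = cut, fn = fn)
  }
  best
}

# minimum-likelihood two-sided exact test by plain-loop enumeration
exact_test_oracle <- function(a, b, sa, sb) {
  n <- a + b
  if (n == 0) return(1)
  p0 <- sa / (sa + sb)
  pobs <- dbinom(a, n, p0)
  total <- 0
  for (k in 0:n) {
    pk <- dbinom(k, n, p0)
    if (pk <= pobs * (1 + 1e-7)) total <- total + pk
  }
  min(1, total)
}

# random model parameters spanning both regimes, coexistence-biased
random_two_state_params <- function() {
  g_wt <- runif(1, 0.05, 0.8)
  g_mut <- runif(1, 0, 0.8)
  r <- runif(1, 0, 0.3)
  two_state_params(g_wt, g_mut, r,
                   p_wt0 = runif(1, 0.5, 100), p_mut0 = runif(1, 0, 10))
}
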