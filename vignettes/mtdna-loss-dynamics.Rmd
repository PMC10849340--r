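---
title: "Quantifying mtDNA loss in growing yeast populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mtDNA loss in growing yeast populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(rhozero)
library(dplyr)
```

## The problem

Budding yeast can survive the complete loss of their mitochondrial genome
(mtDNA). The resulting rho0 cells cannot respire, grow more slowly on
glucose, and found visibly smaller ("petite") colonies. Stressors that
destabilise mtDNA — for instance chronic accumulation of unfolded protein in
the mitochondrial matrix — therefore shift a growing culture toward a
mixture of fast rho+ and slow rho0 cells, and the measurable consequences
are a reduced bulk growth rate and a rising petite-colony fraction.
`rhozero` implements the quantitative machinery to go from raw measurements
(plate-reader OD600 series, colony-area tables, time-resolved petite
counts, pooled barcode-sequencing reads) to interpretable parameters: the
per-cell mtDNA loss rate, the growth constants of both subpopulations, and
ranked lists of gene-dosage suppressors.

## The two-state growth model

The population is described by two compartments: rho+ cells with
exponential growth constant $G_{wt}$ (natural log, per hour) that convert
irreversibly into rho0 cells at a constant per-cell rate $r$, and rho0
cells with growth constant $G_{mut}$:

$$\frac{dP_{wt}}{dt} = (G_{wt} - r)\,P_{wt}, \qquad
  \frac{dP_{mut}}{dt} = G_{mut}\,P_{mut} + r\,P_{wt}.$$

Conversion conserves the cell — a rho+ cell *becomes* a rho0 cell — which
is what makes the per-capita growth rate of the whole population the
mutant-fraction-weighted average $(1-f)G_{wt} + fG_{mut}$. The linear
system solves in closed form:

$$P_{wt}(t) = P_{wt}(0)\,e^{(G_{wt}-r)t}, \qquad
  P_{mut}(t) = P_{mut}(0)\,e^{G_{mut}t} +
  r P_{wt}(0)\, e^{G_{mut}t}\,\frac{e^{(G_{wt}-r-G_{mut})t}-1}{G_{wt}-r-G_{mut}},$$

with the degenerate limit $rP_{wt}(0)\,t\,e^{G_{mut}t}$ when
$G_{wt}-r = G_{mut}$. Numerically the ratio term is evaluated through
`expm1` whenever the rate gap is small (guard $10^{-9}$), which avoids the
catastrophic cancellation the naive difference of exponentials suffers
near the degenerate line; the test suite verifies both branches against
adaptive ODE integration to a relative error below $10^{-8}$ and checks
that the degenerate branch is the continuous limit of the generic one.

Two long-run regimes exist. If $G_{wt} - r > G_{mut}$ (strict), the rho+
compartment outgrows the conversion flux and the mutant fraction converges
to the finite equilibrium

$$f^{*} = \frac{r}{G_{wt} - G_{mut}},$$

with long-run per-capita growth rate $G_{wt}-r$; otherwise the mutant
fixes ($f^{*}=1$) and the population grows at
$\max(G_{wt}-r,\,G_{mut})$. The boundary case has no finite equilibrium
and is classified as fixation — a documented strictness convention.

```{r model}
p <- two_state_params(g_wt = 0.5, g_mut = 0.3, r = 0.05)
classify_regime(p)
autoplot(solve_closed_form(p, seq(0, 60, 0.5)))
```

The stochastic counterpart (`simulate_population_stochastic()`) is an
exact event-driven simulation with three channels — rho+ division, rho+
to rho0 conversion, rho0 division — on integer cell counts. Its ensemble
mean matches the deterministic solution; single runs show demographic
noise of relative size about $1/\sqrt{N}$, which is why the agreement
checks start from several hundred founder cells (the mutant fraction is a
ratio, so its ensemble mean carries an $O(1/N)$ bias that must sit well
below the Monte-Carlo standard error).

### Units

All rates are natural-log constants per hour; `doublings_per_hour()`
converts at the reporting layer. The conversion rate $r$ is treated as
per hour (not per generation) — the assay that measures it samples in
wall-clock hours, so this is the directly identified scale.

## Growth-curve fitting

`fit_exponential_rate()` operationalises "log-transform, truncate to the
linear range, fit a line": the linear range is the longest contiguous run
of points whose blank-subtracted OD lies in `[od_min, od_max]`
(defaults 0.02–0.5) and whose log-linear fit reaches `r2_min`
(default 0.99), with at least `min_points` (default 9, i.e. three hours
of 20-minute reads). The lower bound keeps points above read noise, the
upper bound stops before saturation, and the $R^2$ gate rejects windows
that still contain curvature. All knobs are exposed because no published
truncation rule exists for this assay.

Blank handling deserves a note. Subtracting the first reading is a common
reflex, but the first reading contains the inoculum signal: fitting
$\log(I e^{rt} - I)$ instead of $\log(I e^{rt})$ inflates the slope by a
factor $1/(1-e^{-rt})$ early in the window, which is far larger than the
few-percent accuracy the fit otherwise achieves. The default is therefore
no blank subtraction (`blank = 0`), with `blank = "first_median"`
available when a plate's wells genuinely share a media-only background.

```{r growth}
curve <- generate_growth_curve(rate = 0.35, seed = 1)
fit <- fit_exponential_rate(curve)
glance(fit)
```

Group comparisons use Welch's unequal-variance t-test by default
(`compare_rates()`, switchable to the pooled test); the source assays say
only "t-test", and Welch is the safer default when rho0 and rho+
replicate variances differ. The one-tailed direction is "first group
grows faster". `correlate_validation()` is a thin Pearson wrapper used to
compare arrayed re-test growth rates with pooled-screen rank metrics.

## Petite assay and loss-rate estimation

Colonies below 1.5 mm² (strict inequality) are called petite by
convention; `calibrate_threshold()` re-derives a cutoff from labelled
data by scanning midpoints between sorted distinct areas, requiring for
every strain that respiring false-positives make up less than `max_fp`
(default 50%) of the colonies below the cutoff, and then minimising
non-respiring false-negatives above it (ties to the smallest cutoff). A
strain with no colony below a candidate is vacuously feasible; data with
only one label class cannot be calibrated and raise a classed error.

`petite_fraction_summary()` reports the population-weighted mean petite
fraction (total petites over total colonies) alongside the *unweighted*
SEM of per-replicate fractions — the weighted mean uses every colony
while the SEM honours the biological replicate as the unit of error. With
a single replicate the SEM is flagged undefined rather than fabricated.

`estimate_loss_rate()` fits the model fraction $f(t; r, f_0)$ to a
time-resolved series by weighted least squares with binomial precision
weights $n_{total}$ (a binomial maximum-likelihood option is provided and
agrees within the CI width on synthetic data), with $r$ constrained to
$[0, G_{wt}]$ and the baseline fraction $f_0$ fitted by default, because
aerobically conditioned cultures retain a small petite background.
Boundary solutions ($r=0$ or $r=G_{wt}$) are flagged. The measured petite
fraction is identified with the population mutant fraction at plating; no
correction is attempted for cells that lose mtDNA after plating (the
assay cannot distinguish them), and this is stated here rather than
hidden.

Confidence intervals come from a case-resampling bootstrap over
biological replicates. With the assay's eight replicates the plain
percentile interval is materially too narrow — resampling $k$ units
shrinks the bootstrap spread by roughly $\sqrt{(k-1)/k}$ and uses
normal-like rather than $t_{k-1}$ quantiles; empirically the nominal 90%
interval covered only about 72–74% of the time. The default is therefore
the expanded percentile interval, which replaces the $\alpha/2$ quantile
by $\Phi\!\left(-\sqrt{k/(k-1)}\; t_{k-1,1-\alpha/2}\right)$; measured
coverage rises to about 88% at the design scale. Plain percentile
intervals remain available via `ci_method = "percentile"`.

```{r loss-rate}
p_loss <- two_state_params(g_wt = 0.4, g_mut = 0.4, r = 0.15)
series <- generate_petite_time_series(p_loss, seed = 11)
fit <- estimate_loss_rate(series, g_wt = 0.4, g_mut = 0.4,
                          n_boot = 200, seed = 12)
fit
autoplot(fit)
```

## Barcode screen

Demultiplexing is exact-match by design: a read is counted only when its
index field equals a mapped sample index *and* its barcode field equals a
mapped gene barcode; everything else is discarded with a reason, and
counted + discarded always equals the total. Exact matching forgoes reads
with sequencing errors in exchange for a negligible misassignment rate,
which suits an assay with deep coverage per barcode.

The enrichment test is a conditional binomial exact test on pooled
counts: replicate libraries are rescaled to the common median library
size (median rescaling is robust and keeps counts on a count scale; no
trimmed-mean normalisation is attempted), summed within condition, and
for each gene the two-sided p-value sums all outcome probabilities not
exceeding that of the observed outcome (minimum-likelihood rule; this
differs from tail doubling on skewed nulls and is stated for that
reason). Pooling with a dispersion-free conditional test is a simpler
model than a negative-binomial fit with tagwise dispersion: it treats
replicates as exchangeable Poisson draws, so its p-values are calibrated
under that assumption (the type-I checks in this package use exactly that
null) and will be anti-conservative on strongly overdispersed real data —
the main caveat to carry to applications. A fixed-dispersion variant can
be emulated by generating overdispersed nulls with
`generate_screen_counts(dispersion = ...)` and calibrating empirically.

The rank metric is the sign of enrichment times $-\log_{10}p$ (zero when
$p = 1$ or the fold change is zero; p-values are floored at $10^{-300}$
so the metric stays finite), BH adjustment controls the FDR across genes,
and `select_hits()` slices the ranked table deterministically (ties break
lexicographically by gene id).

```{r screen}
spikes <- tibble::tibble(gene_id = sprintf("g%04d", 1:3),
                         condition = "etbr", log2fc = 2)
counts <- generate_screen_counts(n_genes = 500, spikes = spikes, seed = 3)
res <- run_contrast(counts, c("etbr", "control"))
select_hits(res, "top", k = 5)
```

## What the synthetic generators do and do not emulate

Every input the pipeline consumes has a generator, so the whole analysis
is testable without external data:

* `simulate_population_stochastic()` — demographic noise in the two-state
  process itself.
* `generate_petite_time_series()` — Poisson colonies per plate (default
  150) and binomial petite sampling at the model's fraction, at the
  assay's design: 8 replicates, platings at 0/3/6/9 h. Plates are assumed
  independent; the generator does not model the shared dilution series.
* `generate_growth_curve()` — lag, exact exponential phase, then a
  C1-continuous exponential relaxation to carrying capacity, plus
  additive Gaussian read noise (default SD 0.002 OD). The exponential
  phase is exactly exponential by construction so that round-trip rate
  recovery is a meaningful check of window selection and noise handling;
  real curves bend continuously, show diauxic shifts, and have
  multiplicative noise components — none of which are emulated.
* `generate_colony_areas()` — log-normal small/large area components
  (defaults centred at 0.5 and 3 mm², either side of the 1.5 mm²
  convention) with optional label flipping; real plates add crowding
  effects on colony size.
* `generate_barcode_reads()` — reads laid out as a 6 nt in-line index, a
  20 nt gene barcode and random filler to 30 nt (geometry configurable;
  primer schemes differ), with independent per-base substitution errors
  and a per-read truth table. Indels, quality-dependent error profiles
  and PCR amplification bias are deliberately out of scope.
* `generate_screen_counts()` — negative-binomial (gamma-mixed Poisson)
  counts around condition-specific proportions with spike-in log2 fold
  changes; `dispersion = 0` gives the Poisson null used for type-I
  calibration.

Because cultures in the measured assays were held in exponential phase by
dilution, all generators assume constant rates (no density dependence).
Passing tests on these generators therefore demonstrates correctness of
the estimators under their stated sampling models, not robustness to the
unmodelled features above.

## Numerical choices and degenerate inputs

* Closed form via `expm1` near the degenerate line (guard $10^{-9}$).
* Window selection scans windows longest-first with prefix sums; a
  constant (zero-variance) log-OD segment has undefined $R^2$ and is
  skipped, so flat curves raise the no-linear-range error.
* The loss-rate optimiser is L-BFGS-B from three starts (data slope, a
  small rate, half of $G_{wt}$) with tight convergence (`factr = 10`);
  all-zero petite counts drive $\hat r$ to the 0 boundary, which is
  flagged rather than silently reported.
* Exact-test p-values are floored at the smallest positive double to
  absorb underflow at extreme counts; probability ties in the
  minimum-likelihood sum use a $1+10^{-7}$ relative tolerance.
* Empty count pairs ($n = 0$) return $p = 1$ and zero fold change by
  convention and are flagged `low_evidence` in contrast output.
* The log2 fold change uses half-count pseudocounts
  ($(a+0.5)/s_a$ vs $(b+0.5)/s_b$), which only matters for direction
  ties at zero counts.

## Problem sizes used by the checks

The packaged checks run at: 100 random parameter sets for the
closed-form/ODE comparison; 200 stochastic runs from 500 founder cells
for the ensemble comparison; 50–100 simulated experiments (8 replicates,
4 timepoints, 150 colonies/plate, 200 bootstrap resamples) for loss-rate
recovery and CI coverage; 50 synthetic plate curves spanning
0.1–0.6 /h; all count pairs with $n \le 50$ for exact-test enumeration
plus 100 Poisson null screens of 1,000 genes; and spiked screens of
1,000 genes with ten $|\log_2\mathrm{FC}| = 2$ spikes. These sizes give
each stochastic check a Monte-Carlo error comfortably below the property
being asserted.

## Configuration and orchestration

`run_workflow()` ties the stages into three reproducible workflows
(`simulate`, `loss_rate`, `screen`) driven by a named list or YAML file;
YAML was chosen as the configuration format because it round-trips R
lists losslessly with the installed tooling. Every stochastic stage
receives a sub-seed drawn deterministically from the global seed and
logged in the JSON report, so identical configurations produce
byte-identical outputs. The package is used from R; the exported
functions and `run_workflow()` are the scripting interface.

## Known limitations

* mtDNA presence is binary; copy-number dynamics, heteroplasmy and
  rho− partial deletions are out of scope, as is reversion.
* The enrichment test ignores replicate-level overdispersion (see above).
* The loss-rate assay cannot see post-plating mtDNA loss; estimates are
  conditional on the petite-call being a faithful readout of state at
  plating.
* Percentile-type bootstrap intervals remain approximate for very few
  replicates even after expansion; below four replicates they should not
  be trusted.
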