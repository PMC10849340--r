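# rhozero

Quantitative analysis of mitochondrial DNA (mtDNA) loss in growing budding
yeast populations, and of pooled gene-dosage suppressor screens read out by
barcode sequencing.

Yeast survive complete mtDNA loss, but the resulting ρ0 cells cannot
respire, grow slowly on glucose, and found small "petite" colonies.
Stressors that destabilise mtDNA therefore turn a culture into a mixture of
fast ρ+ and slow ρ0 cells. `rhozero` provides, for experimentalists
working with such populations:

* **A two-state growth model.** ρ+ cells grow at rate *G<sub>wt</sub>* and
  convert to ρ0 cells at a constant per-cell rate *r*; ρ0 cells grow at
  *G<sub>mut</sub>* (all natural-log constants, per hour):

  dP<sub>wt</sub>/dt = (G<sub>wt</sub> − r) P<sub>wt</sub>,  
  dP<sub>mut</sub>/dt = G<sub>mut</sub> P<sub>mut</sub> + r P<sub>wt</sub>

  with closed-form solutions, regime classification (coexistence when
  G<sub>wt</sub> − r > G<sub>mut</sub>, with equilibrium mutant fraction
  f\* = r / (G<sub>wt</sub> − G<sub>mut</sub>); fixation otherwise),
  parameter sweeps, and an exact stochastic (Gillespie) counterpart.
* **Growth-curve fitting.** Log-linear fits of OD600 plate-reader series
  with automatic linear-range selection, Welch t-test group comparisons,
  and Pearson validation correlations.
* **Petite assay analysis.** Colony-size petite calls (area < 1.5 mm²),
  data-driven threshold calibration, weighted petite-fraction summaries,
  and mtDNA loss-rate estimation from time-resolved plating series with
  bootstrap confidence intervals.
* **Barcode-screen analysis.** Exact-match demultiplexing of amplicon
  reads, a conditional binomial exact enrichment test, the signed rank
  metric (sign of enrichment × −log10 p), Benjamini–Hochberg FDR control
  and hit selection.
* **Synthetic data generators** for every input, so the full pipeline is
  testable end to end without external data.

Everything takes and returns tidy tibbles; fitted objects support
`tidy()`, `glance()` and `autoplot()`.

## Worked example

Model a stressed culture, simulate the time-resolved petite assay at its
standard design (8 biological replicates, platings at 0/3/6/9 h, ~150
colonies per plate), and recover the loss rate:

```r
library(rhozero)

two_state_params(g_wt = 0.5, g_mut = 0.3, r = 0.05) |> classify_regime()
#> # A tibble: 1 × 3
#>   regime      f_star growth_rate
#>   <chr>        <dbl>       <dbl>
#> 1 COEXISTENCE   0.25        0.45
```

A loss rate of 0.05/h against a 0.2/h growth-rate gap gives stable
coexistence: the culture settles at 25% ρ0 cells and grows at
0.45/h — the fraction-weighted average of the two growth constants.

```r
p_loss <- two_state_params(g_wt = 0.4, g_mut = 0.4, r = 0.15)
series <- generate_petite_time_series(p_loss, seed = 11)
petite_fraction_summary(series)
#> # A tibble: 4 × 8
#>   genotype  time_h weighted_mean mean_fraction    sem sem_defined n_replicates
#> 1 synthetic      0         0             0     0      TRUE                   8
#> 2 synthetic      3         0.363         0.362 0.0156 TRUE                   8
#> 3 synthetic      6         0.572         0.571 0.0106 TRUE                   8
#> 4 synthetic      9         0.745         0.745 0.0126 TRUE                   8

estimate_loss_rate(series, g_wt = 0.4, g_mut = 0.4, n_boot = 200, seed = 12)
#> <loss_rate_fit>
#>   r_hat = 0.1473 /h  (f0 = 0.0000, wls fit)
#>   90% bootstrap CI: [0.1395, 0.1530]  (200 resamples)
```

At this loss rate the petite fraction climbs to ~75% within nine hours,
and the weighted least-squares fit recovers the generating rate
(0.15/h) inside its bootstrap interval.

Screen analysis on a spiked synthetic count table:

```r
spikes <- tibble::tibble(gene_id = sprintf("g%04d", 1:3),
                         condition = "etbr", log2fc = 2)
counts <- generate_screen_counts(n_genes = 500, spikes = spikes, seed = 3)
res <- run_contrast(counts, c("etbr", "control"))
select_hits(res, "top", k = 5)
#> # A tibble: 5 × 10
#>   gene_id count_a count_b log2fc   p_value     p_adj rank_metric low_evidence
#> 1 g0001      3760     923  2.03  2.23e-308 3.71e-306       300   FALSE
#> 2 g0002      4824    1218  1.98  2.23e-308 3.71e-306       300   FALSE
#> 3 g0003      4162    1178  1.82  2.23e-308 3.71e-306       300   FALSE
#> 4 g0108      1406     863  0.703 2.87e- 30 8.98e- 29        29.5 FALSE
#> 5 g0379      1500     949  0.660 6.36e- 29 1.77e- 27        28.2 FALSE
```

The three spiked genes top the ranking with fold changes at the spiked
value of 2 (log2); the rank metric is capped where p-values underflow.

See `vignette("mtdna-loss-dynamics")` for the model derivation, estimator
details, generator assumptions and numerical choices.

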