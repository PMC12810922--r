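# mitofast

Quantitative machinery for tracking mitochondrial DNA (mtDNA) heteroplasmy
segregation in budding yeast. When a zygote inherits both an intact,
fluorescently labelled mitochondrial genome and a mutant, unlabelled one,
the population it founds segregates within ~20 h into fluorescent and dark
cells. `mitofast` asks, end to end, whether the final dark-cell fraction is
explained by the copy-number asymmetry of the founding zygote plus any
growth handicap of mutant-mtDNA cells — or whether an additional
intracellular mode of selection against mutant genomes must be invoked.

The package is aimed at researchers analysing flow-cytometry segregation
assays and at modellers of organelle genome population dynamics. It
provides:

* **Flow gating (FAST-style classifier)** — forward-scatter debris gate
  (`gate_scatter`), Gaussian KDE of log10 fluorescence (`estimate_kde`),
  prominence-based two-peak and valley detection (`locate_peaks_valley`),
  and classification of events into dark / heteroplasmic / fluorescent
  fractions using a window of ±10% of the interpeak distance around the
  valley (`classify_events`); unimodal samples are scored against a
  non-fluorescent control (`dark_fraction_control`).
* **Segregation simulator** — an agent-based model (`sim_config`,
  `simulate_population`, `run_replicates`, `sweep_ratios`) in which each
  cell carries an ordered string of N = 32 nucleoid alleles, founders are
  initialized from an mtDNA copy-number ratio r with
  `round(N·r/(1+r))` mutant nucleoids, and a cell's division probability in
  one reference doubling time is `p = clamp(2^g − 1, 0, 1)` with
  `g = 1 + (g_other − 1)·h` linear in its heteroplasmy `h`. The inner loop
  is C++ (Rcpp); one 100-run experiment takes well under a minute.
* **Estimators** — exponential growth rate and doubling time
  (`fit_growth_rate`, T_d = ln 2 / r), plate doubling time from cell
  counts (`plate_doubling_time`), fluorescence decay half-life
  (`fit_half_life`), qPCR relative copy number from COX1/ACT1 Cq values
  (`qpcr_relative_cn`), and growth-factor inference from post-growth
  mixing fractions (`infer_growth_factor`).
* **Inference** — one-sided Monte-Carlo resampling p-values of measured
  fractions against the simulation distribution (`mc_pvalue`), Fisher
  combination across replicates (`fisher_combine`), and the orchestrated
  comparison (`compare_fast_to_sim`).
* **Network metrics** — total mitochondrial network length from skeleton
  vertex tables (`network_length`), ratiometric channel summaries in
  per-node-mean and summed modes (`ratiometric_summary`), and P2/P1
  zygote compartment ratios (`compartment_ratio`).
* **Synthetic data** — generators with planted ground truth for every
  input: log-normal event mixtures with debris (`make_flow_mixture`),
  decay series, growth curves, Cq tables and 3-D skeletons, so the whole
  chain is testable without instrument data.

## Worked example

Generate a 10,000-event population with the planted 20 h segregation
fractions (dark 50.9%, heteroplasmic 3.32%, fluorescent 45.8%, plus 5%
debris), classify it, and compare the measured dark fraction to a matched
simulation:

```r
library(mitofast)

spec <- het_mixture_spec(10000, debris_fraction = 0.05)
events <- gate_scatter(make_flow_mixture(spec, seed = 214))
pv <- locate_peaks_valley(estimate_kde(events$fl1))
classify_events(events, pv, window_frac = 0.10)
#> FAST gating: 10000 events (457 debris removed)
#>   dark            4923  ( 51.6%)
#>   heteroplasmic    336  ( 3.52%)
#>   fluorescent     4284  ( 44.9%)
#>   window [2.872, 3.274] log10 units
```

The classifier recovers the planted fractions within sampling error: the
dark and fluorescent clusters sit two decades apart on the log10 axis, and
the ±10% window around the interpeak valley captures the planted
intermediate population.

```r
cfg <- sim_config(ratio = 0.71, g_other = 0.98)  # measured copy-number
run_replicates(cfg, seed = 214)                  # ratio and growth factor
#> segregation simulation: 100 runs, ratio 0.71, g_other 0.98
#>   mean of mean_h = 0.3943 (sd 0.0090)
#>   final cells per run: 454478 (median)

compare_fast_to_sim(c(0.276, 0.281, 0.272), cfg, B = 10000, seed = 214)
#> cross: observed dark fractions 0.276, 0.281, 0.272
#>   simulated mean_h = 0.3943 (sd 0.0090, 100 runs)
#>   combined p = 4.103e-10 *** -> simulation exceeds FAST
```

Starting from the measured 1:0.71 copy-number ratio (13 of 32 founder
nucleoids mutant, a 40.6% starting fraction) and the measured 2% growth
handicap, the simulation predicts ~39.4% mutant cells after 14
generations — but the assay measures only ~27.6%. The one-sided
Monte-Carlo + Fisher test rejects consistency: growth and copy-number
effects alone cannot account for the loss of mutant mtDNA, the signature
of intracellular selection.

The numbered scripts under `analysis/` run this narrative end to end
(`01_synthesize_data.R` → `05_compare_fast_to_sim.R`), writing tables
under `results/`; the methods vignette
(`vignettes/mtdna-segregation-methods.Rmd`) documents the model,
its assumptions and its limitations.

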