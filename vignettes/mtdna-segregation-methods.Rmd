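---
title: "Quantifying mtDNA segregation: gating, simulation and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mtDNA segregation: gating, simulation and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitofast)
```

## The problem

Budding yeast cells carry many copies of their mitochondrial genome
(mtDNA), packaged into nucleoids. When a zygote inherits both an intact,
fluorescently labelled genome and a mutant, unlabelled one, the resulting
heteroplasmic founder gives rise over ~20 h of growth to a population in
which the two variants have largely segregated: most cells end up
fluorescent (intact mtDNA) or dark (mutant mtDNA), with a small residual
heteroplasmic population in between. The central quantitative question is
whether the final proportion of dark cells can be explained by two
"boring" forces alone — the copy-number asymmetry the two parents
contribute to the zygote, and any growth handicap of cells carrying mutant
mtDNA — or whether an additional, intracellular mode of selection against
mutant genomes must be invoked.

`mitofast` implements the full quantitative chain needed to answer that
question: a flow-cytometry gating classifier for segregation tracking, an
agent-based nucleoid segregation simulator with heteroplasmy-coupled
growth, the supporting estimators (growth rate, fluorescence half-life,
qPCR copy number, growth-factor inference), a Monte-Carlo + Fisher
significance test comparing simulations to measurements, mitochondrial
network metrics, and synthetic-data generators with planted ground truth
that stand in for raw instrument data.

## Flow-cytometry gating

Events are first cleaned on forward scatter: genuine cells fall on the
FSC-A ~ FSC-H diagonal, so events with height/area ratio outside a band
(default 0.7–1.3; the instrument gate is drawn by eye, so the band is
configurable) are discarded as debris. The fluorescence channel is then
summarized by a Gaussian-kernel density estimate of log10 intensity
(Silverman's rule-of-thumb bandwidth, 512-point grid extending three
bandwidths past the data). Log10 is used because cytometry channels span
decades and their per-population scatter is approximately log-normal; the
transform is a package choice, fixed once.

Peaks are ranked by topographic prominence and the two most prominent
local maxima, each above 5% of the maximum density, become the dark and
fluorescent landmarks; the valley is the global density minimum strictly
between them. Prominence rather than raw height is used so that a small
intermediate bump between the major modes is never mistaken for a major
peak. The heteroplasmic window is centred on the valley with half-width
10% of the interpeak distance; events below the window are dark, inside
(bounds inclusive — ties count as heteroplasmic, the conservative choice
for detecting heteroplasmy) heteroplasmic, above it fluorescent.
Fractions are reported over post-debris events. A sample without a second
qualifying peak raises a typed condition; such unimodal samples are
scored against a non-fluorescent control strain instead, using a high
quantile (default 0.999) of the control's fluorescence as the darkness
threshold, which fixes the false-positive floor at about 0.1%.

## The segregation simulator

A simulated cell is an ordered string of `N = 32` nucleoids, each carrying
allele 0 (reference, labelled mtDNA) or 1 (the competing variant); the
cell's heteroplasmy `h` is the mean allele. Founders start from the
maximally interleaved string `[1,0,1,0,...]` and random positions are
flipped until the count of 1-alleles is `round(N*r/(1+r))` for the
requested other:reference copy-number ratio `r` — the nearest achievable
match to the ratio (at `r = 0.1`: 3 ones and 29 zeros; at `r = 0.71`: 13
ones, i.e. a 40.6% starting fraction).

Each of `ngen = 14` synchronous steps corresponds to one doubling time of
the reference strain (measured on plates as 1.48 h, so 14 steps span the
20.7 h of the experiment). A cell's relative growth rate interpolates
linearly in its heteroplasmy, `g = 1 + (g_other - 1) h`, where `g_other`
is the measured growth-rate ratio of the strain homoplasmic for the
competing variant. Within one step the cell divides with probability
`p = clamp(2^g - 1, 0, 1)`: a reference-rate cell (`g = 1`) divides with
certainty, a handicapped cell proportionally less often; for `g > 1` the
probability saturates at 1. Cells stop dividing after `ndau = 11`
divisions (replicative lifespan). Each run simulates 30 independent
founders — matching the 30 micromanipulated cells per experiment — and
reports the unweighted mean of `h` over all final cells; replicate runs
(100 by default) summarize the distribution of that mean.

### Division mechanics

At division the nucleoid string is cut at `nspl = 5` distinct internal
boundaries, giving six segments: mixing of the string is limited, which
preserves the spatial coherence of nucleoid lineages. The segments are
distributed *alternately* between mother and daughter (a fair coin decides
which side receives the first segment), reflecting the roughly even
partitioning of mitochondrial material between mother and bud. Both cells
then replenish to `N` nucleoids in *balanced* rounds: a uniformly chosen
subset of residents — every resident, while more copies are missing than
residents exist — is duplicated once, mirroring the roughly
once-per-cell-cycle replication of mtDNA. Each copy enters the string at
a uniformly chosen position, because between divisions the fused
network's fusion/fission dynamics reorder nucleoids, so a fresh copy's
position should not stay tied to its template's.

Two properties anchor this design. First, mother and daughter are
exchangeable and replenishment is unbiased, so expected heteroplasmy is a
martingale: without selection (`g_other = 1`) the population mean of `h`
stays at the founder value for any horizon, which the property suite
verifies. Second, the scheme controls the *speed* of segregation, i.e.
how fast the between-cell variance of `h` grows. We also examined harsher
alternatives: assigning each segment by an independent coin, replenishing
by repeatedly duplicating a single uniformly chosen nucleoid (a Polya
urn), and inserting each copy adjacent to its template so that same-allele
blocks accrete over generations. Each of these behaves like a coarse
bottleneck per division and segregates so fast that, under the measured
parameters of the intact-vs-complex-IV-deletion cross (`r = 0.71`,
`g_other = 0.98`), selection acting on the rapidly generated variance
drags the 14-generation mean several points below the value the measured
parameters should reproduce. The alternating/balanced/mixing mechanics
keep the martingale exact while producing the moderate segregation speed
consistent with that benchmark; with them the cross predicts ~39.4%
mutant cells from the 40.6% founder fraction.

### What the simulation deliberately omits

No explicit mitochondrial network, fusion/fission rates, cristae, cell
death, or zygote bud geometry; generations are synchronous and the
population is unbounded. The per-run variance of the final mean is
therefore model-dependent and is not treated as a calibrated quantity —
only mean behaviour is.

## Estimators

* **Growth rate**: OLS on (t, ln OD600). The automatic window selects the
  contiguous stretch with OD between twice the initial reading and half
  the maximum (an exponential-phase heuristic) that maximizes r²; an
  explicit window is available. Doubling time is `ln 2 / rate`.
* **Plate doubling time**: `T_d = hours * ln 2 / ln(nf/n0)` from seeded
  and harvested cell counts.
* **Fluorescence half-life**: OLS slope of ln(median) against time;
  half-life `ln 2 / (-slope)`. A non-decaying series is an error, not a
  number.
* **qPCR copy number**: per replicate `2^(Cq_ACT1 - Cq_COX1)` (perfect
  amplification efficiency, factor 2 per cycle; the efficiency is a
  parameter), per strain the replicate mean, normalized so the reference
  strain is exactly 1.
* **Growth factor from mixing fractions**: with equal founder numbers
  growing exponentially for `G` reference generations, an observed final
  fraction `f` of the competing strain implies
  `g_other = 1 + log2(f/(1-f))/G`. This inversion is a reconstruction —
  the natural exponential-competition model — with `G` = total time over
  the reference doubling time (20 h / 1.48 h ≈ 13.5).

## Monte-Carlo + Fisher comparison

Each measured replicate (a dark-cell fraction) is compared to the
simulation distribution by resampling: `B = 10000` draws with replacement
from the per-run simulated means, one-sided p-value
`(1 + #draws <= observed)/(B + 1)`. The add-one estimator keeps p strictly
positive so Fisher's method stays finite; ties count as extreme, the
conservative reading. Replicate p-values combine as `-2 sum(log p)`
against chi-square with `2k` degrees of freedom. A small combined p says
the simulation — carrying only growth and copy-number effects — predicts
more mutant cells than measured: the signature of intracellular selection.
Significance tiers 0.05 / 0.005 / 0.001 are reported as stars. The
comparison consumes dark fractions; heteroplasmic-window events are
excluded, as the measurement compares two near-fully-segregated clusters.

## Network metrics

Skeleton vertex tables (one row per node, ordered along each line) yield
the total network length as the sum over lines of Euclidean distances
between consecutive nodes. Ratiometric summaries come in two modes:
`per_node_mean` (mean of per-node channel ratios, zero-denominator nodes
excluded and counted — relevant for excitation-ratio ATP sensors) and
`summed` (ratio of channel totals — relevant for dye accumulation
normalized to a content marker). Compartment ratios apply either mode
separately to P1- and P2-labelled nodes and report P2/P1; compartment
masks are consumed as a precomputed label column because image
segmentation is out of scope. Both modes are provided for the zygote
ratios since the choice is not fully determined; they agree on
homogeneous networks.

## Synthetic data: what it emulates, and what it does not

The generators plant known ground truth: log-normal fluorescence mixtures
with chosen component fractions and a debris population at low
height/area ratio; exponential decay and growth series with multiplicative
log-normal noise; Cq tables under the perfect-efficiency model; straight
polyline skeletons with per-node channel intensities. Defaults were fixed
once to represent realistic instrument output: major components 2 decades
apart (log10 means 2 and 4) with sd 0.35, scatter ratio sd 0.05 for
cells, debris at ratio 0.1–0.6.

The intermediate (heteroplasmic) component is centred midway between the
major components with sd 0.09 x the interpeak distance. That width is a
construction constraint, not a biological model: it puts most planted
intermediates inside the ±10% valley window while keeping the population
smooth enough that the interpeak density minimum stays between the two
major peaks (a much narrower spike would carve its own local maximum at
the centre and displace the detected valley sideways; a much broader one
would spill its mass outside the window). The fluorescence distribution
of true heteroplasmic cells is unknown — only the gating window is
defined — so recovery tests on this component validate the classifier's
bookkeeping, not a biological claim.

More generally, passing synthetic-recovery tests shows that the chain of
estimators inverts the generative models it was built for; it does not
show that real cytometry data meet those models (no spillover,
autofluorescence structure, instrument drift, or doublets are simulated).

## Numerical choices and degenerate inputs

KDE profiles are renormalized to integrate to exactly 1 (trapezoid rule).
Peak detection collapses plateaus to their leftmost point; valley ties
resolve to the lowest grid index. A heteroplasmic window that would reach
past either peak is an error (peaks too close), as is a scatter band that
removes every event, a non-decaying decay series, a non-growing growth
curve, and a division request on a post-replicative cell. Event tables
larger than the 10,000-event acquisition cap are subsampled with a fixed
seed on read. All randomness flows through R's RNG, so a single
`set.seed()` reproduces any run, including the C++ simulation core.

## Problem sizes used in the shipped analyses

The bundled analyses and checks use the study's own scales: 10,000-event
populations, 30 founders, 14 generations, 100 replicate runs for measured
ratios and 10 per grid point for the 0.10–1.00 ratio sweep, and B = 10,000
resampling draws. Property-style tests that hold for any horizon (e.g.
the neutral martingale) are exercised at 6 generations, where 200
replicate runs are cheap; the property, not the horizon, is what is being
checked.

## Known limitations

The simulator's variance structure (and hence per-run spread) is a
modelling choice constrained only by mean behaviour; the growth-factor
inversion assumes equal founder numbers and constant rates; the qPCR
model assumes perfect efficiency; the gating classifier assumes the two
major modes are resolvable on a log10 axis. None of the microscopy-side
intensity processing (deconvolution, segmentation, mask generation) is
reimplemented — the network metrics start from vertex tables.
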