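#!/usr/bin/env Rscript
# The headline comparison: does a simulation carrying only the measured
# growth handicap and copy-number asymmetry reproduce the measured
# dark-cell fractions, or does it predict systematically more mutant
# cells? Each replicate gets a one-sided Monte-Carlo p-value against the
# simulation distribution; replicate p-values are combined with Fisher's
# method. Writes results/comparison_<label>.json.

library(mitofast)

dir.create("results", showWarnings = FALSE)
seed <- 20260927L

# complex-IV deletion cross: measured ratio 1:0.71, growth factor 0.98,
# measured dark fractions around 27.6%
cmp <- compare_fast_to_sim(
  observed = c(0.276, 0.281, 0.272), B = 10000L,
  config = sim_config(ratio = 0.71, g_other = 0.98, n_runs = 100L),
  seed = seed, label = "cox2-cross")
print(cmp)
report_to_json(cmp, "results/comparison_cox2.json")

# ATP-synthase deletion cross (illustrative parameterization: a reduced
# copy-number ratio and the measured growth handicap 0.93); here the
# simulation lands near the measured fraction and the verdict is expected
# to be "consistent"
cmp2 <- compare_fast_to_sim(
  observed = c(0.308, 0.315, 0.301), B = 10000L,
  config = sim_config(ratio = 0.52, g_other = 0.93, n_runs = 100L),
  seed = seed + 1L, label = "atp6-cross")
print(cmp2)
report_to_json(cmp2, "results/comparison_atp6.json")

cat("\nInterpretation: a 'simulation exceeds FAST' verdict means growth\n")
cat("and copy-number effects cannot account for the measured depletion of\n")
cat("mutant-mtDNA cells, i.e. an additional intracellular mode of\n")
cat("selection is at work; 'consistent' means they suffice.\n")
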