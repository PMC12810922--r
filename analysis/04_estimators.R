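#!/usr/bin/env Rscript
# Supporting estimators on the synthetic inputs: growth rate and doubling
# time, plate doubling time, fluorescence half-life, qPCR relative copy
# number, growth-factor inference, and skeleton metrics.
# Run analysis/01_synthesize_data.R first.

library(mitofast)

data_dir <- "results/data"

# growth -------------------------------------------------------------------
g <- read_table_tsv(file.path(data_dir, "growth_curve.tsv"))
fit <- fit_growth_rate(g)
cat(sprintf("liquid growth: rate %.4f /h, doubling time %.3f h (r2 %.4f)\n",
            fit$rate, fit$doubling_time, fit$r_squared))
cat(sprintf("plate doubling time from 30 -> 348000 cells in 20 h: %.3f h\n",
            plate_doubling_time(30, 348000, 20)))

# fluorescence half-life ---------------------------------------------------
dec <- read_table_tsv(file.path(data_dir, "cap_decay.tsv"))
cat(sprintf("apparent fluorescence half-life: %.2f h\n", fit_half_life(dec)))

# qPCR relative copy number ------------------------------------------------
cq <- read_table_tsv(file.path(data_dir, "qpcr_cq.tsv"))
cn <- qpcr_relative_cn(cq, "reference")
cat("relative mtDNA copy numbers (vs reference):\n")
print(round(cn, 3))

# growth factor from a post-growth mixing fraction -------------------------
# a strain at 34% of the pooled population after 20 h (13.5 reference
# generations) implies a ~7% growth handicap
G <- 20 / 1.48
cat(sprintf("mixing fraction 0.34 after %.1f generations -> g_other = %.3f\n",
            G, infer_growth_factor(0.34, G)))
cat(sprintf("mixing fraction 0.51 -> g_other = %.3f (near neutral)\n",
            infer_growth_factor(0.51, G)))

# mitochondrial network metrics --------------------------------------------
vt <- read_table_tsv(file.path(data_dir, "zygote_vertices.tsv"))
ns <- network_length(vt)
cat(sprintf("network length: %.2f um over %d lines (%d nodes)\n",
            ns$total_length, ns$n_lines, ns$n_nodes))
rs <- ratiometric_summary(vt, "tmrm", "mtng", "summed")
cat(sprintf("whole-network TMRM/mtNG (summed): %.3f\n", rs$value))
cat(sprintf("P2/P1 compartment ratio: %.3f\n",
            compartment_ratio(vt, "tmrm", "mtng", "summed")))
cat("(the planted P2 signal is half the P1 signal: local reduction of\n")
cat("membrane potential around the mutant-derived network)\n")
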