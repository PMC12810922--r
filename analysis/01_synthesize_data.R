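#!/usr/bin/env Rscript
# Generate every synthetic input the downstream analyses consume, with
# planted ground truth, and write them as TSV under results/data/.

library(mitofast)

seed <- 20260927L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# Flow-cytometry mixtures -------------------------------------------------
# (i) the 20 h segregation population: dark 50.9 / heteroplasmic 3.32 /
# fluorescent 45.8 percent, plus 5% debris off the scatter diagonal
spec <- het_mixture_spec(10000, debris_fraction = 0.05)
write_table_tsv(make_flow_mixture(spec, seed = seed),
                file.path(out, "fast_20h_mixture.tsv"))

# (ii) three biological replicates of the same planted mixture
for (i in 1:3) {
  write_table_tsv(make_flow_mixture(spec, seed = seed + i),
                  file.path(out, sprintf("fast_20h_rep%d.tsv", i)))
}

# (iii) a unimodal non-fluorescent control strain
dark_ctrl <- mixture_spec(
  data.frame(name = "dark", fraction = 1, mean_log10 = 2, sd_log10 = 0.25),
  n_events = 10000)
write_table_tsv(make_flow_mixture(dark_ctrl, seed = seed + 10),
                file.path(out, "dark_control.tsv"))

# Fluorescence decay after halting mitochondrial translation ---------------
# sampled at 0/2/4/6/8 h, apparent half-life 2.7 h, mild measurement noise
write_table_tsv(
  make_decay_series(1000, 2.7, c(0, 2, 4, 6, 8), noise_sd_log = 0.03,
                    seed = seed + 20),
  file.path(out, "cap_decay.tsv"))

# Plate-reader growth curve ------------------------------------------------
# doubling time 1.48 h (rate ln2/1.48), 12 h at 20-minute intervals
write_table_tsv(
  make_growth_curve(0.1, log(2) / 1.48, 12, noise_sd_log = 0.02,
                    seed = seed + 30),
  file.path(out, "growth_curve.tsv"))

# qPCR table ---------------------------------------------------------------
# planted COX1/ACT1 copy numbers relative to the reference strain; the
# mutant strain carries the measured 0.71 ratio
write_table_tsv(
  make_qpcr_table(c(reference = 1, intact_il = 1.25, mutant = 0.71),
                  noise_sd = 0.1, replicates = 9, seed = seed + 40),
  file.path(out, "qpcr_cq.tsv"))

# Mitochondrial skeleton with compartment labels ---------------------------
# P2-derived network carries half the numerator signal of P1
vt <- make_vertex_table(
  lines = list(list(n_points = 60, spacing = 0.11),
               list(n_points = 40, spacing = 0.11, origin = c(0, 2, 0),
                    direction = c(1, 0.3, 0.1))),
  channels = list(
    tmrm = function(x, y, z) ifelse(y < 1, 200, 100),
    mtng = 100),
  compartments = c("P1", "P2"))
write_table_tsv(vt, file.path(out, "zygote_vertices.tsv"))

cat("synthetic inputs written to", out, "\n")
for (f in list.files(out)) cat(" ", f, "\n")
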