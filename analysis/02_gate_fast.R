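#!/usr/bin/env Rscript
# Gate and classify the synthetic flow-cytometry populations: debris gate,
# KDE of the fluorescence channel, peak/valley detection, +/-10% window
# classification, and the dark-control readout for unimodal samples.
# Run analysis/01_synthesize_data.R first.

library(mitofast)

data_dir <- "results/data"
dir.create("results", showWarnings = FALSE)

# single 20 h population --------------------------------------------------
events <- gate_scatter(read_flow_events(file.path(data_dir,
                                                  "fast_20h_mixture.tsv")))
kde <- estimate_kde(events$fl1)
pv <- locate_peaks_valley(kde)
gr <- classify_events(events, pv, window_frac = 0.10)
print(gr)
cat(sprintf("landmarks: peaks %.2f / %.2f, valley %.2f (log10)\n",
            pv$peak_lo, pv$peak_hi, pv$valley))

# three replicates through the same chain ---------------------------------
reps <- lapply(1:3, function(i) {
  read_flow_events(file.path(data_dir, sprintf("fast_20h_rep%d.tsv", i)))
})
names(reps) <- paste0("rep", 1:3)
rep_tab <- run_fast_report(reps)
print(rep_tab[, c("replicate", "f_dark", "f_het", "f_fluor", "unimodal")])
write_table_tsv(rep_tab, "results/fast_report.tsv")

# dark fraction of the control strain against itself (false-positive floor)
ctrl <- gate_scatter(read_flow_events(file.path(data_dir,
                                                "dark_control.tsv")))
cat(sprintf("dark-control self fraction at the 99.9%% threshold: %.4f\n",
            dark_fraction_control(ctrl, ctrl)))

cat("\nThe planted fractions (dark 0.509 / het 0.0332 / fluor 0.458,\n")
cat("normalized) should be recovered within sampling error; the replicate\n")
cat("table is in results/fast_report.tsv\n")
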