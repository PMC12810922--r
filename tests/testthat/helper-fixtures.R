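# shared fixture builders; everything is generated in code

# straight-line vertex table: n points along +x at `spacing` um
straight_line_vt <- function(n = 11, spacing = 0.5, channels = list(ch = 1)) {
  make_vertex_table(list(list(n_points = n, spacing = spacing)), channels)
}

# random 3-D polyline as a raw data frame (bypasses the generator so it can
# serve as an independent check of network_length)
random_polyline <- function(n = 200, seed = 1) {
  set.seed(seed)
  data.frame(line_id = 1L, point_id = seq_len(n),
             x = cumsum(rnorm(n)), y = cumsum(rnorm(n)), z = cumsum(rnorm(n)))
}

# two-component event table with a planted dark fraction among fluorescent
dark_spike_events <- function(n, f_dark, seed) {
  comps <- data.frame(name = c("dark", "fluor"),
                      fraction = c(f_dark, 1 - f_dark),
                      mean_log10 = c(2, 4), sd_log10 = c(0.25, 0.25))
  make_flow_mixture(mixture_spec(comps, n), seed = seed)
}
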