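#!/usr/bin/env Rscript
# Stage 4 - figures.
#
# Bode overlays of one representative device per arm across the 24-hour
# intervention, and the group-level metric trajectories (normalised 500 Hz
# cross-section and R_b fold-change). Writes PDFs under results/figures/.

suppressPackageStartupMessages({
  library(barrierEIS)
  library(ggplot2)
})

dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)
man <- read_manifest("results/dataset/manifest.json")
tcs <- load_timecourses(man)
metrics <- utils::read.csv("results/report/metrics.csv",
                           stringsAsFactors = FALSE)

# Bode magnitude evolution, first technical device of each arm
reps <- names(tcs)[grepl("_b1_t1$", names(tcs))]
bode_df <- do.call(rbind, lapply(reps, function(id) {
  tc <- tcs[[id]]
  do.call(rbind, lapply(seq_along(tc$timepoints), function(j) {
    b <- bode(tc$spectra[[j]])
    data.frame(intervention = tc$intervention,
               timepoint_h = tc$timepoints[j], b)
  }))
}))
p1 <- ggplot(bode_df, aes(frequency_hz, magnitude_ohm,
                          colour = factor(timepoint_h))) +
  geom_line() +
  scale_x_log10() + scale_y_log10() +
  facet_wrap(~intervention) +
  labs(x = "frequency (Hz)", y = "|Z| (Ohm)", colour = "time (h)",
       title = "Impedance magnitude during the 24-hour interventions") +
  theme_bw()
ggsave("results/figures/bode_timecourses.pdf", p1, width = 9, height = 6)

# group-mean metric trajectories
traj <- aggregate(value ~ intervention + timepoint_h + metric,
                  data = metrics[metrics$metric %in%
                                   c("norm_z500", "rb_foldchange"), ],
                  FUN = mean)
p2 <- ggplot(traj, aes(timepoint_h, value, colour = intervention)) +
  geom_line() + geom_point() +
  facet_wrap(~metric, labeller = as_labeller(
    c(norm_z500 = "|Z(500 Hz)| / baseline",
      rb_foldchange = "R_b fold-change vs baseline"))) +
  labs(x = "time post-inoculation (h)", y = "normalised value",
       title = "Barrier-integrity metrics (group means)") +
  theme_bw()
ggsave("results/figures/metric_trajectories.pdf", p2, width = 9, height = 4)

message("wrote results/figures/bode_timecourses.pdf and ",
        "results/figures/metric_trajectories.pdf")
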