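# Electrodermal phasic activity: differencing and MAD-band peak rates.
#
# First-differences each skin-conductance segment, counts values above
# the per-segment median + 2*MAD band, normalizes to peaks/minute, drops
# active-arm start-of-day segments (preparation time, no task yet), and
# compares the per-participant distributions between the active and sham
# arms, ordered by median.

source(file.path("analysis", "00_config.R"))

spec <- analysis_spec()
eda <- simulate_eda(spec)
eda_kept <- filter_start_of_day(eda)
message("EDA: removed ", attr(eda_kept, "n_removed_segments"),
        " start-of-day segments")

stats <- eda_segment_stats(eda_kept)
summary <- arm_peak_summary(stats)
arm_medians <- tapply(summary$median, summary$arm, median)
message("median of per-participant median peaks/min: DTxP ",
        signif(arm_medians[["DTxP"]], 3), " vs Sham ",
        signif(arm_medians[["Sham"]], 3),
        " (configured pulse rates ", spec$eda_pulse_rate[["DTxP"]], " vs ",
        spec$eda_pulse_rate[["Sham"]], "/min)")

write_table(stats, "eda_segment_stats")
write_table(summary, "eda_participant_summary")

p <- plot_peak_distributions(stats)
ggplot2::ggsave(file.path(results_dir, "eda_peaks_by_participant.png"),
                p, width = 9, height = 4, dpi = 120)
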