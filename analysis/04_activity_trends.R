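# Daily steps: weekly change distributions and per-participant trends.
#
# Aggregates daily step counts to study weeks as change-from-week-1, and
# fits a per-participant OLS line of steps on study day with an
# arm-level summary of the slopes. Heart rate and sleep are described
# only; their daily aggregation is too coarse for modeling.

source(file.path("analysis", "00_config.R"))

spec <- analysis_spec()
activity <- simulate_activity(spec)

weekly <- weekly_step_changes(activity)
trends <- participant_step_trends(activity)

s <- trends$arm_summary
message("arm mean step slopes (steps/day per day):")
for (i in seq_len(nrow(s))) {
  message("  ", s$arm[i], ": ", signif(s$mean_slope[i], 3),
          " (sd ", signif(s$sd_slope[i], 3), ", n ", s$n[i], ")")
}
dtxp_vs_sham <- trends$arm_differences$mean_slope_diff[
  trends$arm_differences$arm_a == "DTxP" &
    trends$arm_differences$arm_b == "Sham"]
message("DTxP - Sham: ", signif(dtxp_vs_sham * 7, 3),
        " steps/week (injected ",
        spec$steps_weekly_trend[["DTxP"]] -
          spec$steps_weekly_trend[["Sham"]], ")")

write_table(weekly, "weekly_step_changes")
write_table(trends$slopes, "step_slopes")
write_table(trends$arm_summary, "step_arm_summary")
write_table(activity_descriptives(activity), "activity_descriptives")

p <- plot_weekly_steps(weekly)
ggplot2::ggsave(file.path(results_dir, "weekly_steps.png"), p,
                width = 8, height = 4, dpi = 120)
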