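# Generate the synthetic cohort and record its ground truth.
#
# Draws the per-participant latent improvement effects and the clinical,
# activity and (summarized) motion/EDA streams for the desk-scale cohort.
# The ground-truth effects table is what the later drivers' recovered
# estimates are judged against.

source(file.path("analysis", "00_config.R"))

spec <- analysis_spec()
cohort <- simulate_cohort(spec)

message("simulated cohort, seed ", spec$seed, ":")
message("  ", nrow(cohort$effects), " DTxP participants, ",
        spec$n_study_days, " study days")
message("  motion samples: ", nrow(cohort$motion), " (",
        round(nrow(cohort$motion) / spec$n_participants), " per participant)")
message("  EDA samples: ", nrow(cohort$eda))
message("  activity days: ", nrow(cohort$activity))
message("  latent daily slopes: mean ",
        signif(mean(cohort$effects$beta), 3), " m/s/day, range [",
        signif(min(cohort$effects$beta), 3), ", ",
        signif(max(cohort$effects$beta), 3), "]")

write_table(cohort$effects, "ground_truth_effects")
write_table(cohort$clinical, "clinical_changes")
write_table(cohort$activity, "activity_days")
# a small raw-stream extract for inspection; the full streams are
# regenerated from the seed by the downstream drivers
demo <- cohort$motion[cohort$motion$participant_id == "P001" &
                        cohort$motion$sensor == "right" &
                        cohort$motion$study_day == 1L, ]
write_table(demo, "motion_stream_demo_p001_right_day1")
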