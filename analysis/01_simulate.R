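#!/usr/bin/env Rscript

# Stage 1 — simulate the study cohort.
#
# Draws the 125-subject cohort (40 young adults, 62 healthy elderly, 23
# cognitively impaired elderly, with the reference demographics), their
# twelve cognitive test measures, and a separate 400-subject normative
# sample, and writes all three tables under results/. One example
# trunk-acceleration recording is also exported so the delimited format is
# visible on disk.

suppressPackageStartupMessages(library(gaitssc))
dir.create("results", showWarnings = FALSE)
root_seed <- 1L

cohort <- generate_cohort(cohort_spec(seed = derive_seed(root_seed, "cohort")))
scores <- generate_cognitive_scores(cohort, seed = derive_seed(root_seed, "scores"))
normative <- generate_normative_scores(400, seed = derive_seed(root_seed, "normative"))

write.csv(cohort, "results/cohort.csv", row.names = FALSE)
write.csv(scores, "results/scores.csv", row.names = FALSE)
write.csv(normative, "results/normative.csv", row.names = FALSE)

pr <- default_gait_profiles()[["HE"]][["NormalW"]]
sim <- generate_acceleration(pr, task = "NormalW", seed = derive_seed(root_seed, "demo"),
                             subject_id = cohort$id[41])
write_recording(sim$recording, "results/example_recording.csv")
write_events(as_gait_events(sim$events, c(0, sim$turn["start"])),
             "results/example_events.csv")

cat(sprintf("Cohort: %d subjects (%s)\n", nrow(cohort),
            paste(table(cohort$group), collapse = " / ")))
cat(sprintf("Example recording: %.1f s at 100 Hz, turn gap at %.1f-%.1f s\n",
            max(sim$recording$t), sim$turn["start"], sim$turn["end"]))
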