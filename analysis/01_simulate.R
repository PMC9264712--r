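#!/usr/bin/env Rscript
# Build the working dataset: a synthetic exit-interview survey at the study
# scale (1407 patients, 150 facilities), written as the canonical CSV with
# its ground-truth sidecar so later stages can be checked against known
# parameters.

suppressPackageStartupMessages(library(equicost))

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
cfg <- generator_config(seed = 20120117)  # survey period: January 2012
survey <- generate_survey(cfg)

write_exit_interviews(survey, "results/data/exit_interviews.csv")
write_ground_truth(survey, "results/data/ground_truth_patients.csv",
                   "results/data/ground_truth_params.csv")

rec <- survey$records
message(sprintf("Simulated %d patients in %d facilities.", n_records(survey),
                length(unique(rec$facility_id))))
message(sprintf("On foot: %.1f%%; rural: %.1f%%; public facilities: %.1f%% of visits.",
                100 * mean(rec$travel_mode == "foot"),
                100 * mean(rec$residence == "rural"),
                100 * mean(rec$ownership == "public")))
message(sprintf("Paying for transport: %.1f%%; paying for care: %.1f%%.",
                100 * mean(rec$transport_cost_tzs > 0, na.rm = TRUE),
                100 * mean(rec$medical_cost_tzs > 0, na.rm = TRUE)))
message("Wrote results/data/exit_interviews.csv and ground-truth sidecars.")
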