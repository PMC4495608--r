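#!/usr/bin/env Rscript
# Stage 2 -- preprocessing of the continuous recording.
#
# filter (8-300 Hz, zero phase) -> epoch (-100..+200 ms) -> reject trials
# exceeding 100 uV -> average ~80 sweeps -> baseline-correct (-80..-30 ms)
# -> re-reference to the average reference (the vertex reference becomes a
# 33rd channel). Verifies that exactly the planted artifact trials are
# rejected.

library(ssepmap)

out <- "results"
rec <- read_recording("results/data/median_session_raw.edf")
truth <- jsonlite::read_json("results/data/median_session_truth.json",
                             simplifyVector = TRUE)

pp <- preprocess_recording(rec, default_config())
cat("trials:", pp$report$n_trials,
    "| kept:", pp$report$n_kept,
    "| rejected:", pp$report$n_rejected,
    "| planted artifacts:", length(truth$artifact_trials), "\n")
rejected <- which(!pp$epochs$kept)
cat("rejected == planted:",
    identical(sort(rejected), sort(truth$artifact_trials)), "\n")

write_evoked(pp$evoked, file.path(out, "median_session_evoked.tsv"))
jsonlite::write_json(pp$report, file.path(out, "rejection_report.json"),
                     auto_unbox = TRUE, digits = NA)

bsel <- in_window(pp$evoked$times, c(-80, -30))
cat("max |baseline mean| per channel:",
    format(max(abs(rowMeans(pp$evoked$data[, bsel]))), digits = 3), "uV\n")
cat("n_sweeps:", pp$evoked$n_sweeps, "(about 80 sweeps)\n")
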