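#!/usr/bin/env Rscript
# Stage 1 -- synthesize the study data.
#
# Emulates the acquisition protocol: median- and tibial-nerve SSEP sessions
# recorded with a 33-electrode whole-scalp cap in an anaesthetized macaque,
# 0.5 Hz stimulation for 3 minutes (90 stimuli), 5 kHz sampling. Nine
# sessions per nerve are generated at the epoch level with per-session cap
# perturbation; one full continuous median session (with planted artifact
# trials) is additionally written out in both EDF and delimited-text form
# so the preprocessing stage can exercise the file readers.

library(ssepmap)

seed <- 20260919L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

montage <- macaque33_montage()
write_montage(montage, file.path(out, "montage_macaque33.txt"))

for (nerve in c("median", "tibial")) {
  script <- make_default_script(nerve, montage)
  study <- synthesize_study(script, noise_spec(), n_sessions = 9,
                            n_trials = 90, seed = seed)
  for (s in seq_along(study$sessions))
    write_evoked(study$sessions[[s]],
                 file.path(out, sprintf("%s_evoked_%02d.tsv", nerve, s)))
  truth <- study$truths[[1]]
  jsonlite::write_json(
    list(nerve = nerve, K = script$K, boundaries = script$boundaries,
         peak_ms = script$peak_ms, peak_gfp = script$peak_gfp,
         n_sessions = 9, n_trials = 90, seed = seed,
         rotation_deg = vapply(study$truths,
                               function(t) t$rotation$angle_deg, 0)),
    file.path(out, sprintf("%s_ground_truth.json", nerve)),
    auto_unbox = TRUE, digits = NA)
  write.table(data.frame(time_ms = truth$times, state = truth$labels),
              file.path(out, sprintf("%s_state_labels.tsv", nerve)),
              quote = FALSE, row.names = FALSE, sep = "\t")
  cat(nerve, "script: K =", script$K, "| boundaries",
      paste(script$boundaries, collapse = "/"), "ms |",
      length(study$sessions), "sessions written\n")
}

# one continuous median session with 10 % planted artifact trials
script <- make_default_script("median", montage)
ses <- synthesize_session(script, noise_spec(artifact_fraction = 0.1),
                          duration_min = 3, rate = 5000, seed = seed + 1)
write_recording(ses$recording, file.path(out, "median_session_raw.edf"))
write_recording(ses$recording, file.path(out, "median_session_raw.tsv"))
jsonlite::write_json(
  list(artifact_trials = ses$truth$artifact_trials,
       n_events = nrow(ses$recording$events)),
  file.path(out, "median_session_truth.json"),
  auto_unbox = TRUE, digits = NA)
cat("continuous session:", nrow(ses$recording$events), "stimuli,",
    length(ses$truth$artifact_trials), "planted artifact trials\n")
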