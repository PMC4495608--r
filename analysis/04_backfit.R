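#!/usr/bin/env Rscript
# Stage 4 -- back-fitting and intraindividual stability.
#
# Fits the GA-derived templates back to each of the 9 individual sessions,
# computes the eight topographic parameters per map and session, summarizes
# the stability surface (mean/SD of onset latencies, best-SC latencies and
# mean SC across sessions) and tests whether successive component maps have
# separable latencies (t-test or Mann-Whitney after a normality gate,
# Bonferroni-corrected by the electrode count).

library(ssepmap)

montage <- macaque33_montage()
out <- "results"

for (nerve in c("median", "tibial")) {
  sessions <- lapply(sprintf("results/data/%s_evoked_%02d.tsv", nerve, 1:9),
                     read_evoked, montage = montage)
  tm <- as.matrix(read.delim(sprintf("results/%s_templates.tsv", nerve),
                             row.names = 1))
  window <- if (nerve == "median") c(6, 50) else c(10.8, 60)
  fits <- backfit_sessions(sessions, tm, window)
  write.table(fits, file.path(out, sprintf("%s_fit_parameters.tsv", nerve)),
              quote = FALSE, row.names = FALSE, sep = "\t")

  cat("\n==", nerve, "nerve back-fitting across 9 sessions ==\n")
  summ <- do.call(rbind, lapply(split(fits, fits$map), function(d)
    data.frame(map = d$map[1],
               onset_mean = mean(d$latency_first_onset),
               onset_sd = sd(d$latency_first_onset),
               best_sc_mean = mean(d$latency_best_sc),
               best_sc_sd = sd(d$latency_best_sc),
               mean_sc = mean(d$mean_sc),
               sc_sd = sd(d$mean_sc))))
  print(summ, digits = 3, row.names = FALSE)
  tot <- tapply(fits$gev, fits$session, sum)
  cat("mean total GEV across sessions:",
      round(100 * mean(tot), 2), "% (SD",
      round(100 * sd(tot), 2), ")\n")

  st <- compare_successive_map_latencies(fits, alpha = 0.01,
                                         n_electrodes = 33)
  write.table(st, file.path(out, sprintf("%s_latency_stats.tsv", nerve)),
              quote = FALSE, row.names = FALSE, sep = "\t")
  cat(sum(st$test == "t"), "t-tests and", sum(st$test == "mann-whitney"),
      "Mann-Whitney tests;", sum(st$significant),
      "of", nrow(st), "comparisons significant after Bonferroni\n")
}
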