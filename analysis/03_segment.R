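#!/usr/bin/env Rscript
# Stage 3 -- microstate segmentation of the grand averages.
#
# Clusters the median-nerve GA (6-50 ms) and the tibial-nerve GA
# (10.8-60 ms) with the modified K-means, picks K with the Krzanowski-Lai
# and cross-validation criteria, and compares the recovered templates and
# state boundaries with the planted ground truth.

library(ssepmap)

montage <- macaque33_montage()
out <- "results"

for (nerve in c("median", "tibial")) {
  sessions <- lapply(sprintf("results/data/%s_evoked_%02d.tsv", nerve, 1:9),
                     read_evoked, montage = montage)
  ga <- grand_average(sessions)
  window <- if (nerve == "median") c(6, 50) else c(10.8, 60)
  sel <- select_k(ga, window, k_range = 1:8, restarts = 50, seed = 2)
  cat("\n==", nerve, "nerve GA ==\n")
  print(sel$curve, digits = 4)
  cat("KL selects K =", sel$best_k_kl, "| CV selects K =", sel$best_k_cv, "\n")

  best <- sel$segmentations[[match(sel$best_k_kl, sel$curve$K)]]
  # renumber the maps in order of first appearance so map 1 is the earliest
  ord <- order(vapply(seq_len(best$templates$K), function(k)
    min(which(best$labeling$labels == k)), 0))
  best$templates$templates <- best$templates$templates[, ord, drop = FALSE]
  best$labeling$labels <- match(best$labeling$labels, ord)
  cat("total GEV of the segmentation:",
      round(100 * best$templates$gev_total, 2), "%\n")

  truth <- jsonlite::read_json(
    sprintf("results/data/%s_ground_truth.json", nerve),
    simplifyVector = TRUE)
  script <- make_default_script(nerve, montage)
  M <- abs(crossprod(best$templates$templates, script$templates)) /
    outer(sqrt(colSums(best$templates$templates^2)),
          sqrt(colSums(script$templates^2)))
  cat("best |SC| of each recovered template to a planted one:",
      paste(round(apply(M, 1, max), 3), collapse = " "), "\n")

  runs <- rle(best$labeling$labels)
  onsets <- best$labeling$times[cumsum(c(1, head(runs$lengths, -1)))]
  cat("recovered state onsets (ms):", paste(onsets, collapse = ", "),
      "| planted:", paste(head(truth$boundaries, -1), collapse = ", "), "\n")

  write.table(sel$curve, file.path(out, sprintf("%s_criterion_curve.tsv",
                                                nerve)),
              quote = FALSE, row.names = FALSE, sep = "\t")
  write.table(data.frame(channel = rownames(best$templates$templates),
                         best$templates$templates),
              file.path(out, sprintf("%s_templates.tsv", nerve)),
              quote = FALSE, row.names = FALSE, sep = "\t")
  write.table(data.frame(time_ms = best$labeling$times,
                         map = best$labeling$labels),
              file.path(out, sprintf("%s_labels.tsv", nerve)),
              quote = FALSE, row.names = FALSE, sep = "\t")
}
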