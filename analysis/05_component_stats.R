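#!/usr/bin/env Rscript
# Stage 5 -- pre/post "craniotomy" comparison.
#
# The craniotomy itself is not modelled (the skull stays a uniform shell);
# instead two groups of 4 sessions are synthesized under identical
# conditions, which is the expected outcome of a sealed bone-flap
# replacement: the analysis chain should find (i) no electrodewise
# amplitude differences, (ii) no classical component differences, and
# (iii) no differences in the eight topographic fitting parameters.

library(ssepmap)

montage <- macaque33_montage()
script <- make_default_script("median", montage)
out <- "results"

pre <- synthesize_study(script, noise_spec(), n_sessions = 4,
                        n_trials = 90, seed = 101)$sessions
post <- synthesize_study(script, noise_spec(), n_sessions = 4,
                         n_trials = 90, seed = 202)$sessions

# (i) electrode x time amplitude comparison, p < 0.01 Bonferroni-by-33
res <- electrodewise_ttest(pre, post, alpha = 0.01, window = c(0, 60))
cat("electrodewise comparison over 0-60 ms:",
    sum(res$mask), "significant cells of", length(res$mask), "\n")
write.table(data.frame(channel = rownames(res$mask), res$mask),
            file.path(out, "prepost_electrodewise_mask.tsv"),
            quote = FALSE, row.names = FALSE, sep = "\t")

# (ii) classical component measures: brainstem and cortical peaks on the
# role electrodes and the GFP, amplitude and latency, 8 unpaired t-tests
cmp <- compare_component_measures(pre, post,
                                  default_component_specs(montage),
                                  alpha = 0.01)
print(cmp[, c("component", "channel", "measure", "mean_A", "mean_B",
              "p_value", "significant")], digits = 3, row.names = FALSE)
cat("significant component differences:",
    sum(cmp$significant, na.rm = TRUE), "of", nrow(cmp), "\n")
write.table(cmp, file.path(out, "prepost_component_stats.tsv"),
            quote = FALSE, row.names = FALSE, sep = "\t")

# (iii) the eight topographic parameters, map by map (common clustering:
# templates from the pooled grand average of all 8 sessions)
ga <- grand_average(c(pre, post))
seg <- kmeans_segment(ga, c(6, 50), K = 4, restarts = 50, seed = 3)
seg <- postprocess_clusters(seg$templates, seg$labeling, ga)
fits_pre <- backfit_sessions(pre, seg$templates, c(6, 50))
fits_post <- backfit_sessions(post, seg$templates, c(6, 50))
grp <- compare_groups(fits_pre, fits_post, alpha = 0.01, n_electrodes = 33)
cat("fitting-parameter comparison:",
    sum(grp$significant, na.rm = TRUE), "significant of", nrow(grp),
    "(map x parameter) cells\n")
write.table(grp, file.path(out, "prepost_fitting_stats.tsv"),
            quote = FALSE, row.names = FALSE, sep = "\t")
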