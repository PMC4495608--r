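#' Grand average of session evokeds
#' @param evokeds list of `ssep_evoked` with identical shape
#' @return an `ssep_evoked` averaging the sessions; `n_sweeps` sums
#' @export
grand_average <- function(evokeds) {
  stopifnot(length(evokeds) >= 1)
  dat <- Reduce(`+`, lapply(evokeds, function(e) e$data)) / length(evokeds)
  out <- evokeds[[1]]
  out$data <- dat
  out$n_sweeps <- sum(vapply(evokeds, function(e)
    ifelse(is.na(e$n_sweeps), 0L, e$n_sweeps), 0L))
  out
}

#' Run the SSEP analysis pipeline
#'
#' Orchestrates the stages over a configuration: `simulate` (synthesize a
#' multi-session study), `preprocess` (average, baseline-correct and
#' re-reference each session — or read and preprocess recording files when
#' `input` lists paths), `segment` (cluster the grand average and select
#' K), `fit` (back-fit the templates to each session), `stats` (successive
#' map latency comparisons). Outputs are written under `out_dir` as
#' delimited tables plus a JSON log of all parameters and seeds, so a rerun
#' with the same config and seed is byte-identical.
#'
#' @param config an `ssep_config`, or the path of a YAML config file
#' @param out_dir output directory (created if needed)
#' @param input `"simulate"` or a character vector of recording paths
#' @param stages stages to run, in order
#' @param nerve `"median"` or `"tibial"` (simulate path)
#' @param n_sessions,n_trials study size (simulate path)
#' @param rate sampling rate for simulation (Hz)
#' @param restarts K-means restarts for the segment stage
#' @param k_range candidate K values (default from config)
#' @param noise an `ssep_noise` for the simulate path
#' @return (invisibly) a list of in-memory stage results
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         input = "simulate",
                         stages = c("simulate", "preprocess", "segment",
                                    "fit", "stats"),
                         nerve = "median", n_sessions = 9, n_trials = 90,
                         rate = 5000, restarts = 100, k_range = NULL,
                         noise = noise_spec()) {
  cfg <- if (is.character(config)) read_config(config) else config
  known <- c("simulate", "preprocess", "segment", "fit", "stats", "inverse")
  if (!all(stages %in% known)) stop("unknown stage(s)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = cfg)
  log <- list(config = unclass(cfg), stages = stages, nerve = nerve,
              n_sessions = n_sessions, n_trials = n_trials, rate = rate)
  montage <- macaque33_montage()
  seg_window <- if (nerve == "median") cfg$seg_window_median
                else cfg$seg_window_tibial
  log$seg_window <- seg_window

  if ("simulate" %in% stages) {
    script <- make_default_script(nerve, montage)
    study <- synthesize_study(script, noise, n_sessions = n_sessions,
                              n_trials = n_trials, rate = rate,
                              seed = cfg$seed, level = "epochs",
                              window = cfg$epoch_ms)
    res$study <- study
    log$simulate <- list(seed = cfg$seed, K_planted = script$K)
  }

  if ("preprocess" %in% stages) {
    if (identical(input, "simulate")) {
      if (is.null(res$study)) stop("preprocess requires the simulate stage")
      evokeds <- lapply(res$study$sessions, function(ep) {
        kept <- apply(abs(ep$data), 1, max) <= cfg$reject_uV
        ep$kept <- kept
        average_reference(average_epochs(ep, cfg$baseline_ms))
      })
    } else {
      evokeds <- lapply(input, function(p) {
        rec <- read_recording(p)
        preprocess_recording(rec, cfg)$evoked
      })
    }
    res$evokeds <- evokeds
    for (s in seq_along(evokeds))
      write_evoked(evokeds[[s]],
                   file.path(out_dir, sprintf("evoked_%02d.tsv", s)))
    log$preprocess <- list(n_sessions = length(evokeds),
                           n_sweeps = vapply(evokeds, function(e)
                             e$n_sweeps, 0L))
  }

  if ("segment" %in% stages) {
    if (is.null(res$evokeds)) stop("segment requires the preprocess stage")
    ga <- grand_average(res$evokeds)
    kr <- if (is.null(k_range)) cfg$k_range else k_range
    sel <- select_k(ga, seg_window, k_range = kr, restarts = restarts,
                    seed = cfg$seed, min_frames = cfg$min_frames,
                    merge_sc = cfg$merge_sc)
    best <- sel$segmentations[[match(sel$best_k_kl, sel$curve$K)]]
    res$ga <- ga
    res$selection <- sel
    res$templates <- best$templates
    utils::write.table(sel$curve, file.path(out_dir, "criterion_curve.tsv"),
                       quote = FALSE, row.names = FALSE, sep = "\t")
    utils::write.table(
      data.frame(channel = rownames(best$templates$templates),
                 best$templates$templates),
      file.path(out_dir, "templates.tsv"),
      quote = FALSE, row.names = FALSE, sep = "\t")
    log$segment <- list(window = seg_window, best_k_kl = sel$best_k_kl,
                        best_k_cv = sel$best_k_cv, restarts = restarts,
                        seed = cfg$seed)
  }

  if ("fit" %in% stages) {
    if (is.null(res$templates)) stop("fit requires the segment stage")
    fits <- backfit_sessions(res$evokeds, res$templates, seg_window,
                             min_frames = cfg$min_frames)
    res$fits <- fits
    utils::write.table(fits, file.path(out_dir, "fit_parameters.tsv"),
                       quote = FALSE, row.names = FALSE, sep = "\t")
    log$fit <- list(n_rows = nrow(fits))
  }

  if ("stats" %in% stages) {
    if (is.null(res$fits)) stop("stats requires the fit stage")
    st <- compare_successive_map_latencies(res$fits,
                                           alpha = cfg$alpha_scalp,
                                           n_electrodes = length(montage$labels))
    res$latency_stats <- st
    utils::write.table(st, file.path(out_dir, "latency_stats.tsv"),
                       quote = FALSE, row.names = FALSE, sep = "\t")
  }

  if ("inverse" %in% stages) {
    if (is.null(res$ga)) stop("inverse requires the segment stage")
    space <- build_source_space(head_model(), n_target = 3000)
    lf <- compute_leadfield(head_model(), montage, space)
    op <- loreta_operator(lf, n_alphas = cfg$n_alphas)
    cd <- estimate_cd(op, res$ga, alpha_select = "gcv")
    res$cd <- cd
    utils::write.table(
      data.frame(space$points, cd_mean = rowMeans(cd$magnitude)),
      file.path(out_dir, "cd_mean.tsv"),
      quote = FALSE, row.names = FALSE, sep = "\t")
    log$inverse <- list(n_sources = nrow(space$points),
                        alpha_index = cd$alpha_index)
  }

  jsonlite::write_json(log, file.path(out_dir, "pipeline_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
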