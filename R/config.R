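#' Analysis configuration
#'
#' `default_config()` returns the full set of pipeline constants used by the
#' study design this package reproduces: an 8-300 Hz analysis band, a 100 uV
#' absolute rejection threshold, a -80..-30 ms pre-stimulus baseline, a
#' 6-50 ms (median nerve) / 10.8-60 ms (tibial nerve) segmentation window,
#' template merging above a spatial correlation of 0.92, a 2-frame minimum
#' segment duration (0.4 ms at 5 kHz), 13 Tikhonov regularization levels and
#' significance levels of 0.01 (scalp statistics, Bonferroni-corrected by the
#' number of electrodes) and 0.05 (source statistics, uncorrected).
#'
#' @return a named list of class `ssep_config`
#' @export
default_config <- function() {
  structure(list(
    filter_lo       = 8,          # Hz, band-pass low edge
    filter_hi       = 300,        # Hz, band-pass high edge
    notch50         = FALSE,      # optional 50 Hz notch
    reject_uV       = 100,        # absolute amplitude rejection threshold
    baseline_ms     = c(-80, -30),
    epoch_ms        = c(-100, 200),
    seg_window_median = c(6, 50),     # ms post-stimulus
    seg_window_tibial = c(10.8, 60),  # ms post-stimulus
    k_range         = 1:10,
    merge_sc        = 0.92,       # template merge threshold (signed SC)
    min_frames      = 2,          # minimum segment duration, frames
    n_alphas        = 13,         # Tikhonov regularization grid size
    alpha_scalp     = 0.01,       # scalp-stat significance level
    alpha_source    = 0.05,       # source-stat significance level
    seed            = 1L
  ), class = "ssep_config")
}

#' Read / write an analysis configuration (YAML)
#'
#' Unknown keys are rejected so that typos in a config file fail loudly;
#' missing keys fall back to [default_config()].
#' @param path YAML file path
#' @return an `ssep_config`
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  bad <- setdiff(names(raw), names(cfg))
  if (length(bad)) stop("invalid config keys: ", paste(bad, collapse = ", "))
  for (k in names(raw)) {
    v <- raw[[k]]
    if (k == "k_range" && length(v) == 2) v <- v[1]:v[2]
    cfg[[k]] <- if (is.numeric(cfg[[k]]) && !is.integer(cfg[[k]]))
      as.numeric(v) else v
  }
  cfg
}

#' @rdname read_config
#' @param cfg an `ssep_config`
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
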