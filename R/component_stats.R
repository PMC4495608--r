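#' Peak amplitude and latency of a waveform component
#'
#' Classical component analysis: the extremum of the requested polarity
#' within a search window, on a single electrode or on the GFP waveform
#' (`channel = "GFP"`, which always uses `polarity = "max"`). The latency is
#' the peak frame's time from stimulus onset; a peak falling on a window
#' edge is flagged as a boundary hit, and a flat signal is flagged missing.
#'
#' @param evoked an `ssep_evoked`
#' @param channel electrode label, or `"GFP"`
#' @param window search window `c(t0, t1)` ms
#' @param polarity `"neg"`, `"pos"` or `"max"` (largest absolute value)
#' @param component optional component name carried into the result
#' @return one-row data.frame: component, channel, polarity, latency (ms),
#'   amplitude (uV), `boundary_hit`, `missing`
#' @export
detect_component <- function(evoked, channel, window,
                             polarity = c("neg", "pos", "max"),
                             component = NA_character_) {
  polarity <- match.arg(polarity)
  sel <- in_window(evoked$times, window)
  if (!any(sel)) stop("empty search window")
  times <- evoked$times[sel]
  if (identical(channel, "GFP")) {
    y <- gfp(evoked$data[, sel, drop = FALSE])
    polarity <- "max"
  } else {
    if (!channel %in% rownames(evoked$data)) stop("unknown channel ", channel)
    y <- evoked$data[channel, sel]
  }
  flat <- stats::sd(y) == 0
  i <- switch(polarity,
              neg = which.min(y),
              pos = which.max(y),
              max = which.max(abs(y)))
  data.frame(component = component, channel = channel, polarity = polarity,
             latency = times[i], amplitude = y[i],
             boundary_hit = i == 1L || i == length(y),
             missing = flat)
}

#' Default component search specifications
#'
#' The two classical components measured in this pipeline, using the
#' montage role metadata (the deep-posterior `"e32"`-like channel for the
#' brainstem component and the contralateral sensorimotor `"e12"`-like
#' channel for the main cortical component), each also measured on the GFP
#' waveform.
#' @param montage an `ssep_montage` with `roles`
#' @return list of spec lists (component, channel, window, polarity)
#' @export
default_component_specs <- function(montage = macaque33_montage()) {
  list(
    list(component = "brainstem", channel = montage$roles$e32,
         window = c(4, 10), polarity = "neg"),
    list(component = "brainstem", channel = "GFP",
         window = c(4, 10), polarity = "max"),
    list(component = "cortical", channel = montage$roles$e12,
         window = c(12, 25), polarity = "pos"),
    list(component = "cortical", channel = "GFP",
         window = c(12, 25), polarity = "max"))
}

# vectorized two-sample pooled-variance t-test over matching array cells;
# returns t, two-sided p and a flag for zero-variance cells
cellwise_ttest <- function(A, B) {
  nA <- length(A); nB <- length(B)
  mA <- Reduce(`+`, A) / nA
  mB <- Reduce(`+`, B) / nB
  ssA <- Reduce(`+`, lapply(A, function(x) (x - mA)^2))
  ssB <- Reduce(`+`, lapply(B, function(x) (x - mB)^2))
  df <- nA + nB - 2
  sp2 <- (ssA + ssB) / df
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  zero <- se == 0
  t <- (mA - mB) / ifelse(zero, 1, se)
  t[zero] <- 0
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p[zero] <- 1
  list(t = t, p = p, df = df, zero_variance = zero)
}

#' Electrode x time group comparison of evoked amplitudes
#'
#' Two-tailed unpaired (pooled-variance) t-tests at every (electrode,
#' frame) cell between two groups of evoked responses, Bonferroni-corrected
#' by the electrode count: a cell is significant iff its p-value is below
#' `alpha / n_electrodes`. Cells with zero variance in both groups are not
#' significant and flagged.
#'
#' @param groupA,groupB lists of `ssep_evoked` sharing montage and window
#' @param alpha base significance level
#' @param window optional `c(t0, t1)` ms restriction (default: full epoch)
#' @return list: `t`, `p` (electrodes x frames), `mask` (logical
#'   significance), `threshold`, `times`, `zero_variance`
#' @export
electrodewise_ttest <- function(groupA, groupB, alpha = 0.01,
                                window = NULL) {
  stopifnot(length(groupA) >= 2, length(groupB) >= 2)
  ref <- groupA[[1]]
  sel <- if (is.null(window)) rep(TRUE, ncol(ref$data))
         else in_window(ref$times, window)
  getm <- function(ev) {
    stopifnot(identical(dim(ev$data), dim(ref$data)))
    ev$data[, sel, drop = FALSE]
  }
  res <- cellwise_ttest(lapply(groupA, getm), lapply(groupB, getm))
  n_e <- nrow(ref$data)
  thr <- alpha / n_e
  mask <- res$p < thr & !res$zero_variance
  dimnames(mask) <- dimnames(res$t) <- dimnames(res$p) <-
    list(rownames(ref$data), NULL)
  list(t = res$t, p = res$p, mask = mask, threshold = thr,
       times = ref$times[sel], zero_variance = res$zero_variance)
}

#' Compare classical component measures between two groups
#'
#' Detects each specified component in every evoked of both groups and
#' compares amplitude and latency with two-tailed unpaired t-tests at
#' `alpha` (uncorrected, mirroring the 8-test classical comparison).
#' Components flagged missing are excluded as observations.
#'
#' @inheritParams electrodewise_ttest
#' @param specs list of component specs (see [default_component_specs()])
#' @return data.frame: component, channel, measure, group means/SDs, t, p,
#'   significance at `alpha`
#' @export
compare_component_measures <- function(groupA, groupB,
                                       specs = default_component_specs(),
                                       alpha = 0.01) {
  detect_all <- function(group) {
    do.call(rbind, lapply(group, function(ev)
      do.call(rbind, lapply(specs, function(s)
        detect_component(ev, s$channel, s$window, s$polarity,
                         component = s$component)))))
  }
  da <- detect_all(groupA); db <- detect_all(groupB)
  rows <- list()
  for (s in specs) {
    for (measure in c("amplitude", "latency")) {
      a <- da[da$component == s$component & da$channel == s$channel &
                !da$missing, measure]
      b <- db[db$component == s$component & db$channel == s$channel &
                !db$missing, measure]
      res <- tryCatch({
        tt <- stats::t.test(a, b, var.equal = TRUE)
        list(t = unname(tt$statistic), p = tt$p.value)
      }, error = function(e) list(t = NA_real_, p = NA_real_))
      rows[[length(rows) + 1]] <- data.frame(
        component = s$component, channel = s$channel, measure = measure,
        mean_A = mean(a), sd_A = stats::sd(a), n_A = length(a),
        mean_B = mean(b), sd_B = stats::sd(b), n_B = length(b),
        t = res$t, p_value = res$p,
        significant = !is.na(res$p) && res$p < alpha)
    }
  }
  do.call(rbind, rows)
}
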